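#' Read a JASPAR-style position frequency matrix
#'
#' Accepts the JASPAR PFM text layout: an optional `>ID NAME` header
#' followed by four rows of counts in A, C, G, T order, either bare
#' numbers or the bracketed `A [ 1 2 3 ]` form.
#'
#' @param path PFM file path.
#' @return Integer-count matrix (4 x k, rownames ACGT) with attribute
#'   `id`.
#' @export
read_pfm <- function(path) {
  lines <- trimws(readLines(path, warn = FALSE))
  lines <- lines[nzchar(lines)]
  id <- sub("\\.[^.]*$", "", basename(path))
  if (startsWith(lines[1L], ">")) {
    id <- strsplit(sub("^>\\s*", "", lines[1L]), "\\s+")[[1L]][1L]
    lines <- lines[-1L]
  }
  if (length(lines) < 4L) stop("PFM needs 4 count rows (A, C, G, T)", call. = FALSE)
  rows <- lapply(lines[1:4], function(l) {
    l <- sub("^[ACGTacgt]\\s*\\[", "", l)
    l <- sub("\\]\\s*$", "", l)
    vals <- suppressWarnings(as.numeric(strsplit(trimws(l), "\\s+")[[1L]]))
    if (anyNA(vals)) stop("non-numeric count in PFM", call. = FALSE)
    vals
  })
  if (length(unique(lengths(rows))) != 1L) {
    stop("PFM rows have unequal lengths", call. = FALSE)
  }
  counts <- do.call(rbind, rows)
  rownames(counts) <- c("A", "C", "G", "T")
  attr(counts, "id") <- id
  counts
}

#' Build a log-odds position weight matrix from counts
#'
#' Column counts receive a pseudocount distributed by the background
#' frequencies, are converted to per-position probabilities, and scored as
#' log2 odds against the background.
#'
#' @param counts 4 x k count matrix, rows A, C, G, T.
#' @param pseudocount Total pseudocount added per column (default 0.8),
#'   split across bases proportionally to `background`.
#' @param background Background base frequencies (A, C, G, T); uniform by
#'   default.
#' @param id Motif identifier; taken from `counts` when available.
#' @return Object of class `pwm`: list with `id`, `mat` (4 x k log2-odds),
#'   `background`, `max_score`.
#' @export
pwm_from_counts <- function(counts, pseudocount = 0.8,
                            background = rep(0.25, 4), id = NULL) {
  if (!is.matrix(counts) || nrow(counts) != 4L || ncol(counts) < 4L) {
    stop("`counts` must be a 4 x k matrix with k >= 4", call. = FALSE)
  }
  if (any(counts < 0)) stop("negative counts", call. = FALSE)
  background <- background / sum(background)
  if (is.null(id)) id <- attr(counts, "id") %||% "motif"
  adj <- counts + pseudocount * background
  probs <- sweep(adj, 2L, colSums(adj), "/")
  mat <- log2(probs / background)
  rownames(mat) <- c("A", "C", "G", "T")
  structure(
    list(id = id, mat = mat, background = background,
         max_score = sum(apply(mat, 2L, max))),
    class = "pwm"
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.pwm <- function(x, ...) {
  cat(sprintf("PWM '%s': width %d, max log2-odds score %.3f\n",
              x$id, ncol(x$mat), x$max_score))
  invisible(x)
}

#' Scan a sequence with a PWM
#'
#' Slides the motif over the sequence (and its reverse complement when
#' `strands = "both"`) and reports every window whose log2-odds score
#' reaches `threshold_frac` times the maximum attainable score of the
#' PWM. Windows containing `N` are skipped. Reverse-strand hits are
#' reported in forward coordinates.
#'
#' @param sequence DNA string over A, C, G, T, N (case-insensitive).
#' @param pwm A [pwm_from_counts()] object.
#' @param threshold_frac Score threshold as a fraction of the maximum
#'   attainable score, in (0, 1]; default 0.8.
#' @param strands `"both"` (default), `"+"` or `"-"`.
#' @param chrom Chromosome/sequence name attached to the hits.
#' @param offset Offset added to hit coordinates (absolute placement of
#'   the sequence start, 0-based).
#' @return Data frame of class `motif_hits` with columns `chrom`,
#'   `start`, `end` (0-based half-open), `strand`, `score`.
#' @export
pwm_scan <- function(sequence, pwm, threshold_frac = 0.8,
                     strands = c("both", "+", "-"), chrom = "seq",
                     offset = 0L) {
  strands <- match.arg(strands)
  stopifnot(inherits(pwm, "pwm"))
  stopifnot_scalar_number(threshold_frac, "threshold_frac")
  if (threshold_frac <= 0 || threshold_frac > 1) {
    stop("`threshold_frac` must be in (0, 1]", call. = FALSE)
  }
  k <- ncol(pwm$mat)
  seq_up <- toupper(sequence)
  threshold <- threshold_frac * pwm$max_score
  hits <- list()
  if (strands %in% c("both", "+")) {
    hits[["+"]] <- scan_strand(seq_up, pwm$mat, threshold)
  }
  if (strands %in% c("both", "-")) {
    rc <- revcomp(seq_up)
    h <- scan_strand(rc, pwm$mat, threshold)
    if (nrow(h)) {
      L <- nchar(seq_up)
      h$start <- L - (h$start + k)  # map rc window back to forward strand
    }
    hits[["-"]] <- h
  }
  out <- do.call(rbind, c(
    lapply(names(hits), function(s) {
      h <- hits[[s]]
      h$strand <- rep(s, nrow(h))
      h
    }),
    list(make.row.names = FALSE)
  ))
  if (is.null(out) || nrow(out) == 0L) {
    out <- data.frame(start = integer(), score = numeric(),
                      strand = character())
  }
  out <- data.frame(chrom = rep(chrom, nrow(out)),
                    start = as.integer(out$start + offset),
                    end = as.integer(out$start + offset + k),
                    strand = out$strand, score = out$score,
                    stringsAsFactors = FALSE)
  out <- out[order(out$start, out$strand), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("motif_hits", "data.frame")
  out
}

# Score all windows of one strand; returns 0-based window starts.
scan_strand <- function(seq_up, mat, threshold) {
  k <- ncol(mat)
  codes <- match(strsplit(seq_up, "", fixed = TRUE)[[1L]],
                 c("A", "C", "G", "T"))
  L <- length(codes)
  if (L < k) return(data.frame(start = integer(), score = numeric()))
  n_win <- L - k + 1L
  scores <- numeric(n_win)
  valid <- rep(TRUE, n_win)
  for (j in seq_len(k)) {
    cj <- codes[j:(j + n_win - 1L)]
    bad <- is.na(cj)
    valid <- valid & !bad
    cj[bad] <- 1L
    scores <- scores + mat[cbind(cj, j)]
  }
  keep <- valid & scores >= threshold
  data.frame(start = which(keep) - 1L, score = scores[keep])
}

revcomp <- function(x) {
  chartr("ACGTN", "TGCAN", paste(rev(strsplit(x, "", fixed = TRUE)[[1L]]),
                                 collapse = ""))
}

#' Motif co-occurrence within co-localized peak pairs
#'
#' A co-localized pair "contains both motifs" when at least one hit of
#' each motif overlaps the pair's union footprint (the two partner peak
#' intervals, merged where they touch).
#'
#' @param coloc A [colocalize()] result.
#' @param a,b The peak sets that produced `coloc`.
#' @param hits_a,hits_b `motif_hits` for the two motifs, in the same
#'   coordinate system as the peaks.
#' @return List with `n_pairs`, `n_both` and `fraction` of pairs
#'   containing at least one hit of each motif.
#' @export
pair_motif_cooccurrence <- function(coloc, a, b, hits_a, hits_b) {
  stopifnot(inherits(coloc, "coloc_result"))
  pairs <- coloc$pairs
  n_pairs <- nrow(pairs)
  if (n_pairs == 0L) return(list(n_pairs = 0L, n_both = 0L, fraction = 0))
  has_hit <- function(hits, chr, s1, e1, s2, e2) {
    if (nrow(hits) == 0L) return(rep(FALSE, length(chr)))
    vapply(seq_along(chr), function(i) {
      on_chr <- hits$chrom == chr[i]
      any(on_chr & hits$start < e1[i] & hits$end > s1[i]) ||
        any(on_chr & hits$start < e2[i] & hits$end > s2[i])
    }, logical(1))
  }
  chr <- a$chrom[pairs$index_a]
  s1 <- a$start[pairs$index_a]; e1 <- a$end[pairs$index_a]
  s2 <- b$start[pairs$index_b]; e2 <- b$end[pairs$index_b]
  both <- has_hit(hits_a, chr, s1, e1, s2, e2) &
          has_hit(hits_b, chr, s1, e1, s2, e2)
  list(n_pairs = n_pairs, n_both = sum(both), fraction = mean(both))
}
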