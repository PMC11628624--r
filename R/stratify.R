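#' Median-dichotomize expression values gene by gene
#'
#' For each requested gene present in the matrix, a sample is called HIGH
#' when its expression is strictly greater than the cohort median of that
#' gene (median of the cohort being scored; midpoint of the two central
#' order statistics for even n). Ties at the median are LOW, which bounds
#' the HIGH fraction per gene at 50%. Genes with any missing value are
#' dropped from the calls and reported, never imputed.
#'
#' @param matrix Numeric matrix, genes in rows (rownames = symbols),
#'   samples in columns (colnames = sample IDs), log2-scale expression.
#' @param genes Character vector of gene symbols to dichotomize.
#' @return A list of class `median_calls`: `calls` (logical genes x samples
#'   matrix, `TRUE` = HIGH), `genes_missing` (requested but absent),
#'   `genes_dropped` (present but containing missing values).
#' @examples
#' m <- matrix(1:4, 1, dimnames = list("G1", paste0("S", 1:4)))
#' median_dichotomize(m, "G1")$calls
#' @export
median_dichotomize <- function(matrix, genes) {
  matrix <- validate_expression_matrix(matrix)
  if (ncol(matrix) < 2L) stop("need at least 2 samples", call. = FALSE)
  genes <- unique(normalize_symbols(genes))
  present <- intersect(genes, rownames(matrix))
  missing <- setdiff(genes, present)
  sub <- matrix[present, , drop = FALSE]
  has_na <- rowSums(is.na(sub)) > 0L
  dropped <- rownames(sub)[has_na]
  sub <- sub[!has_na, , drop = FALSE]
  if (nrow(sub) == 0L) {
    stop("none of the requested genes are usable in the matrix", call. = FALSE)
  }
  med <- apply(sub, 1L, stats::median)
  calls <- sweep(sub, 1L, med, FUN = ">")
  structure(
    list(calls = calls, genes_missing = missing, genes_dropped = dropped),
    class = "median_calls"
  )
}

#' Score samples against a signature by HIGH-call tally
#'
#' Each sample's score is the number of signature genes called HIGH by
#' [median_dichotomize()]. Coverage records the fraction of signature
#' genes actually used (present in the matrix and free of missing values).
#'
#' @param matrix Expression matrix as in [median_dichotomize()].
#' @param sig A [gene_signature] (or plain character vector of symbols).
#' @return A list of class `signature_scores`: `scores` (named integer,
#'   one per sample), `coverage` (fraction of signature genes used),
#'   `genes_used`, `genes_missing`, `genes_dropped`.
#' @examples
#' m <- rbind(G1 = 1:4, G2 = 4:1)
#' colnames(m) <- paste0("S", 1:4)
#' signature_score(m, gene_signature("toy", c("G1", "G2")))$scores
#' @export
signature_score <- function(matrix, sig) {
  genes <- if (inherits(sig, "gene_signature")) sig$genes else normalize_symbols(sig)
  dich <- median_dichotomize(matrix, genes)
  scores <- as.integer(colSums(dich$calls))
  names(scores) <- colnames(dich$calls)
  structure(
    list(scores = scores,
         coverage = nrow(dich$calls) / length(unique(genes)),
         genes_used = rownames(dich$calls),
         genes_missing = dich$genes_missing,
         genes_dropped = dich$genes_dropped),
    class = "signature_scores"
  )
}

#' @export
print.signature_scores <- function(x, ...) {
  cat(sprintf("Signature scores for %d samples (%d genes used, coverage %.1f%%)\n",
              length(x$scores), length(x$genes_used), 100 * x$coverage))
  print(utils::head(x$scores))
  invisible(x)
}

#' Stratify samples into k equally sized ordered groups
#'
#' Samples are sorted ascending by score, ties broken deterministically by
#' sample ID, and cut into k contiguous blocks whose sizes differ by at
#' most one (the larger blocks sit at the low end when `n %% k != 0`). The
#' lowest block receives the first label.
#'
#' @param scores Named numeric vector (sample -> score), or a
#'   `signature_scores` object.
#' @param k Number of groups (>= 2).
#' @param labels Group labels, lowest to highest; length k.
#' @return Named factor of group labels with levels `labels`.
#' @examples
#' s <- stats::setNames(1:9, paste0("S", 1:9))
#' stratify_equal_groups(s)
#' @export
stratify_equal_groups <- function(scores, k = 3L,
                                  labels = c("LOW", "INT", "HIGH")) {
  if (inherits(scores, "signature_scores")) scores <- scores$scores
  if (is.null(names(scores)) || anyNA(scores)) {
    stop("`scores` must be a named vector without missing values", call. = FALSE)
  }
  k <- as.integer(k)
  if (k < 2L) stop("`k` must be >= 2", call. = FALSE)
  if (length(labels) != k) stop("`labels` must have length k", call. = FALSE)
  n <- length(scores)
  if (n < k) stop("fewer samples than groups", call. = FALSE)
  ord <- order(scores, names(scores), method = "radix")
  sizes <- rep(n %/% k, k)
  r <- n %% k
  if (r > 0L) sizes[seq_len(r)] <- sizes[seq_len(r)] + 1L
  lab <- rep(labels, times = sizes)
  out <- factor(character(n), levels = labels)
  out[ord] <- lab
  names(out) <- names(scores)
  out
}

#' Dichotomize a single variable by lower/upper quantile tails
#'
#' The bottom `floor(q * n)` samples by value are labeled LOW, the top
#' `floor(q * n)` HIGH, and the remainder EXCLUDED; ties are broken by
#' sample ID. With the default `q = 1/3` this is the "33% lowest or
#' highest" single-gene cut used for SOX2, with the middle third dropped
#' from downstream contrasts.
#'
#' @param values Named numeric vector (sample -> value).
#' @param q Tail fraction, `0 < q <= 0.5`.
#' @param labels Labels for (low tail, middle, high tail).
#' @return Named factor with levels `labels`.
#' @examples
#' quantile_dichotomize(stats::setNames(1:9, paste0("S", 1:9)))
#' @export
quantile_dichotomize <- function(values, q = 1 / 3,
                                 labels = c("LOW", "EXCLUDED", "HIGH")) {
  if (is.null(names(values)) || anyNA(values)) {
    stop("`values` must be a named vector without missing values", call. = FALSE)
  }
  stopifnot_scalar_number(q, "q")
  if (q <= 0 || q > 0.5) stop("`q` must be in (0, 0.5]", call. = FALSE)
  n <- length(values)
  if (n < 3L) stop("need at least 3 samples", call. = FALSE)
  m <- floor(q * n + sqrt(.Machine$double.eps))
  ord <- order(values, names(values), method = "radix")
  out <- factor(rep(labels[2L], n), levels = labels)
  if (m > 0L) {
    out[ord[seq_len(m)]] <- labels[1L]
    out[ord[seq.int(n - m + 1L, n)]] <- labels[3L]
  }
  names(out) <- names(values)
  out
}

#' Cross-stratify two labelings into four combined groups
#'
#' Samples labeled LOW or HIGH under both inputs receive a combined label
#' (e.g. `"NOTCH_HIGH/SOX2_LOW"`); samples that are intermediate under
#' either input (INT / EXCLUDED) are dropped and reported via the
#' `"dropped"` attribute.
#'
#' @param a Named factor over `{LOW, INT, HIGH}` (tertile labels).
#' @param b Named factor over `{LOW, EXCLUDED, HIGH}` (quantile labels).
#' @param prefixes Length-2 names used to build combined labels.
#' @return Named factor over the four combined labels (kept samples only),
#'   with attribute `dropped` listing the removed sample IDs.
#' @export
cross_stratify <- function(a, b, prefixes = c("A", "B")) {
  if (is.null(names(a)) || is.null(names(b))) {
    stop("`a` and `b` must be named", call. = FALSE)
  }
  if (!setequal(names(a), names(b))) {
    stop("`a` and `b` must label the same samples", call. = FALSE)
  }
  b <- b[names(a)]
  keep <- as.character(a) %in% c("LOW", "HIGH") &
          as.character(b) %in% c("LOW", "HIGH")
  combos <- as.vector(outer(c("HIGH", "LOW"), c("HIGH", "LOW"), function(x, y) {
    sprintf("%s_%s/%s_%s", prefixes[1L], x, prefixes[2L], y)
  }))
  lab <- sprintf("%s_%s/%s_%s", prefixes[1L], as.character(a)[keep],
                 prefixes[2L], as.character(b)[keep])
  out <- factor(lab, levels = combos)
  names(out) <- names(a)[keep]
  attr(out, "dropped") <- names(a)[!keep]
  out
}

#' Classify NOTCH receptor genetic alterations per sample
#'
#' A sample is `mutated` when any of the receptor genes carries a missense
#' mutation, `amplified` when any carries a copy-number code of 2
#' (high-level amplification); the two flags are independent and combine
#' to `mutated+amplified`.
#'
#' @param table Data frame with columns `sample`, `gene`, `missense`
#'   (logical) and `cna` (integer codes in -2..2; `NA` allowed).
#' @param genes Receptor genes considered.
#' @param samples Sample universe; defaults to the samples in `table`.
#'   Samples without qualifying records are classified `none`.
#' @return Named factor with levels
#'   `none, mutated, amplified, mutated+amplified`.
#' @export
classify_notch_alteration <- function(table,
                                      genes = paste0("NOTCH", 1:4),
                                      samples = NULL) {
  if (!is.data.frame(table) ||
      !all(c("sample", "gene", "missense", "cna") %in% names(table))) {
    stop("`table` needs columns sample, gene, missense, cna", call. = FALSE)
  }
  bad <- !is.na(table$cna) & !table$cna %in% -2:2
  if (any(bad)) {
    stop(sprintf("unknown cna code(s): %s",
                 paste(unique(table$cna[bad]), collapse = ", ")), call. = FALSE)
  }
  table$gene <- normalize_symbols(table$gene)
  if (is.null(samples)) samples <- unique(as.character(table$sample))
  rel <- table[table$gene %in% normalize_symbols(genes), , drop = FALSE]
  mut <- unique(rel$sample[isTRUE_vec(rel$missense)])
  amp <- unique(rel$sample[!is.na(rel$cna) & rel$cna == 2L])
  lab <- ifelse(samples %in% mut & samples %in% amp, "mutated+amplified",
         ifelse(samples %in% mut, "mutated",
         ifelse(samples %in% amp, "amplified", "none")))
  out <- factor(lab, levels = c("none", "mutated", "amplified",
                                "mutated+amplified"))
  names(out) <- samples
  out
}

isTRUE_vec <- function(x) !is.na(x) & as.logical(x)

validate_expression_matrix <- function(matrix) {
  if (is.data.frame(matrix)) matrix <- as.matrix(matrix)
  if (!is.matrix(matrix) || !is.numeric(matrix)) {
    stop("expression must be a numeric matrix (genes x samples)", call. = FALSE)
  }
  if (is.null(rownames(matrix)) || is.null(colnames(matrix))) {
    stop("expression matrix needs gene rownames and sample colnames", call. = FALSE)
  }
  rownames(matrix) <- normalize_symbols(rownames(matrix))
  if (anyDuplicated(rownames(matrix))) stop("duplicate gene rows", call. = FALSE)
  if (anyDuplicated(colnames(matrix))) stop("duplicate sample columns", call. = FALSE)
  matrix
}
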