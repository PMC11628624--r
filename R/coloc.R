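#' Construct a peak set
#'
#' Peaks are genomic intervals in 0-based half-open coordinates carrying a
#' single-bp summit (the highest-scoring position) inside the interval.
#'
#' @param chrom Character chromosome names.
#' @param start,end Integer interval bounds, `0 <= start < end`.
#' @param summit Integer absolute summit positions in `[start, end)`;
#'   defaults to the interval midpoint (floor).
#' @param score Numeric peak scores (optional).
#' @param name Peak names (optional).
#' @return Data frame of class `peak_set`.
#' @export
peak_set <- function(chrom, start, end, summit = NULL, score = NA_real_,
                     name = NA_character_) {
  chrom <- as.character(chrom)
  start <- as.integer(start)
  end <- as.integer(end)
  if (any(is.na(start) | is.na(end) | start < 0L | end <= start)) {
    stop("invalid interval coordinates (need 0 <= start < end)", call. = FALSE)
  }
  if (is.null(summit)) summit <- start + (end - start) %/% 2L
  summit <- as.integer(summit)
  if (any(summit < start | summit >= end)) {
    stop("summit outside its interval", call. = FALSE)
  }
  structure(
    data.frame(chrom = chrom, start = start, end = end, summit = summit,
               score = score, name = name, stringsAsFactors = FALSE),
    class = c("peak_set", "data.frame")
  )
}

#' @export
print.peak_set <- function(x, ...) {
  cat(sprintf("Peak set: %d peaks on %d chromosome(s)\n",
              nrow(x), length(unique(x$chrom))))
  print.data.frame(utils::head(x), row.names = FALSE)
  if (nrow(x) > 6L) cat(sprintf("... %d more\n", nrow(x) - 6L))
  invisible(x)
}

#' Region sets (BED3-style intervals)
#'
#' @param chrom,start,end Interval coordinates, 0-based half-open; regions
#'   may overlap.
#' @return Data frame of class `region_set`.
#' @export
region_set <- function(chrom, start, end) {
  start <- as.integer(start)
  end <- as.integer(end)
  if (any(is.na(start) | is.na(end) | start < 0L | end <= start)) {
    stop("invalid region coordinates", call. = FALSE)
  }
  structure(
    data.frame(chrom = as.character(chrom), start = start, end = end,
               stringsAsFactors = FALSE),
    class = c("region_set", "data.frame")
  )
}

#' Nearest summit-to-summit distance per query peak
#'
#' For each query peak, the minimum absolute distance between its summit
#' and any target summit on the same chromosome, found by binary search in
#' per-chromosome sorted summit vectors (O((n+m) log m)). Query peaks on
#' chromosomes absent from the target get `NA`.
#'
#' @param query,target `peak_set` objects (non-empty).
#' @return Data frame with `distance` (integer bp or `NA`) and
#'   `target_index` (row index of the nearest target peak, ties to the
#'   leftward summit).
#' @export
nearest_summit_distance <- function(query, target) {
  for (nm in c("query", "target")) {
    p <- get(nm)
    if (!is.data.frame(p) || nrow(p) == 0L) {
      stop(sprintf("`%s` must be a non-empty peak set", nm), call. = FALSE)
    }
  }
  dist <- rep(NA_integer_, nrow(query))
  tidx <- rep(NA_integer_, nrow(query))
  for (chr in unique(query$chrom)) {
    qi <- which(query$chrom == chr)
    ti <- which(target$chrom == chr)
    if (length(ti) == 0L) next
    ord <- ti[order(target$summit[ti])]
    ts <- target$summit[ord]
    qs <- query$summit[qi]
    pos <- findInterval(qs, ts)  # index of rightmost ts <= qs
    left <- pmax(pos, 1L)
    right <- pmin(pos + 1L, length(ts))
    dl <- abs(qs - ts[left])
    dr <- abs(ts[right] - qs)
    use_left <- dl <= dr
    dist[qi] <- as.integer(ifelse(use_left, dl, dr))
    tidx[qi] <- ord[ifelse(use_left, left, right)]
  }
  data.frame(distance = dist, target_index = tidx)
}

#' Summit co-localization between two peak sets
#'
#' A peak of one set is co-localized when its nearest summit in the other
#' set (same chromosome) lies strictly closer than `max_dist` bp. The two
#' directions are computed independently, so `fraction_a` and
#' `fraction_b` need not agree.
#'
#' @param a,b `peak_set` objects.
#' @param max_dist Distance threshold in bp (strict `<`); default 500.
#' @return Object of class `coloc_result`: `pairs` (data frame
#'   `index_a`, `index_b`, `distance` for co-localized A peaks and their
#'   nearest B partner), `n_a`, `n_b`, `coloc_a`, `coloc_b`,
#'   `fraction_a`, `fraction_b`, `max_dist`.
#' @export
colocalize <- function(a, b, max_dist = 500L) {
  stopifnot_scalar_number(max_dist, "max_dist")
  if (max_dist <= 0) stop("`max_dist` must be positive", call. = FALSE)
  da <- nearest_summit_distance(a, b)
  db <- nearest_summit_distance(b, a)
  hit_a <- !is.na(da$distance) & da$distance < max_dist
  hit_b <- !is.na(db$distance) & db$distance < max_dist
  structure(
    list(pairs = data.frame(index_a = which(hit_a),
                            index_b = da$target_index[hit_a],
                            distance = da$distance[hit_a]),
         n_a = nrow(a), n_b = nrow(b),
         coloc_a = sum(hit_a), coloc_b = sum(hit_b),
         fraction_a = mean(hit_a), fraction_b = mean(hit_b),
         max_dist = max_dist),
    class = "coloc_result"
  )
}

#' @export
print.coloc_result <- function(x, ...) {
  cat(sprintf("Summit co-localization (< %d bp):\n", x$max_dist))
  cat(sprintf("  set A: %d / %d peaks co-localized (%.1f%%)\n",
              x$coloc_a, x$n_a, 100 * x$fraction_a))
  cat(sprintf("  set B: %d / %d peaks co-localized (%.1f%%)\n",
              x$coloc_b, x$n_b, 100 * x$fraction_b))
  invisible(x)
}

#' Sample background positions from a region set
#'
#' Draws n positions uniformly over the concatenated base-pair space of
#' the regions (length-weighted region choice, then uniform offset, with
#' replacement), as degenerate 1-bp peaks. Used to build the resampled
#' background null for enrichment testing against enhancer space.
#'
#' @param regions A `region_set`.
#' @param n Number of positions to draw.
#' @param seed RNG seed (required; draws are reproducible given the seed).
#' @return A `peak_set` of n single-bp peaks.
#' @export
sample_background_positions <- function(regions, n, seed) {
  if (!is.data.frame(regions) || nrow(regions) == 0L) {
    stop("`regions` must be a non-empty region set", call. = FALSE)
  }
  n <- as.integer(n)
  if (n < 1L) stop("`n` must be >= 1", call. = FALSE)
  widths <- regions$end - regions$start
  with_seed(seed, {
    ridx <- sample.int(nrow(regions), n, replace = TRUE, prob = widths)
    offs <- floor(stats::runif(n) * widths[ridx])
    pos <- as.integer(regions$start[ridx] + offs)
    peak_set(regions$chrom[ridx], pos, pos + 1L, summit = pos,
             name = sprintf("bg_%d", seq_len(n)))
  })
}

#' Fisher exact test on co-localization proportions
#'
#' Two-sided Fisher exact p-value for the 2x2 table contrasting
#' co-localized vs non-co-localized counts in the observed and background
#' sets, computed by exact hypergeometric enumeration: the two-sided p is
#' the total probability of all tables with the given margins whose
#' probability does not exceed that of the observed table (the
#' probability-mass definition used by standard statistical packages).
#'
#' @param obs_coloc,obs_total Co-localized and total peaks, observed set.
#' @param bg_coloc,bg_total Same for the background set.
#' @param alternative `"two.sided"` (default), `"greater"` (observed
#'   proportion larger) or `"less"`.
#' @return The p-value (single numeric).
#' @examples
#' coloc_enrichment_test(8, 10, 2, 10)
#' @export
coloc_enrichment_test <- function(obs_coloc, obs_total, bg_coloc, bg_total,
                                  alternative = c("two.sided", "greater",
                                                  "less")) {
  alternative <- match.arg(alternative)
  counts <- c(obs_coloc, obs_total, bg_coloc, bg_total)
  if (any(counts != floor(counts)) || any(counts < 0)) {
    stop("counts must be non-negative integers", call. = FALSE)
  }
  if (obs_coloc > obs_total || bg_coloc > bg_total) {
    stop("co-localized count exceeds total", call. = FALSE)
  }
  r1 <- obs_total; r2 <- bg_total
  kk <- obs_coloc + bg_coloc
  if (r1 + r2 == 0L || kk == 0L || kk == r1 + r2) return(1)
  support <- max(0L, kk - r2):min(kk, r1)
  probs <- stats::dhyper(support, r1, r2, kk)
  p_obs <- probs[match(obs_coloc, support)]
  p <- switch(alternative,
    two.sided = sum(probs[probs <= p_obs * (1 + 1e-7)]),
    greater   = sum(probs[support >= obs_coloc]),
    less      = sum(probs[support <= obs_coloc])
  )
  min(p, 1)
}
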