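# Independent brute-force oracles used across the suite. These deliberately
# re-derive results by the most naive route available (all-pairs scans,
# explicit enumeration, per-cell loops) and never call the code paths they
# check.

# Kaplan-Meier by explicit cumulative product over event times.
oracle_km <- function(time, event) {
  ts <- sort(unique(time[event == 1]))
  s <- 1
  out <- data.frame(time = ts, survival = NA_real_)
  for (i in seq_along(ts)) {
    at_risk <- sum(time >= ts[i])
    deaths <- sum(time == ts[i] & event == 1)
    s <- s * (1 - deaths / at_risk)
    out$survival[i] <- s
  }
  out
}

# Two-group log-rank via the scalar (O-E)^2/V formulation, looping over
# event times.
oracle_logrank2 <- function(time, event, group) {
  g <- sort(unique(group))
  stopifnot(length(g) == 2)
  ts <- sort(unique(time[event == 1]))
  O1 <- E1 <- V <- 0
  for (t in ts) {
    at <- time >= t
    n <- sum(at)
    n1 <- sum(at & group == g[1])
    d <- sum(time == t & event == 1)
    d1 <- sum(time == t & event == 1 & group == g[1])
    O1 <- O1 + d1
    E1 <- E1 + d * n1 / n
    if (n > 1) V <- V + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  chisq <- (O1 - E1)^2 / V
  list(chisq = chisq, p = pchisq(chisq, 1, lower.tail = FALSE))
}

# All-pairs nearest summit distance (quadratic scan).
oracle_nearest <- function(query, target) {
  vapply(seq_len(nrow(query)), function(i) {
    same <- target$chrom == query$chrom[i]
    if (!any(same)) return(NA_real_)
    min(abs(target$summit[same] - query$summit[i]))
  }, numeric(1))
}

# Two-sided Fisher p by exhaustive enumeration of all tables with the
# observed margins, probabilities from choose() directly.
oracle_fisher2 <- function(a, r1, c_, r2) {
  k <- a + c_
  total <- choose(r1 + r2, k)
  support <- max(0, k - r2):min(k, r1)
  probs <- choose(r1, support) * choose(r2, k - support) / total
  p_obs <- probs[match(a, support)]
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# Exhaustive per-window PWM rescoring on one strand of a sequence.
oracle_scan_strand <- function(seq_chr, mat) {
  bases <- strsplit(seq_chr, "")[[1]]
  k <- ncol(mat)
  n <- length(bases)
  if (n < k) return(data.frame(start = integer(), score = numeric()))
  res <- list()
  for (p in seq_len(n - k + 1)) {
    win <- bases[p:(p + k - 1)]
    idx <- match(win, c("A", "C", "G", "T"))
    if (anyNA(idx)) next
    res[[length(res) + 1]] <-
      data.frame(start = p - 1, score = sum(mat[cbind(idx, seq_len(k))]))
  }
  if (!length(res)) return(data.frame(start = integer(), score = numeric()))
  do.call(rbind, res)
}

oracle_revcomp <- function(x) {
  comp <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
  paste(rev(comp[strsplit(x, "")[[1]]]), collapse = "")
}

random_dna <- function(n, p_n = 0) {
  sample(c("A", "C", "G", "T", "N"), n, replace = TRUE,
         prob = c(rep((1 - p_n) / 4, 4), p_n)) |> paste(collapse = "")
}

# Random peak set on a few chromosomes.
random_peaks <- function(n, chroms = c("chr1", "chr2", "chr3"),
                         span = 1e6) {
  summit <- sample.int(span - 600, n) + 300
  peak_set(sample(chroms, n, replace = TRUE), summit - 250, summit + 250,
           summit = summit)
}
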