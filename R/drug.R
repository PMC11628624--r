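#' Z'-factor plate quality control
#'
#' Screening-window statistic `1 - 3 (sd_pos + sd_neg) / |mean_pos -
#' mean_neg|` with sample (n-1) standard deviations. Values above 0.5
#' indicate an excellent assay window.
#'
#' @param pos,neg Numeric readings for the positive and negative control
#'   wells (at least 2 each).
#' @return The Z'-factor (single numeric; 1 in the zero-variance limit).
#' @examples
#' zprime(rnorm(16, 100, 5), rnorm(16, 0, 5))
#' @export
zprime <- function(pos, neg) {
  if (length(pos) < 2L || length(neg) < 2L) {
    stop("need at least 2 readings per control arm", call. = FALSE)
  }
  delta <- abs(mean(pos) - mean(neg))
  if (delta == 0) stop("control means are identical; Z' undefined", call. = FALSE)
  1 - 3 * (stats::sd(pos) + stats::sd(neg)) / delta
}

#' Fit a four-parameter logistic dose-response curve
#'
#' Least-squares fit of `response = bottom + (top - bottom) / (1 +
#' (ic50 / dose)^hill)` with the IC50 parameterized on the log scale for
#' stability, bounded parameters (`bottom` in \[-20, 50\], `top` in
#' \[50, 120\], `hill` in (0, 10\], IC50 within 100x the tested dose
#' range) and multi-start initialization over a hill/IC50 grid. Poor or
#' degenerate fits set `converged = FALSE` rather than raising.
#'
#' @param doses Strictly positive doses (>= 4 distinct values).
#' @param responses Percent inhibition at each dose.
#' @return Object of class `dose_response_fit`: `coefficients`
#'   (bottom, top, ic50, hill), `rss`, `converged`, `data`.
#' @examples
#' d <- 10^seq(-2, 2, length.out = 8)
#' fit_4pl(d, 100 / (1 + (1 / d)^1.2))
#' @export
fit_4pl <- function(doses, responses) {
  if (length(doses) != length(responses)) {
    stop("`doses` and `responses` lengths differ", call. = FALSE)
  }
  if (length(unique(doses)) < 4L) {
    stop("need at least 4 distinct doses", call. = FALSE)
  }
  if (any(doses <= 0)) stop("doses must be strictly positive", call. = FALSE)
  dat <- data.frame(dose = as.numeric(doses), resp = as.numeric(responses))
  fail <- structure(
    list(coefficients = c(bottom = NA_real_, top = NA_real_,
                          ic50 = NA_real_, hill = NA_real_),
         rss = NA_real_, converged = FALSE, data = dat),
    class = "dose_response_fit"
  )
  if (stats::sd(dat$resp) < .Machine$double.eps^0.5) return(fail)
  lic_lo <- log(min(dat$dose) / 100)
  lic_hi <- log(max(dat$dose) * 100)
  lower <- c(bottom = -20, top = 50, lic50 = lic_lo, hill = 1e-3)
  upper <- c(bottom = 50, top = 120, lic50 = lic_hi, hill = 10)
  starts <- expand.grid(
    hill = c(0.5, 1, 2, 4),
    lic50 = log(stats::quantile(dat$dose, c(0.2, 0.5, 0.8), names = FALSE))
  )
  best <- NULL
  for (i in seq_len(nrow(starts))) {
    st <- c(bottom = max(min(dat$resp), -20),
            top = min(max(max(dat$resp), 50), 120),
            lic50 = starts$lic50[i], hill = starts$hill[i])
    fit <- tryCatch(
      minpack.lm::nlsLM(
        resp ~ bottom + (top - bottom) /
          (1 + exp(hill * (lic50 - log(dose)))),
        data = dat, start = as.list(st),
        lower = lower, upper = upper,
        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (is.null(fit)) next
    rss <- sum(stats::residuals(fit)^2)
    if (is.null(best) || rss < best$rss) best <- list(fit = fit, rss = rss)
  }
  if (is.null(best)) return(fail)
  cf <- stats::coef(best$fit)
  structure(
    list(coefficients = c(bottom = unname(cf["bottom"]),
                          top = unname(cf["top"]),
                          ic50 = exp(unname(cf["lic50"])),
                          hill = unname(cf["hill"])),
         rss = best$rss, converged = TRUE, data = dat),
    class = "dose_response_fit"
  )
}

#' @export
print.dose_response_fit <- function(x, ...) {
  if (!x$converged) {
    cat("4PL dose-response fit: did not converge\n")
    return(invisible(x))
  }
  cf <- x$coefficients
  cat(sprintf(
    "4PL dose-response fit (n = %d): bottom %.2f, top %.2f, IC50 %.4g, hill %.3f (RSS %.3g)\n",
    nrow(x$data), cf["bottom"], cf["top"], cf["ic50"], cf["hill"], x$rss))
  invisible(x)
}

#' @export
coef.dose_response_fit <- function(object, ...) object$coefficients

#' @export
predict.dose_response_fit <- function(object, newdata = NULL, ...) {
  if (!object$converged) stop("fit did not converge", call. = FALSE)
  dose <- if (is.null(newdata)) object$data$dose else {
    if (is.data.frame(newdata)) newdata$dose else newdata
  }
  cf <- object$coefficients
  cf["bottom"] + (cf["top"] - cf["bottom"]) /
    (1 + (cf["ic50"] / dose)^cf["hill"])
}

#' @export
residuals.dose_response_fit <- function(object, ...) {
  object$data$resp - predict(object)
}

#' @export
plot.dose_response_fit <- function(x, ...) {
  graphics::plot(x$data$dose, x$data$resp, log = "x",
                 xlab = "Dose", ylab = "% inhibition", ...)
  if (x$converged) {
    grid_d <- exp(seq(log(min(x$data$dose)), log(max(x$data$dose)),
                      length.out = 200))
    graphics::lines(grid_d, predict(x, grid_d))
  }
  invisible(x)
}

#' Hill-slope plausibility filter
#'
#' Keeps curves whose fitted Hill slope lies strictly inside `(lo, hi)`
#' (default 0.5 < hill < 5), the screening criterion for plausible
#' single-agent dose-response behavior.
#'
#' @param curve A converged [fit_4pl()] result.
#' @param lo,hi Strict bounds on the Hill slope.
#' @return `TRUE` when the slope passes.
#' @export
hill_filter <- function(curve, lo = 0.5, hi = 5) {
  stopifnot(inherits(curve, "dose_response_fit"))
  if (!curve$converged) stop("fit did not converge", call. = FALSE)
  hill <- curve$coefficients[["hill"]]
  hill > lo && hill < hi
}

#' Construct a dose matrix
#'
#' Percent-inhibition measurements over a two-drug concentration grid.
#' Both dose vectors must include 0 (the monotherapy row/column); cell
#' `[1, 1]` is the untreated baseline.
#'
#' @param doses_a,doses_b Increasing dose vectors including 0.
#' @param inhibition Numeric matrix, `length(doses_a)` x
#'   `length(doses_b)`, percent inhibition.
#' @return Object of class `dose_matrix`.
#' @export
dose_matrix <- function(doses_a, doses_b, inhibition) {
  doses_a <- as.numeric(doses_a); doses_b <- as.numeric(doses_b)
  for (d in list(doses_a, doses_b)) {
    if (d[1L] != 0 || is.unsorted(d, strictly = TRUE)) {
      stop("dose vectors must be strictly increasing and start at 0",
           call. = FALSE)
    }
  }
  inhibition <- as.matrix(inhibition)
  if (!all(dim(inhibition) == c(length(doses_a), length(doses_b)))) {
    stop("inhibition matrix does not match the dose grid", call. = FALSE)
  }
  if (anyNA(inhibition)) stop("missing inhibition values", call. = FALSE)
  dimnames(inhibition) <- list(doses_a, doses_b)
  structure(list(doses_a = doses_a, doses_b = doses_b,
                 inhibition = inhibition),
            class = "dose_matrix")
}

#' Highest-single-agent (HSA) synergy score
#'
#' For every combination cell (both doses > 0) the excess over the HSA
#' reference is `inhibition(i, j) - max(inhibition(i, 0),
#' inhibition(0, j))`, in percentage points; the summary score is the
#' arithmetic mean of the excesses over all combination cells.
#'
#' @param matrix A [dose_matrix()].
#' @return Object of class `hsa_synergy`: `excess` (matrix over
#'   combination cells), `score` (mean excess, percentage points),
#'   `n_cells`.
#' @export
hsa_score <- function(matrix) {
  stopifnot(inherits(matrix, "dose_matrix"))
  inh <- matrix$inhibition
  na <- length(matrix$doses_a); nb <- length(matrix$doses_b)
  if (na < 2L || nb < 2L) {
    stop("dose matrix has no combination cells", call. = FALSE)
  }
  mono_a <- inh[, 1L]  # drug A alone, per dose of A
  mono_b <- inh[1L, ]  # drug B alone, per dose of B
  ref <- outer(mono_a[-1L], mono_b[-1L], pmax)
  excess <- inh[-1L, -1L, drop = FALSE] - ref
  structure(
    list(excess = excess, score = mean(excess), n_cells = length(excess)),
    class = "hsa_synergy"
  )
}

#' @export
print.hsa_synergy <- function(x, ...) {
  cat(sprintf("HSA synergy: mean excess %.2f points over %d combination cells\n",
              x$score, x$n_cells))
  invisible(x)
}

#' @export
plot.hsa_synergy <- function(x, ...) {
  graphics::image(seq_len(nrow(x$excess)), seq_len(ncol(x$excess)),
                  x$excess, xlab = "Drug A dose index",
                  ylab = "Drug B dose index",
                  main = sprintf("HSA excess (score %.1f)", x$score), ...)
  invisible(x)
}
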