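#' Cap follow-up at a maximum duration
#'
#' Records observed beyond the cap are administratively censored at the
#' cap; records at or below it are untouched. An event falling exactly on
#' the cap is kept as an event.
#'
#' @param table Data frame with columns `sample`, `time` (months, >= 0),
#'   `event` (0/1) and optionally `group`.
#' @param cap Maximum follow-up in months; default 120 (10 years).
#' @return The capped table.
#' @examples
#' tab <- data.frame(sample = c("a", "b"), time = c(140, 60), event = 1)
#' cap_followup(tab)
#' @export
cap_followup <- function(table, cap = 120) {
  table <- validate_survival_table(table, need_group = FALSE)
  stopifnot_scalar_number(cap, "cap")
  if (cap <= 0) stop("`cap` must be positive", call. = FALSE)
  over <- table$time > cap
  table$time[over] <- cap
  table$event[over] <- 0L
  table
}

#' Kaplan-Meier product-limit estimate
#'
#' Survival is estimated as the cumulative product of `1 - d_i / n_i` over
#' distinct event times `t_i`, with `d_i` events occurring simultaneously
#' at `t_i` and `n_i` subjects at risk (censorings at an event time count
#' as at risk through that time). Times with only censorings do not change
#' the curve.
#'
#' @param table Survival table as in [cap_followup()].
#' @param group If given, restrict the estimate to this group label.
#' @return Object of class `km_curve`: data frame with columns `time`,
#'   `n_risk`, `n_event`, `survival` (rows at distinct event times), plus
#'   attributes `n` (subjects) and `group`.
#' @examples
#' km_estimate(data.frame(sample = c("a", "b"), time = c(5, 7),
#'                        event = c(1, 0)))
#' @export
km_estimate <- function(table, group = NULL) {
  table <- validate_survival_table(table, need_group = !is.null(group))
  if (!is.null(group)) table <- table[table$group == group, , drop = FALSE]
  if (nrow(table) == 0L) stop("no records selected", call. = FALSE)
  times <- sort(unique(table$time[table$event == 1L]))
  n_risk <- vapply(times, function(t) sum(table$time >= t), numeric(1))
  n_event <- vapply(times, function(t) {
    sum(table$time == t & table$event == 1L)
  }, numeric(1))
  surv <- cumprod(1 - n_event / n_risk)
  structure(
    data.frame(time = times, n_risk = n_risk, n_event = n_event,
               survival = surv),
    class = c("km_curve", "data.frame"),
    n = nrow(table), group = if (is.null(group)) "all" else group
  )
}

#' @export
print.km_curve <- function(x, ...) {
  cat(sprintf("Kaplan-Meier curve (group '%s', n = %d, %d event times)\n",
              attr(x, "group"), attr(x, "n"), nrow(x)))
  print.data.frame(x, row.names = FALSE)
  invisible(x)
}

#' Plot a Kaplan-Meier step curve
#'
#' @param x A `km_curve`.
#' @param ... Passed to [graphics::plot.default()].
#' @export
plot.km_curve <- function(x, ...) {
  graphics::plot(c(0, x$time), c(1, x$survival), type = "s",
                 xlab = "Time (months)", ylab = "Survival probability",
                 ylim = c(0, 1), ...)
  invisible(x)
}

#' k-sample log-rank test
#'
#' At each distinct event time the observed events per group are compared
#' with their expectation under the hypergeometric model for the pooled
#' risk set; the chi-square statistic is the quadratic form of the
#' observed-minus-expected vector with its hypergeometric covariance
#' (reducing to the familiar scalar `(O-E)^2/V` for two groups), referred
#' to a chi-square distribution with k-1 degrees of freedom.
#'
#' @param table Survival table with a `group` column (>= 2 groups).
#' @return Object of class `logrank_test`: `chisq`, `df`, `p.value`, plus
#'   per-group `observed` and `expected` event counts and `n`.
#' @export
logrank_test <- function(table) {
  table <- validate_survival_table(table, need_group = TRUE)
  groups <- sort(unique(as.character(table$group)))
  k <- length(groups)
  if (k < 2L) stop("log-rank needs at least 2 groups", call. = FALSE)
  gidx <- match(as.character(table$group), groups)
  times <- sort(unique(table$time[table$event == 1L]))
  O <- E <- numeric(k)
  V <- matrix(0, k, k)
  for (t in times) {
    at_risk <- table$time >= t
    n <- sum(at_risk)
    nj <- tabulate(gidx[at_risk], nbins = k)
    ev <- table$event == 1L & table$time == t
    d <- sum(ev)
    dj <- tabulate(gidx[ev], nbins = k)
    O <- O + dj
    E <- E + d * nj / n
    if (n > 1L) {
      # hypergeometric covariance of the event-count vector at this time
      scale <- d * (n - d) / (n - 1) / n^2
      V <- V + scale * (diag(nj * n, k) - outer(nj, nj))
    }
  }
  u <- (O - E)[-k]
  Vk <- V[-k, -k, drop = FALSE]
  chisq <- tryCatch(drop(t(u) %*% solve(Vk, u)), error = function(e) {
    # singular covariance (e.g. a group with no risk overlap): use a
    # generalized inverse
    drop(t(u) %*% ginv_sym(Vk) %*% u)
  })
  if (length(chisq) == 0L || is.na(chisq)) chisq <- 0
  chisq <- max(chisq, 0)
  df <- k - 1L
  structure(
    list(chisq = chisq, df = df,
         p.value = stats::pchisq(chisq, df, lower.tail = FALSE),
         observed = stats::setNames(O, groups),
         expected = stats::setNames(E, groups),
         n = nrow(table)),
    class = "logrank_test"
  )
}

ginv_sym <- function(m, tol = 1e-12) {
  e <- eigen(m, symmetric = TRUE)
  pos <- e$values > tol * max(abs(e$values), 1)
  if (!any(pos)) return(matrix(0, nrow(m), ncol(m)))
  e$vectors[, pos, drop = FALSE] %*%
    (t(e$vectors[, pos, drop = FALSE]) / e$values[pos])
}

#' @export
print.logrank_test <- function(x, ...) {
  cat(sprintf("Log-rank test: chisq = %.4g on %d df, p = %.4g (n = %d)\n",
              x$chisq, x$df, x$p.value, x$n))
  tab <- data.frame(group = names(x$observed), observed = x$observed,
                    expected = round(x$expected, 2))
  print(tab, row.names = FALSE)
  invisible(x)
}

validate_survival_table <- function(table, need_group = FALSE) {
  if (!is.data.frame(table) || !all(c("time", "event") %in% names(table))) {
    stop("survival table needs columns `time` and `event`", call. = FALSE)
  }
  if (!is.numeric(table$time) || anyNA(table$time) ||
      any(!is.finite(table$time))) {
    stop("`time` must be finite numeric", call. = FALSE)
  }
  if (any(table$time < 0)) stop("negative survival times", call. = FALSE)
  ev <- table$event
  if (anyNA(ev) || !all(ev %in% c(0, 1))) {
    stop("`event` must be 0/1", call. = FALSE)
  }
  table$event <- as.integer(ev)
  if (need_group && !"group" %in% names(table)) {
    stop("survival table needs a `group` column", call. = FALSE)
  }
  table
}
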