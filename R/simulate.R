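#' Simulate survival data under proportional hazards
#'
#' Event times are exponential with hazard `baseline_hazard` for the
#' inactive arm and `baseline_hazard * hr` for the active arm. Censoring
#' is independent uniform administrative censoring `U(0, cmax)` with
#' `cmax` solved numerically so the expected censored fraction over the
#' two-arm mixture equals `censoring`.
#'
#' @param n_active,n_inactive Arm sizes.
#' @param hr Hazard ratio, active vs inactive.
#' @param baseline_hazard Events per month in the inactive arm; the
#'   default 0.01 puts the inactive median near 69 months, a plausible
#'   scale for breast-cancer overall survival in months.
#' @param censoring Target censored fraction in \[0, 1).
#' @param seed RNG seed.
#' @param labels Group labels (inactive, active).
#' @return Survival table (data frame `sample`, `time`, `event`,
#'   `group`).
#' @examples
#' simulate_survival(50, 50, hr = 2.5, seed = 1)
#' @export
simulate_survival <- function(n_active, n_inactive, hr = 2.5,
                              baseline_hazard = 0.01, censoring = 0.3,
                              seed,
                              labels = c("inactive", "active")) {
  n_active <- as.integer(n_active); n_inactive <- as.integer(n_inactive)
  if (n_active < 1L || n_inactive < 1L) stop("arm sizes must be >= 1", call. = FALSE)
  if (hr <= 0 || baseline_hazard <= 0) {
    stop("`hr` and `baseline_hazard` must be positive", call. = FALSE)
  }
  if (censoring < 0 || censoring >= 1) {
    stop("`censoring` must be in [0, 1)", call. = FALSE)
  }
  rates <- c(rep(baseline_hazard, n_inactive),
             rep(baseline_hazard * hr, n_active))
  group <- c(rep(labels[1L], n_inactive), rep(labels[2L], n_active))
  n <- length(rates)
  with_seed(seed, {
    t_event <- stats::rexp(n, rate = rates)
    if (censoring > 0) {
      cmax <- censoring_horizon(censoring,
                                c(baseline_hazard, baseline_hazard * hr),
                                c(n_inactive, n_active) / n)
      t_cens <- stats::runif(n, 0, cmax)
      time <- pmin(t_event, t_cens)
      event <- as.integer(t_event <= t_cens)
    } else {
      time <- t_event
      event <- rep(1L, n)
    }
    data.frame(sample = sprintf("S%04d", seq_len(n)), time = time,
               event = event, group = group, stringsAsFactors = FALSE)
  })
}

# P(censored) for T ~ Exp(lambda), C ~ U(0, cmax) is
# (1 - exp(-lambda cmax)) / (lambda cmax); solve the mixture for cmax.
censoring_horizon <- function(target, rates, weights) {
  pcens <- function(cmax) {
    sum(weights * (1 - exp(-rates * cmax)) / (rates * cmax)) - target
  }
  stats::uniroot(pcens, lower = 1e-6, upper = 1e6, tol = 1e-10)$root
}

#' Simulate an expression cohort with planted signature activity
#'
#' Generates a genes x samples log2 expression matrix in which a planted
#' "active" fraction of samples has every signature gene shifted upward
#' by `effect` log2 units, plus proportional-hazards survival keyed to
#' the active label via [simulate_survival()]. Gene baselines are drawn
#' once per gene from Normal(8, 2) (a plausible log2 microarray/RNA-seq
#' range); noise is Normal on the log2 scale.
#'
#' @param sig A [gene_signature] (its genes get the planted shift).
#' @param n_samples Cohort size.
#' @param active_fraction Fraction of samples planted as active, in
#'   (0, 1).
#' @param effect Log2-unit upward shift in active samples (>= 0).
#' @param noise_sd Residual SD on the log2 scale.
#' @param n_background_genes Unshifted genes added to the matrix.
#' @param hr,baseline_hazard,censoring Passed to [simulate_survival()].
#' @param seed RNG seed; the whole cohort is reproducible from it.
#' @return List of class `cohort_sim`: `expression` (matrix), `survival`
#'   (table with `group` = active/inactive), `active` (named logical,
#'   the planted truth), `config` (the generating parameters).
#' @examples
#' sig <- gene_signature("toy", paste0("G", 1:5))
#' sim <- simulate_cohort(sig, n_samples = 30, seed = 1)
#' @export
simulate_cohort <- function(sig, n_samples = 300, active_fraction = 1 / 3,
                            effect = 1.5, noise_sd = 0.5,
                            n_background_genes = 500, hr = 2.5,
                            baseline_hazard = 0.01, censoring = 0.3,
                            seed) {
  genes <- if (inherits(sig, "gene_signature")) sig$genes else normalize_symbols(sig)
  if (effect < 0) stop("`effect` must be >= 0", call. = FALSE)
  if (active_fraction <= 0 || active_fraction >= 1) {
    stop("`active_fraction` must be in (0, 1)", call. = FALSE)
  }
  if (noise_sd <= 0) stop("`noise_sd` must be positive", call. = FALSE)
  n_samples <- as.integer(n_samples)
  n_active <- max(1L, round(active_fraction * n_samples))
  all_genes <- c(genes, sprintf("BG%04d", seq_len(n_background_genes)))
  samples <- sprintf("P%04d", seq_len(n_samples))
  with_seed(seed, {
    active_idx <- sample.int(n_samples, n_active)
    active <- stats::setNames(rep(FALSE, n_samples), samples)
    active[active_idx] <- TRUE
    baseline <- stats::rnorm(length(all_genes), mean = 8, sd = 2)
    expr <- baseline +
      matrix(stats::rnorm(length(all_genes) * n_samples, sd = noise_sd),
             nrow = length(all_genes))
    expr[seq_along(genes), active] <- expr[seq_along(genes), active] + effect
    dimnames(expr) <- list(all_genes, samples)
    surv_seed <- sample.int(.Machine$integer.max, 1L)
    surv <- simulate_survival(n_active = n_active,
                              n_inactive = n_samples - n_active,
                              hr = hr, baseline_hazard = baseline_hazard,
                              censoring = censoring, seed = surv_seed)
    # map generated arm records onto the planted sample IDs
    surv$sample <- c(samples[!active], samples[active])
    surv <- surv[order(surv$sample), , drop = FALSE]
    rownames(surv) <- NULL
    structure(
      list(expression = expr, survival = surv, active = active,
           config = list(n_samples = n_samples,
                         active_fraction = active_fraction,
                         effect = effect, noise_sd = noise_sd,
                         n_background_genes = n_background_genes,
                         hr = hr, baseline_hazard = baseline_hazard,
                         censoring = censoring, seed = seed)),
      class = "cohort_sim"
    )
  })
}

#' @export
print.cohort_sim <- function(x, ...) {
  cfg <- x$config
  cat(sprintf(
    "Simulated cohort: %d samples (%d active), %d genes, effect %.2g log2, HR %.2g\n",
    cfg$n_samples, sum(x$active), nrow(x$expression), cfg$effect, cfg$hr))
  invisible(x)
}

#' Simulate two peak sets with planted summit co-localization
#'
#' Candidate summit slots are laid out on a grid spaced `10 * threshold`
#' bp apart inside the supplied regions, so peaks on different slots can
#' never co-localize. A planted fraction of A peaks receives a B partner
#' whose summit is jittered by a truncated Normal(0, `jitter_sd`)
#' strictly inside the threshold; the remaining B peaks and all decoys
#' occupy their own slots.
#'
#' @param n_pairs Number of A peaks (each non-planted A peak still gets a
#'   far-away B counterpart, keeping the two sets the same size).
#' @param coloc_fraction Planted co-localized fraction of A peaks.
#' @param jitter_sd SD (bp) of the summit offset for planted partners.
#' @param threshold Co-localization threshold the planting respects
#'   (offsets are kept strictly below it); default 500.
#' @param decoys_a,decoys_b Extra unpaired peaks per set.
#' @param regions Optional `region_set` to place peaks in; defaults to
#'   three 20-Mb synthetic chromosomes sized to the request.
#' @param peak_halfwidth Half-width of the peak intervals around each
#'   summit.
#' @param seed RNG seed.
#' @return List of class `peak_sim`: `a`, `b` (peak sets), `regions`,
#'   `truth` (logical: which A peaks were planted with a partner).
#' @examples
#' sim <- simulate_peak_pairs(n_pairs = 100, coloc_fraction = 0.4, seed = 1)
#' colocalize(sim$a, sim$b)$fraction_a
#' @export
simulate_peak_pairs <- function(n_pairs, coloc_fraction = 0.4,
                                jitter_sd = 100, threshold = 500L,
                                decoys_a = 0L, decoys_b = 0L,
                                regions = NULL, peak_halfwidth = 250L,
                                seed) {
  n_pairs <- as.integer(n_pairs)
  if (n_pairs < 1L) stop("`n_pairs` must be >= 1", call. = FALSE)
  if (coloc_fraction < 0 || coloc_fraction > 1) {
    stop("`coloc_fraction` must be in [0, 1]", call. = FALSE)
  }
  if (jitter_sd >= threshold) {
    stop("`jitter_sd` must be below the co-localization threshold",
         call. = FALSE)
  }
  spacing <- 10L * as.integer(threshold)
  n_slots_needed <- 2L * n_pairs + as.integer(decoys_a) + as.integer(decoys_b)
  if (is.null(regions)) {
    chrom_len <- max(20e6, ceiling(n_slots_needed / 3) * spacing * 1.2 +
                       2 * spacing)
    regions <- region_set(paste0("chr", 1:3), rep(0L, 3),
                          rep(as.integer(chrom_len), 3))
  }
  margin <- as.integer(threshold) + peak_halfwidth + 1L
  slots <- do.call(rbind, lapply(seq_len(nrow(regions)), function(i) {
    pos <- seq.int(regions$start[i] + margin, regions$end[i] - margin,
                   by = spacing)
    data.frame(chrom = regions$chrom[i], pos = pos,
               stringsAsFactors = FALSE)
  }))
  if (nrow(slots) < n_slots_needed) {
    stop(sprintf(
      "regions too small: %d summit slots available, %d needed",
      nrow(slots), n_slots_needed), call. = FALSE)
  }
  n_coloc <- round(coloc_fraction * n_pairs)
  with_seed(seed, {
    pick <- sample.int(nrow(slots), n_slots_needed)
    a_slots <- slots[pick[seq_len(n_pairs)], ]
    far_b_slots <- slots[pick[n_pairs + seq_len(n_pairs)], ]
    planted <- rep(FALSE, n_pairs)
    if (n_coloc > 0L) planted[sample.int(n_pairs, n_coloc)] <- TRUE
    # planted partners: jitter truncated strictly inside the threshold
    jit <- round(stats::rnorm(n_pairs, 0, jitter_sd))
    jit <- pmax(pmin(jit, threshold - 1L), -(threshold - 1L))
    b_chrom <- ifelse(planted, a_slots$chrom, far_b_slots$chrom)
    b_summit <- ifelse(planted, a_slots$pos + jit, far_b_slots$pos)
    mk_peaks <- function(chrom, summit, prefix, n0) {
      peak_set(chrom, summit - peak_halfwidth, summit + peak_halfwidth,
               summit = summit,
               name = sprintf("%s_%d", prefix, n0 + seq_along(summit)))
    }
    a_chrom <- a_slots$chrom; a_summit <- a_slots$pos
    used <- 2L * n_pairs
    if (decoys_a > 0L) {
      dk <- slots[pick[used + seq_len(decoys_a)], ]
      a_chrom <- c(a_chrom, dk$chrom); a_summit <- c(a_summit, dk$pos)
      used <- used + as.integer(decoys_a)
    }
    if (decoys_b > 0L) {
      dk <- slots[pick[used + seq_len(decoys_b)], ]
      b_chrom <- c(b_chrom, dk$chrom); b_summit <- c(b_summit, dk$pos)
    }
    structure(
      list(a = mk_peaks(a_chrom, as.integer(a_summit), "A", 0L),
           b = mk_peaks(b_chrom, as.integer(b_summit), "B", 0L),
           regions = regions, truth = planted,
           config = list(n_pairs = n_pairs,
                         coloc_fraction = coloc_fraction,
                         jitter_sd = jitter_sd, threshold = threshold,
                         seed = seed)),
      class = "peak_sim"
    )
  })
}

# 4PL response at arbitrary dose (dose 0 gives `bottom`).
pl4_response <- function(dose, bottom, top, ic50, hill) {
  ifelse(dose == 0, bottom,
         bottom + (top - bottom) / (1 + (ic50 / dose)^hill))
}

#' Simulate a dose matrix with planted HSA excess
#'
#' Monotherapy rows follow each drug's 4PL curve; combination cells are
#' `max(mono_a, mono_b) + delta + Normal(0, noise_sd)`, clipped to
#' \[0, 100\].
#'
#' @param params_a,params_b Named lists/vectors with `bottom`, `top`,
#'   `ic50`, `hill` for each drug.
#' @param doses_a,doses_b Dose grids including 0.
#' @param delta Planted uniform HSA excess in percentage points.
#' @param noise_sd SD of the additive noise on combination cells (0 for
#'   noise-free matrices).
#' @param seed RNG seed (required when `noise_sd > 0`).
#' @return A [dose_matrix()].
#' @examples
#' p <- list(bottom = 0, top = 80, ic50 = 1, hill = 1)
#' m <- simulate_dose_matrix(p, p, c(0, 10^(-2:2)), c(0, 10^(-2:2)),
#'                           delta = 20)
#' hsa_score(m)$score
#' @export
simulate_dose_matrix <- function(params_a, params_b,
                                 doses_a, doses_b, delta = 0,
                                 noise_sd = 0, seed = NULL) {
  pa <- as.list(params_a); pb <- as.list(params_b)
  for (p in list(pa, pb)) {
    if (!all(c("bottom", "top", "ic50", "hill") %in% names(p))) {
      stop("4PL parameters need bottom, top, ic50, hill", call. = FALSE)
    }
  }
  mono_a <- pl4_response(doses_a, pa$bottom, pa$top, pa$ic50, pa$hill)
  mono_b <- pl4_response(doses_b, pb$bottom, pb$top, pb$ic50, pb$hill)
  inh <- outer(mono_a, mono_b, pmax)
  inh[, 1L] <- mono_a
  inh[1L, ] <- mono_b
  inh[1L, 1L] <- max(pa$bottom, pb$bottom)  # untreated baseline
  comb <- outer(mono_a[-1L], mono_b[-1L], pmax) + delta
  if (noise_sd > 0) {
    if (is.null(seed)) stop("`seed` required when noise_sd > 0", call. = FALSE)
    comb <- comb + with_seed(seed, {
      matrix(stats::rnorm(length(comb), sd = noise_sd), nrow = nrow(comb))
    })
  }
  inh[-1L, -1L] <- pmin(pmax(comb, 0), 100)
  dose_matrix(doses_a, doses_b, inh)
}

#' Caliper tumor volume
#'
#' `volume = length * width^2 / 2` in mm^3. By the caliper convention the
#' width is the smaller axis; if `width > length` the two are swapped
#' before applying the formula.
#'
#' @param length,width Caliper measurements in mm (vectorized, >= 0).
#' @return Tumor volumes in mm^3.
#' @examples
#' tumor_volume(10, 5)
#' @export
tumor_volume <- function(length, width) {
  if (any(length < 0 | width < 0)) {
    stop("measurements must be non-negative", call. = FALSE)
  }
  l <- pmax(length, width)
  w <- pmin(length, width)
  l * w^2 / 2
}
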