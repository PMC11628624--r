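toy_sig <- gene_signature("toy", sprintf("SG%02d", 1:20))

test_that("simulators are reproducible from their seed", {
  s1 <- simulate_cohort(toy_sig, n_samples = 40, seed = 5,
                        n_background_genes = 30)
  s2 <- simulate_cohort(toy_sig, n_samples = 40, seed = 5,
                        n_background_genes = 30)
  expect_identical(s1$expression, s2$expression)
  expect_identical(s1$survival, s2$survival)
  expect_identical(s1$active, s2$active)
  p1 <- simulate_peak_pairs(n_pairs = 50, seed = 9)
  p2 <- simulate_peak_pairs(n_pairs = 50, seed = 9)
  expect_identical(p1$a, p2$a)
  expect_identical(p1$b, p2$b)
  m1 <- simulate_dose_matrix(list(bottom = 0, top = 80, ic50 = 1, hill = 1),
                             list(bottom = 0, top = 70, ic50 = 2, hill = 2),
                             c(0, 1, 10), c(0, 1, 10), delta = 5,
                             noise_sd = 2, seed = 11)
  m2 <- simulate_dose_matrix(list(bottom = 0, top = 80, ic50 = 1, hill = 1),
                             list(bottom = 0, top = 70, ic50 = 2, hill = 2),
                             c(0, 1, 10), c(0, 1, 10), delta = 5,
                             noise_sd = 2, seed = 11)
  expect_identical(m1$inhibition, m2$inhibition)
  # the generator does not disturb the caller's RNG stream
  set.seed(123); before <- rnorm(1)
  set.seed(123); invisible(simulate_cohort(toy_sig, n_samples = 10,
                                           seed = 5,
                                           n_background_genes = 5))
  expect_identical(rnorm(1), before)
})

test_that("simulated objects satisfy their type invariants", {
  sim <- simulate_cohort(toy_sig, n_samples = 60, seed = 13,
                         n_background_genes = 40)
  expect_false(anyDuplicated(rownames(sim$expression)) > 0)
  expect_false(anyDuplicated(colnames(sim$expression)) > 0)
  expect_true(all(is.finite(sim$expression)))
  expect_true(all(sim$survival$time >= 0))
  expect_true(all(sim$survival$event %in% 0:1))
  expect_setequal(sim$survival$sample, colnames(sim$expression))
  expect_equal(sum(sim$active), round(60 / 3))
  # active label and survival group agree
  expect_identical(unname(sim$active[sim$survival$sample]),
                   sim$survival$group == "active")
  pk <- simulate_peak_pairs(n_pairs = 100, coloc_fraction = 0.5, seed = 17,
                            decoys_a = 10, decoys_b = 5)
  expect_true(all(pk$a$summit >= pk$a$start & pk$a$summit < pk$a$end))
  expect_equal(nrow(pk$a), 110)
  expect_equal(nrow(pk$b), 105)
  expect_error(simulate_cohort(toy_sig, effect = -1, seed = 1), "effect")
  expect_error(simulate_peak_pairs(n_pairs = 1e5, seed = 1,
                                   regions = region_set("c", 0, 1e5)),
               "slots")
})

test_that("null effect leaves active and inactive scores indistinguishable", {
  sim <- simulate_cohort(toy_sig, n_samples = 500, effect = 0,
                         noise_sd = 0.5, seed = 19,
                         n_background_genes = 50)
  sc <- signature_score(sim$expression, toy_sig)$scores
  p <- wilcox.test(sc[sim$active], sc[!sim$active], exact = FALSE)$p.value
  expect_gt(p, 0.01)
})

test_that("a strong planted effect drives active samples into the HIGH tertile", {
  sim <- simulate_cohort(toy_sig, n_samples = 300, active_fraction = 1 / 3,
                         effect = 2, noise_sd = 0.5, seed = 23,
                         n_background_genes = 100)
  sc <- signature_score(sim$expression, toy_sig)
  groups <- stratify_equal_groups(sc$scores)
  recovery <- mean(groups[names(sim$active)[sim$active]] == "HIGH")
  expect_gte(recovery, 0.9)
})

test_that("planted hazard ratio is detected on true labels", {
  sim <- simulate_cohort(toy_sig, n_samples = 300, hr = 2.5, seed = 29,
                         n_background_genes = 20)
  res <- logrank_test(sim$survival)
  expect_lt(res$p.value, 0.001)
})

test_that("censoring calibration hits the requested fraction", {
  fracs <- vapply(1:20, function(s) {
    tab <- simulate_survival(250, 250, hr = 2.5, censoring = 0.3, seed = s)
    mean(tab$event == 0)
  }, numeric(1))
  expect_lt(abs(mean(fracs) - 0.3), 0.02)
  none <- simulate_survival(50, 50, censoring = 0, seed = 3)
  expect_true(all(none$event == 1))
})

test_that("full pipeline recovers a planted survival difference end to end", {
  # simulate -> score -> tertiles -> cap -> log-rank on HIGH vs LOW
  sim <- simulate_cohort(toy_sig, n_samples = 300, active_fraction = 1 / 3,
                         effect = 2, noise_sd = 0.5, hr = 2.5,
                         seed = 31, n_background_genes = 100)
  sc <- signature_score(sim$expression, toy_sig)
  groups <- stratify_equal_groups(sc$scores)
  surv <- cap_followup(sim$survival)
  surv$group <- as.character(groups[surv$sample])
  contrast <- surv[surv$group %in% c("LOW", "HIGH"), ]
  expect_lt(logrank_test(contrast)$p.value, 0.001)
})

test_that("tumor_volume applies the caliper formula with axis swap", {
  expect_equal(tumor_volume(10, 5), 125)
  expect_equal(tumor_volume(5, 10), 125)  # width > length: swapped
  expect_equal(tumor_volume(7, 0), 0)
  expect_equal(tumor_volume(c(10, 4), c(5, 4)), c(125, 32))
  expect_error(tumor_volume(-1, 5), "non-negative")
})
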