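test_that("median_dichotomize uses strict comparison against per-gene medians", {
  m <- matrix(c(1, 2, 3, 4), 1, dimnames = list("G1", paste0("S", 1:4)))
  calls <- median_dichotomize(m, "G1")$calls
  expect_equal(as.vector(calls), c(FALSE, FALSE, TRUE, TRUE))  # median 2.5
  # constant gene: ties at the median are LOW
  mc <- matrix(5, 1, 6, dimnames = list("G1", paste0("S", 1:6)))
  expect_false(any(median_dichotomize(mc, "G1")$calls))
})

test_that("median_dichotomize matches a brute-force per-cell oracle", {
  set.seed(11)
  m <- matrix(rnorm(20 * 30, 8, 2), 20, 30,
              dimnames = list(sprintf("G%02d", 1:20), sprintf("S%02d", 1:30)))
  calls <- median_dichotomize(m, rownames(m))$calls
  for (g in rownames(m)) {
    v <- sort(m[g, ])
    med <- unname((v[15] + v[16]) / 2)  # midpoint of the central order statistics
    for (s in colnames(m)) {
      expect_identical(unname(calls[g, s]), unname(m[g, s] > med))
    }
  }
})

test_that("median_dichotomize reports absent and NA genes instead of fabricating", {
  m <- matrix(rnorm(8), 2, 4,
              dimnames = list(c("G1", "G2"), paste0("S", 1:4)))
  m["G2", 2] <- NA
  d <- median_dichotomize(m, c("G1", "G2", "G3"))
  expect_equal(rownames(d$calls), "G1")
  expect_equal(d$genes_missing, "G3")
  expect_equal(d$genes_dropped, "G2")
  expect_error(median_dichotomize(m, "NOPE"), "none")
})

test_that("signature_score tallies HIGH calls and records coverage", {
  m <- rbind(G1 = 1:4, G2 = 4:1)
  colnames(m) <- paste0("S", 1:4)
  sc <- signature_score(m, gene_signature("t", c("G1", "G2", "G3")))
  # per-gene HIGH: G1 in S3,S4; G2 in S1,S2; G3 absent
  expect_equal(unname(sc$scores), c(1, 1, 1, 1))
  expect_equal(sc$coverage, 2 / 3)
  # all-identical samples score 0 under the strict-median rule
  mi <- matrix(3, 2, 5, dimnames = list(c("G1", "G2"), paste0("S", 1:5)))
  expect_true(all(signature_score(mi, c("G1", "G2"))$scores == 0))
})

test_that("signature_score is rank-invariant and bounded by signature size", {
  set.seed(13)
  m <- matrix(rnorm(15 * 40, 8, 2), 15, 40,
              dimnames = list(sprintf("G%02d", 1:15), sprintf("S%02d", 1:40)))
  sig <- gene_signature("t", rownames(m))
  sc <- signature_score(m, sig)$scores
  expect_true(all(sc >= 0 & sc <= 15))
  # monotone per-gene transformation leaves scores unchanged
  m2 <- t(apply(m, 1, function(v) exp(v / 3) + 5))
  dimnames(m2) <- dimnames(m)
  expect_identical(signature_score(m2, sig)$scores, sc)
})

test_that("stratify_equal_groups cuts into contiguous near-equal blocks", {
  s <- setNames(1:9, paste0("S", 1:9))
  g <- stratify_equal_groups(s)
  expect_equal(unname(table(g)), rep(3L, 3), ignore_attr = TRUE)
  expect_true(all(g[paste0("S", 1:3)] == "LOW"))
  expect_true(all(g[paste0("S", 7:9)] == "HIGH"))
  # n %% k != 0: larger groups at the low end
  s10 <- setNames(1:10, sprintf("S%02d", 1:10))
  expect_equal(as.vector(table(stratify_equal_groups(s10))), c(4L, 3L, 3L))
  expect_error(stratify_equal_groups(setNames(1:2, c("a", "b")), k = 3),
               "fewer")
})

test_that("stratification is deterministic under ties and input permutation", {
  set.seed(17)
  for (rep in 1:5) {
    n <- 200
    s <- setNames(sample(0:5, n, replace = TRUE), sprintf("S%03d", 1:n))
    g <- stratify_equal_groups(s)
    sizes <- table(g)
    expect_lte(max(sizes) - min(sizes), 1L)
    # permuting input order never changes the labels
    perm <- sample(n)
    expect_identical(stratify_equal_groups(s[perm])[names(s)], g)
    # labels non-decreasing in score after the (score, ID) tie-break
    ord <- order(s, names(s), method = "radix")
    expect_true(!is.unsorted(as.integer(g[ord])))
  }
})

test_that("quantile_dichotomize labels floor(q*n) samples per tail", {
  v <- setNames(1:9, paste0("S", 1:9))
  g <- quantile_dichotomize(v)
  expect_true(all(g[paste0("S", 1:3)] == "LOW"))
  expect_true(all(g[paste0("S", 4:6)] == "EXCLUDED"))
  expect_true(all(g[paste0("S", 7:9)] == "HIGH"))
  g3 <- quantile_dichotomize(setNames(c(3, 1, 2), c("a", "b", "c")))
  expect_equal(as.vector(table(g3)), c(1L, 1L, 1L))
  expect_error(quantile_dichotomize(setNames(1:2, c("a", "b"))), "3 samples")
})

test_that("quantile_dichotomize keeps tails disjoint with duplicate values", {
  set.seed(19)
  for (n in c(7, 30, 101)) {
    v <- setNames(sample(1:4, n, replace = TRUE), sprintf("S%03d", 1:n))
    g <- quantile_dichotomize(v, q = 1 / 3)
    m <- floor(n / 3)
    expect_equal(sum(g == "LOW"), m)
    expect_equal(sum(g == "HIGH"), m)
    expect_equal(sum(g == "EXCLUDED"), n - 2 * m)
    # every LOW value <= every HIGH value
    expect_lte(max(v[g == "LOW"]), min(v[g == "HIGH"]))
  }
})

test_that("cross_stratify combines extreme labels and drops intermediates", {
  samples <- sprintf("S%02d", 1:12)
  a <- factor(rep(c("LOW", "INT", "HIGH"), each = 4),
              levels = c("LOW", "INT", "HIGH"))
  b <- factor(rep(c("LOW", "EXCLUDED", "HIGH"), times = 4),
              levels = c("LOW", "EXCLUDED", "HIGH"))
  names(a) <- names(b) <- samples
  g <- cross_stratify(a, b, prefixes = c("NOTCH", "SOX2"))
  expect_setequal(attr(g, "dropped"),
                  samples[a == "INT" | b == "EXCLUDED"])
  expect_equal(unname(g["S01"]),
               factor("NOTCH_LOW/SOX2_LOW", levels = levels(g)))
  # counts equal a brute-force cross-tabulation over kept samples
  keep <- a %in% c("LOW", "HIGH") & b %in% c("LOW", "HIGH")
  tab <- table(droplevels(a[keep]), droplevels(b[keep]))
  for (la in c("LOW", "HIGH")) for (lb in c("LOW", "HIGH")) {
    expect_equal(sum(g == sprintf("NOTCH_%s/SOX2_%s", la, lb)),
                 unname(tab[la, lb]))
  }
  expect_error(cross_stratify(a, b[-1]), "same samples")
})

test_that("classify_notch_alteration applies the missense / cna==2 rule", {
  tab <- data.frame(
    sample = c("P1", "P2", "P2", "P3", "P4"),
    gene = c("NOTCH2", "NOTCH3", "NOTCH1", "TP53", "NOTCH4"),
    missense = c(TRUE, FALSE, TRUE, TRUE, FALSE),
    cna = c(NA, 2L, NA, 2L, 1L))
  cls <- classify_notch_alteration(tab)
  expect_equal(unname(cls["P1"]), factor("mutated", levels = levels(cls)))
  expect_equal(as.character(cls["P2"]), "mutated+amplified")
  expect_equal(as.character(cls["P3"]), "none")  # TP53 records ignored
  expect_equal(as.character(cls["P4"]), "none")  # cna 1 is not amplification
  bad <- data.frame(sample = "P1", gene = "NOTCH1", missense = FALSE,
                    cna = 5L)
  expect_error(classify_notch_alteration(bad), "cna")
})
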