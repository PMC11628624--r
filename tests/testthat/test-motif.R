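# A PWM with one dominant base per column scores its consensus at the
# maximum attainable score.
consensus_pwm <- function(consensus, weight = 100) {
  k <- nchar(consensus)
  counts <- matrix(0, 4, k, dimnames = list(c("A", "C", "G", "T"), NULL))
  idx <- match(strsplit(consensus, "")[[1]], rownames(counts))
  counts[cbind(idx, seq_len(k))] <- weight
  pwm_from_counts(counts, id = consensus)
}

test_that("read_pfm parses JASPAR bracketed and bare layouts", {
  tmp <- withr::local_tempfile(fileext = ".pfm")
  writeLines(c(">MA0442.1 SOX2",
               "A [ 10  0  2  0  8  1 ]",
               "C [  0 12  0  0  1  1 ]",
               "G [  1  0  9  0  2  1 ]",
               "T [  1  0  1 12  1  9 ]"), tmp)
  counts <- read_pfm(tmp)
  expect_equal(dim(counts), c(4L, 6L))
  expect_equal(attr(counts, "id"), "MA0442.1")
  expect_equal(unname(counts["C", 2]), 12)
  tmp2 <- withr::local_tempfile(fileext = ".pfm")
  writeLines(c("10 0 2 0", "0 12 0 0", "1 0 9 0", "1 0 1 12"), tmp2)
  expect_equal(dim(read_pfm(tmp2)), c(4L, 4L))
  tmp3 <- withr::local_tempfile(fileext = ".pfm")
  writeLines(c("1 2", "3 x", "5 6", "7 8"), tmp3)
  expect_error(read_pfm(tmp3), "non-numeric")
})

test_that("pwm_from_counts produces finite log-odds matching a hand computation", {
  counts <- matrix(c(10, 0, 0, 0), 4, 6,
                   dimnames = list(c("A", "C", "G", "T"), NULL))
  pwm <- pwm_from_counts(counts, pseudocount = 0.8)
  expect_true(all(is.finite(pwm$mat)))
  # hand: column count A=10 + 0.8*0.25 = 10.2 of 10.8 total -> log2((10.2/10.8)/0.25)
  expect_equal(unname(pwm$mat["A", 1]), log2((10 + 0.2) / (10 + 0.8) / 0.25),
               tolerance = 1e-12)
  expect_equal(unname(pwm$mat["C", 1]), log2(0.2 / 10.8 / 0.25), tolerance = 1e-12)
  expect_equal(pwm$max_score, sum(apply(pwm$mat, 2, max)))
})

test_that("pwm_scan finds a planted consensus on the expected strand", {
  pwm <- consensus_pwm("ACGTAC")
  hits <- pwm_scan("TTTACGTACTTT", pwm, threshold_frac = 1)
  expect_equal(nrow(hits), 1L)
  expect_equal(hits$start, 3L)
  expect_equal(hits$end, 9L)
  expect_equal(hits$strand, "+")
  # consensus present only as reverse complement -> one minus-strand hit
  rc_seq <- paste0("GG", oracle_revcomp("ACGTAC"), "GGGG")
  hits_rc <- pwm_scan(rc_seq, pwm, threshold_frac = 1)
  expect_equal(nrow(hits_rc), 1L)
  expect_equal(hits_rc$strand, "-")
  expect_equal(hits_rc$start, 2L)
  # sequence shorter than the motif -> empty result
  expect_equal(nrow(pwm_scan("ACG", pwm)), 0L)
  # windows containing N are skipped: no reported window may cover the N
  seq_n <- "TTTACGNACTTT"
  hits_n <- pwm_scan(seq_n, pwm, threshold_frac = 0.01)
  n_pos <- as.integer(regexpr("N", seq_n)) - 1L  # 0-based
  expect_true(all(hits_n$start > n_pos | hits_n$end <= n_pos))
})

test_that("pwm_scan equals exhaustive per-window rescoring on random sequences", {
  set.seed(59)
  tmp <- withr::local_tempfile(fileext = ".pfm")
  writeLines(c(">TEST", "8 2 0 5 1 9 0 3", "1 5 0 2 6 0 1 3",
               "1 2 9 2 1 0 8 3", "0 1 1 1 2 1 1 1"), tmp)
  pwm <- pwm_from_counts(read_pfm(tmp))
  for (rep in 1:3) {
    seq_chr <- random_dna(2000, p_n = 0.01)
    hits <- pwm_scan(seq_chr, pwm, threshold_frac = 0.8)
    thr <- 0.8 * pwm$max_score
    fwd <- oracle_scan_strand(seq_chr, pwm$mat)
    fwd <- fwd[fwd$score >= thr, , drop = FALSE]
    rc <- oracle_scan_strand(oracle_revcomp(seq_chr), pwm$mat)
    rc <- rc[rc$score >= thr, , drop = FALSE]
    rc$start <- nchar(seq_chr) - rc$start - ncol(pwm$mat)
    expect_equal(nrow(hits), nrow(fwd) + nrow(rc))
    got_f <- hits[hits$strand == "+", ]
    expect_equal(got_f$start, sort(fwd$start))
    expect_equal(got_f$score[order(got_f$start)],
                 fwd$score[order(fwd$start)], tolerance = 1e-12)
    got_r <- hits[hits$strand == "-", ]
    expect_setequal(got_r$start, rc$start)
  }
})

test_that("forward scores are invariant under revcomp plus strand swap", {
  set.seed(61)
  pwm <- consensus_pwm("ACGGT")
  seq_chr <- random_dna(500)
  fwd <- pwm_scan(seq_chr, pwm, threshold_frac = 0.7, strands = "+")
  swapped <- pwm_scan(oracle_revcomp(seq_chr), pwm, threshold_frac = 0.7,
                      strands = "-")
  # minus-strand hits on the reverse complement cover the same windows,
  # with positions mapped by start' = L - start - k
  k <- 5L
  mapped <- nchar(seq_chr) - swapped$start - k
  expect_equal(sort(fwd$start), sort(mapped))
  expect_equal(fwd$score[order(fwd$start)],
               swapped$score[order(mapped)], tolerance = 1e-12)
})

test_that("pair_motif_cooccurrence counts pairs with both motifs in the footprint", {
  a <- peak_set(rep("chr1", 3), c(1000, 5000, 9000), c(1500, 5500, 9500))
  b <- peak_set(rep("chr1", 3), c(1100, 5100, 9100), c(1600, 5600, 9600))
  coloc <- colocalize(a, b, 500)
  expect_equal(coloc$fraction_a, 1)
  hit <- function(starts) {
    data.frame(chrom = rep("chr1", length(starts)), start = starts,
               end = starts + 6, strand = rep("+", length(starts)),
               score = rep(10, length(starts)))
  }
  # both motifs in pair 1 footprint; only motif a in pair 2; none in pair 3
  res <- pair_motif_cooccurrence(coloc, a, b,
                                 hits_a = hit(c(1200, 5200)),
                                 hits_b = hit(1550))
  expect_equal(res$n_pairs, 3L)
  expect_equal(res$n_both, 1L)
  expect_equal(res$fraction, 1 / 3)
  # full coverage -> fraction 1; empty hits -> fraction 0
  all_hits <- hit(c(1200, 5200, 9200))
  expect_equal(pair_motif_cooccurrence(coloc, a, b, all_hits,
                                       all_hits)$fraction, 1)
  expect_equal(pair_motif_cooccurrence(coloc, a, b, hit(numeric(0)),
                                       all_hits)$fraction, 0)
})

test_that("planted motif co-occurrence fraction is recovered at scale", {
  set.seed(67)
  n <- 1000
  sim <- simulate_peak_pairs(n_pairs = n, coloc_fraction = 1,
                             jitter_sd = 50, seed = 71)
  coloc <- colocalize(sim$a, sim$b, 500)
  expect_equal(nrow(coloc$pairs), n)
  planted <- runif(n) < 0.6
  mk_hits <- function(idx) {
    data.frame(chrom = sim$a$chrom[idx],
               start = sim$a$summit[idx] - 3L,
               end = sim$a$summit[idx] + 3L,
               strand = "+", score = 10)
  }
  res <- pair_motif_cooccurrence(coloc, sim$a, sim$b,
                                 mk_hits(which(planted)),
                                 mk_hits(which(planted)))
  expect_lt(abs(res$fraction - mean(planted)), 0.03)
})
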