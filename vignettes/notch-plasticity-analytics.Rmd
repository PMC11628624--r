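---
title: "Quantitative methods for NOTCH activity scoring, survival contrasts, peak co-localization and drug synergy"
author: "tnbcnotch authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantitative methods for NOTCH activity scoring, survival contrasts, peak co-localization and drug synergy}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tnbcnotch)
```

# Scope

Triple-negative breast cancer (TNBC) tumors can toggle between a
Notch-driven state and a SOX2-high, stem-like state, and the balance
between the two carries prognostic and therapeutic weight. `tnbcnotch`
implements the quantitative backbone such a study needs: curating a
Notch-activity gene signature from differential-expression evidence,
scoring and stratifying patient cohorts with it, contrasting survival
between strata, quantifying ChIP-seq summit co-localization between two
transcription factors against a resampled enhancer background, scanning
co-localized regions for binding-site motifs, and scoring drug-combination
synergy from dose matrices. A synthetic-data generator with planted,
known effects makes every one of these stages testable without any
external download.

# Signature curation

A signature is curated in three steps from differential-expression (DE)
tables: (i) per cell line, genes passing a fold-change threshold in a
GSI-washout (signal withdrawal) experiment are selected and the union is
taken across cell lines; (ii) that union is intersected with the genes
responding in a NOTCH1-ICD gain-of-function experiment (fold-change plus
adjusted-p filter); (iii) the intersection is merged with a manually
curated list of canonical Notch targets. `select_regulated_genes()`
implements the thresholding, `curate_signature()` the set algebra, and the
result records per gene which rule admitted it.

Two conventions here were genuinely open and are our choices:

* **"Fold-change threshold of 1" is read on the log2 scale**
  (`|log2FC| >= 1`, i.e. two-fold). A threshold of 1 on the linear scale
  would select every gene and is vacuous; the DE pipelines this kind of
  table comes from report log2 fold changes.
* **Direction defaults to up-regulation** (`direction = "up"`), because
  washout- and ICD-induced genes are what define the Notch-ON state; both
  directions are available via `direction = "both"`.
* The washout step applies **no adjusted-p filter** unless one is given:
  `padj_max = NULL` filters on fold change only, and requesting a padj
  filter on a table without the column is an error rather than a silent
  skip.

Symbols are uppercased and whitespace-stripped before any comparison; no
alias or identifier mapping is attempted — a requested gene absent from a
matrix is reported as missing, never guessed.

The packaged signature `TNBC_NOTCH_77` (77 genes, `ACTBL2` … `ZNF750`)
ships as a plain text file, one symbol per line with `#` provenance
headers, and `load_packaged_signature()` validates its length on load.

# Cohort scoring and stratification

Scoring is deliberately rank-based and parameter-free:

1. `median_dichotomize()` calls each signature gene HIGH in a sample when
   its expression is **strictly greater** than that gene's median across
   the cohort being scored. The strict inequality means ties at the median
   are LOW, bounding the HIGH fraction per gene at 50% — relevant for
   discretized or low-complexity data. Medians are always computed within
   the scored cohort; there is no external reference distribution.
2. `signature_score()` tallies HIGH calls per sample. Because only ranks
   enter, the score is invariant under any monotone per-gene
   transformation — log-scale conventions or quantile normalizations do
   not move it. Genes with any missing value are dropped (and reported)
   rather than imputed; the `coverage` field makes the effective signature
   size visible.
3. `stratify_equal_groups()` cuts the cohort into k contiguous,
   near-equal blocks by score (default k = 3: LOW / INT / HIGH). "Equally
   sized" cannot be exact when `n %% k != 0`; the remainder goes to the
   lowest blocks, and ties are broken by sample ID so the labeling is a
   pure function of the data, independent of input order.
4. `quantile_dichotomize()` implements the single-gene 33%-tails cut
   (e.g. SOX2): `floor(q*n)` samples per tail, middle excluded. Floor was
   chosen over interpolation so both tails are exactly equal in size and
   never overlap, whatever the tie structure.
5. `cross_stratify()` combines a tertile labeling with a tails labeling
   into four extreme groups (e.g. NOTCH_HIGH/SOX2_LOW), dropping and
   reporting intermediate samples.

`classify_notch_alteration()` applies the genetic rule: a patient is
*mutated* when any of NOTCH1–4 carries a missense mutation and
*amplified* when any carries copy-number code 2 (high-level
amplification); the flags are independent.

# Survival analysis

The estimator and test are implemented from first principles (and checked
in the test suite against both brute-force oracles and the `survival`
package):

* `cap_followup()` administratively censors records **strictly beyond**
  the cap (default 120 months). An event exactly at the cap is kept as an
  event — the convention is not dictated by the capping idea itself, so
  we chose the variant that discards no observed information.
* `km_estimate()` is the product-limit estimator with simultaneous
  handling of tied events; censorings at an event time count as at risk
  through that time (right-continuous convention); censor-only times do
  not move the curve.
* `logrank_test()` is the k-sample log-rank: per distinct event time, the
  observed event vector is compared with its hypergeometric expectation,
  covariances accumulate, and the statistic is the quadratic form on k−1
  groups (algebraically equal to the scalar `(O−E)²/V` for k = 2, which
  the tests verify to 1e-9). Risk sets of size 1 contribute no variance.
  p-values are upper chi-square tails with k−1 df, no continuity
  correction. A singular covariance (e.g. groups with disjoint risk
  windows) falls back to a symmetric generalized inverse.

# Peak co-localization

Two summits co-localize when they lie on the same chromosome strictly
closer than `max_dist` bp (default 500; "less than" is taken literally,
so 500 exactly does not co-localize). `nearest_summit_distance()` uses
per-chromosome sorted summit vectors and binary search, and the tests
prove it identical to a quadratic all-pairs scan. Fractions are computed
independently in both directions (A against B and B against A), matching
the asymmetry of reported overlap percentages.

The null model is resampling: `sample_background_positions()` draws
positions uniformly over the concatenated base-pair space of a region set
(length-weighted region choice, then uniform offset), and
`coloc_enrichment_test()` compares co-localized proportions by a Fisher
exact test. The two-sided p-value uses the probability-mass definition —
the total probability of all tables (fixed margins) no more probable than
the observed one — which is what mainstream statistical software reports;
the test suite verifies exact agreement with full enumeration for every
table with margins up to 30.

narrowPeak input takes the summit from column 10 (offset from start); a
missing summit (−1) and BED6/BED3 input fall back to the interval
midpoint (floor). All coordinates are 0-based half-open internally.

## Motif scanning

`pwm_scan()` is a minimal position-weight-matrix scanner: JASPAR-style
counts plus a pseudocount of 0.8 distributed by the background
frequencies give per-column probabilities, scored as log2 odds against
the background. Every window (both strands; reverse-strand hits mapped
back to forward coordinates) scoring at least `threshold_frac` × the
maximum attainable score is reported; windows containing N are skipped.
The threshold is deliberately score-fraction based: no p-value
calibration of motif hits is attempted, so hit counts are comparable
between motifs only through their own score scales.
`pair_motif_cooccurrence()` then asks, per co-localized pair, whether at
least one hit of each motif overlaps the union footprint of the two
partner peak intervals — the window definition was open, and the union
footprint is the least arbitrary choice that uses both peaks.

# Drug-response analytics

* `zprime()` is the standard screening-window factor
  `1 − 3(σ₊+σ₋)/|μ₊−μ₋|` with sample (n−1) standard deviations; > 0.5
  is the usual bar for an excellent assay.
* `fit_4pl()` fits `response = bottom + (top−bottom)/(1+(IC50/dose)^hill)`
  by bounded least squares (Levenberg–Marquardt via `minpack.lm`), with
  the IC50 on the log scale internally, multi-start initialization over a
  hill × IC50 grid, and box constraints (bottom ∈ [−20, 50], top ∈
  [50, 120], hill ∈ (0, 10], IC50 within 100× the tested range) that keep
  the optimizer out of degenerate corners. Constant responses return
  `converged = FALSE` instead of raising. `hill_filter()` applies the
  strict plausibility bounds 0.5 < hill < 5.
* `hsa_score()` computes, per combination cell (both doses > 0), the
  excess of the measured inhibition over the **highest single agent** at
  the same doses, and summarizes as the arithmetic mean excess in
  percentage points. The mean (over combination cells only) is the
  convention of common synergy software; published HSA scores do not
  always state their aggregation, so scores from other tools should be
  compared qualitatively unless their definition is known to match.

# The synthetic-data generator

The generator plants known effects so recovery can be measured:

* `simulate_cohort()` — genes × samples log2 expression with per-gene
  baselines from Normal(8, 2) (a plausible log2 microarray/RNA-seq
  range), Normal noise on the log2 scale (default sd 0.5), and a planted
  active fraction (default 1/3, echoing the tertile design) whose
  signature genes are shifted up by a fixed effect (default 1.5 log2
  units). Survival is exponential (constant hazard) keyed to the active
  label by a hazard ratio (default 2.5); the baseline hazard 0.01/month
  puts the inactive median near 69 months, a realistic scale for overall
  survival in months.
* Censoring is independent uniform administrative censoring `U(0, c)`,
  with `c` solved numerically (via `uniroot` on the closed-form censoring
  probability of the exponential–uniform pair, mixed over arms) so the
  expected censored fraction equals the requested one (default 30%).
* `simulate_peak_pairs()` — summit slots on a grid spaced 10× the
  co-localization threshold apart, so only planted partners can
  co-localize; a planted fraction of A peaks gets a B partner whose
  summit offset is Normal(0, jitter) truncated strictly inside the
  threshold. The planted fraction is therefore recovered exactly up to
  rounding, and decoys dilute it in a controlled way.
* `simulate_dose_matrix()` — monotherapy rows from each drug's 4PL curve,
  combination cells `max(monoA, monoB) + δ + noise`, clipped to [0, 100].
  With the default curves (top = 80) a planted δ of 20 is recovered
  exactly in the noise-free case because clipping never binds.
* `tumor_volume()` — the caliper formula `length × width² / 2`, with the
  axes swapped when width exceeds length (caliper convention: width is
  the smaller axis).

Every generator takes an explicit seed, restores the caller's RNG state,
and attaches its configuration to the output.

**What the generator does not emulate** — and hence what passing tests do
*not* show about real data: real cohorts have correlated genes, batch
structure and non-Normal marginals; real hazards are rarely constant and
censoring is rarely administrative-uniform; real peak sets have width and
score distributions tied to read depth, and co-localization is not a
clean two-population mixture; real dose matrices have plate effects and
edge artifacts. The generator demonstrates *correctness of the
procedures under their own assumptions*, not robustness to everything
real data does.

# Problem sizes and numerical choices

The test suite and the acceptance script use problem sizes at which every
statistical property is measurable with comfortable margins while the
whole suite stays fast: cohorts of 300 samples (500 background genes),
200 replicates of 150-per-arm survival simulations for power/size, 2000
peak pairs for co-localization recovery, the full enumeration sweep of
2×2 tables with margins ≤ 30 for Fisher exactness, 50 noisy replicates
for HSA recovery, and 2-kb sequences for scanner/oracle equivalence.
Tolerances follow the quantity: 1e-9 where two algebraically equal
formulations are compared, binomial-width bands (±0.03 at n = 2000;
±1 point over 50 replicates) where sampling noise is the only source of
error.

Tie-breaks are deterministic everywhere (sample ID in stratification,
leftward summit at equidistant neighbors), so every labeled output is a
pure function of the input data.

# Known limitations

* No Cox regression, competing risks, or confidence bands — the survival
  module covers exactly KM and log-rank.
* The PWM scanner has no p/q-value machinery; thresholds are score
  fractions.
* No normalization, batch correction, or cross-platform harmonization:
  expression input is taken as already log2-scale and comparable across
  samples.
* Synergy is HSA-only (no Bliss/Loewe/ZIP), and the HSA summary is the
  mean per-cell excess as defined above.
* No network clients: cohort or ChIP data from public portals must be
  exported to the supported plain-text formats by the user.
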