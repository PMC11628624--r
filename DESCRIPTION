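Package: tnbcnotch
Title: NOTCH Signature Scoring, Survival, Peak Co-Localization and Drug
    Synergy Analytics for Triple-Negative Breast Cancer
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantitative toolkit for studies of Notch-pathway activity and
    plasticity in triple-negative breast cancer. Curates gene signatures from
    differential-expression tables and ships a packaged 77-gene NOTCH
    signature; scores patients by median dichotomization and HIGH-call
    tallying; stratifies cohorts into equal tertiles and cross-stratifies
    against single-gene expression cuts; classifies NOTCH1-4 genetic
    alterations; caps follow-up, estimates Kaplan-Meier curves and runs
    k-sample log-rank tests from first principles; computes ChIP-seq
    summit-distance co-localization with resampled enhancer backgrounds,
    Fisher exact enrichment and position-weight-matrix motif co-occurrence;
    scores dose-matrix drug synergy under the highest-single-agent model with
    Z'-factor plate QC and four-parameter logistic dose-response fitting; and
    simulates cohorts, peak sets and dose matrices with planted effects so
    every stage is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    minpack.lm
Suggests:
    testthat (>= 3.0.0),
    survival,
    jsonlite,
    withr
Config/testthat/edition: 3
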