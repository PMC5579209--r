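Package: gravistab
Title: Gene Expression Stability Screening Across Gravity Research Platforms
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for screening bulk expression data for transcripts whose
    expression is stable across altered-gravity conditions, as measured on the
    three Earth-based microgravity research platforms (parabolic flight,
    suborbital ballistic rocket, and 2D clinostat/centrifuge ground
    facilities). Implements quantile normalization of log2 intensity
    matrices, an equivalence-style stability screen combining a fold-change
    band (|FC| <= 1.1) with one-way ANOVA and Tukey multiple-comparison
    tests, fold-change bin censuses (stable / minimal / changed at the
    +/-1.3 threshold), per-platform and cross-platform stable-set
    intersections, reference-gene stability ranking by the geNorm,
    NormFinder, BestKeeper and comparative delta-Ct algorithms with a
    geometric-mean consensus, and cytogenetic-band stability enrichment.
    A synthetic multi-platform data generator with known ground truth makes
    every stage testable without microarray downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    limma
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
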