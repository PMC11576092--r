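Package: geomet
Title: Geometric Summary Statistics and Reproducibility Analysis for
    Postprandial Metabolite Time Courses
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Log-scale descriptive statistics for serum metabolite
    concentrations (geometric mean, geometric standard deviation, geometric
    standard error and geometric compatibility intervals), ratio-to-baseline
    relative-change time courses, within-person reproducibility via the
    two-way random-effects absolute-agreement intraclass correlation
    (no-interaction model), limit-of-detection LOD/2 substitution, and
    accuracy-in-parameter-estimation (AIPE) precision-based sample-size
    planning. Includes a seeded lognormal trajectory simulator that emulates
    a single-meal postprandial study design (one pre-meal baseline draw plus
    thirteen post-meal timepoints out to 24 h) with known ground-truth
    response curves, so the full pipeline is testable end to end without
    external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    tibble,
    readr,
    rlang,
    stats,
    withr,
    jsonlite,
    optparse
Suggests:
    testthat (>= 3.0.0),
    ggplot2
Config/testthat/edition: 3
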