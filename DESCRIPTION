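Package: fcnf
Title: Dynamic Functional-Connectivity Neurofeedback Simulation and Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for closed-loop functional-connectivity neurofeedback
    (fc-NF) studies: block-design run schedules with per-volume window
    bookkeeping, a moving-window partial-correlation engine with three
    thermometer feedback mappings, a synthetic ROI time-series and cohort
    generator, subject-level connectivity metrics (initial fc, practice
    slope, fc-NF-effect, position profiles), group statistics (Fisher
    r-to-z comparison of correlations, bootstrapped-Mahalanobis
    multivariate outlier removal), and a mean-centered three-way
    moderation model with simple-slopes decomposition.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    jsonlite,
    readr,
    rlang,
    stats,
    tibble,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
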