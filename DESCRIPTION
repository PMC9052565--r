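Package: crpcnet
Title: Stability-Selected Partial-Correlation Networks and Survival
    Subgroups for Synthetic CRPC Cohorts
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: Simulates patient-level castration-resistant prostate cancer
    (CRPC) cohorts with a known (planted) dependency structure --
    Weibull proportional-hazards survival outcomes under one-year
    administrative censoring, dose- and exposure-driven adverse events,
    and PSA response -- and analyses them with a graphical-Markov
    workflow: Fisher-z partial-correlation conditional independence
    tests, PC-style skeleton estimation with a ridge fallback for
    ill-conditioned correlation submatrices, stability selection over
    resampled or re-simulated iterations, consensus community detection
    across seven classical graph-clustering algorithms, and confirmatory
    Kaplan-Meier / Cox subgroup analysis. Edge recovery can be scored
    against the planted ground truth.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    stats,
    survival,
    utils
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
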