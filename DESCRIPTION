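Package: erpdyn
Title: Time-Resolved ERP State-Space Dynamics for Auditory Oddball EEG
Version: 0.1.0
Authors@R: person("erpdyn", "maintainers", email = "erpdyn@example.org",
    role = c("aut", "cre"))
Description: Analysis pipeline for time-resolved event-related potential (ERP)
    dynamics in auditory oddball paradigms: epoch-level preprocessing,
    N200/P300 quantification, windowed scalp-topography correlation analysis,
    trajectory geometry in a two-dimensional PCA state space with bootstrap
    pseudo-population inference, data-driven dominant topographic states,
    microstate-style state sequences and transition matrices, linear-SVM
    subtype classification with shuffle nulls, and the accompanying
    nonparametric statistics (Kruskal-Wallis, Dunn-Sidak, Benjamini-Hochberg
    FDR, partial correlation, chi-square, noncentral-F power analysis).
    Includes a synthetic-cohort generator with planted topographic templates
    so the full pipeline is testable without clinical recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    optparse
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
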