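Package: smfe
Title: Single-Sample Markov Flow Entropy for Critical-State Detection
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects the pre-disease (critical) state of a biological system
    from a single case sample and a reference cohort using single-sample
    Markov flow entropy (sMFE), a per-gene network-entropy score computed on
    a directed gene-interaction network. Provides tools to build
    confidence-filtered directed networks from STRING-style scored edge
    lists, score case samples against a reference cohort, call the tipping
    point across ordered disease stages, screen signaling genes for
    optimistic and pessimistic prognostic biomarkers by Kaplan-Meier
    log-rank analysis, and simulate dynamic-network-biomarker structured
    expression cohorts with linked survival data for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    MASS,
    purrr,
    readr,
    rlang,
    stats,
    survival,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
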