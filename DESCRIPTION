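Package: sdbdetect
Title: Two-Stage LSTM Detection of Sleep Apnea and Hypopnea Episodes in
    Respiratory Polygraphy Signals
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects and classifies sleep-disordered-breathing episodes
    (apnea versus hypopnea) in three-channel respiratory polygraphy
    recordings (oronasal airflow, thoracic and abdominal respiratory
    effort). Implements the full processing chain: energy-based record
    quality screening, signal scaling, zero-phase Butterworth filtering and
    inter-channel phase alignment; a first LSTM stage labelling windows as
    normal breathing, apnea or hypopnea onset; a minimal-energy breath
    signal and a second LSTM stage producing a normal/apnea/hypopnea
    probability timeline; and a postprocessing stage that extracts episodes,
    scores their certainty, optimizes class thresholds against validation
    AI/HI indices and marks additional low-normal-probability events.
    Includes a seeded synthetic polygraphy simulator, respiratory event
    index (REI) estimation with severity classes, epoch-based confusion
    matrix evaluation, and wake-period exclusion analysis. The LSTM networks
    are implemented in compiled code with no external deep-learning
    dependency.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    signal,
    stats,
    tools,
    utils,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
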