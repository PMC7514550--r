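Package: hrvdyn
Title: Symbolic Dynamics and Machine-Learning Analysis of Heart Rate Variability
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing beat-to-beat heart-rate dynamics from
    RR-interval (tachogram) recordings. Implements quantized
    acceleration/deceleration pattern spaces and their Shannon entropies,
    the transition-rate entropy and self-transfer entropy, heart-rate
    fragmentation indices (PIP, PAS, PSS) and partial pattern entropies,
    alongside standard time-domain, Poincare and Lomb-Scargle
    frequency-domain measures. Provides shuffle-surrogate validation,
    cohort feature tables, correlation graphs, exploratory factor
    analysis, support-vector-machine age-decade classification with
    posterior probabilities, per-feature age regression with
    distributional screening, and a synthetic nocturnal RR-cohort
    generator for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    purrr,
    rlang,
    readr,
    ggplot2,
    generics,
    igraph,
    e1071,
    car,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
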