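Package: contactmem
Title: Social-Contact Need Probabilities and Forgetting-Curve Model Comparison
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for a rational analysis of social contact and memory in
    fission-fusion societies. Builds ternary dyad-by-day contact matrices
    (contact / no contact / missing) from scan-sampling observations and
    community-membership intervals, estimates need probabilities - the
    probability that a pair will be in contact again - as a function of the
    frequency and the recency of past contact using moving windows with
    controlled missingness and Wilson binomial confidence intervals, fits and
    compares linear, power, and exponential curves by binomial maximum
    likelihood with small-sample corrected AIC (AICc) and Akaike weights, fits
    forgetting functions to delayed matching-to-sample retention data, and
    computes ACT-R base-level activation from encounter histories. A synthetic
    data module simulates fission-fusion subgroup dynamics, recency-dependent
    contact hazards, scan sampling with imperfect detection, missingness, and
    binomially noisy retention data so that every stage of the pipeline can be
    exercised and validated without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    jsonlite,
    rlang,
    stats,
    tibble,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
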