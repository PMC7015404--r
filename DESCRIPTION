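Package: synkit
Title: Muscle Synergy Extraction and Pre/Post-Treatment EMG Reconstruction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for muscle synergy analysis of multi-channel surface EMG
    recorded during walking. Implements the standard envelope pipeline
    (high-pass filtering, rectification, low-pass filtering, stride
    time-normalisation and unit-variance channel scaling), non-negative matrix
    factorisation with multiplicative updates and random restarts, bootstrap
    selection of the number of synergies from the variance-accounted-for (VAF)
    distribution, non-negative least-squares reconstruction of target EMG under
    fixed synergy weights (activation optimisation) or fixed activation
    profiles (weight optimisation), generic cohort-level synergies, and derived
    metrics (GOOD, SPEC, IMP, synergy matching, dW, dH). A seeded synthetic-EMG
    generator with known ground-truth synergies supports end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    ggplot2,
    generics,
    jsonlite,
    pracma,
    purrr,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
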