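Package: mimicmatch
Title: Quantifying Avian Vocal Mimicry with Speech-Processing Features
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: An automated pipeline for quantifying vocal mimicry: synthesizes
    seeded libraries of bird-like calls in five spectral-signature classes
    (frequency-modulated sweeps, trills, narrowband trills, harmonic stacks,
    broadband bursts), extracts mel-frequency cepstral coefficients (39-dim),
    line spectral frequencies and RASTA-filtered perceptual linear prediction
    cepstral coefficients (12-dim) from short-time spectra, ranks candidate
    model calls under five similarity measures (Jaccard, correlation, cosine
    angle, city-block, Euclidean), scores matching accuracy under rank-based
    criteria, and compares matching methods with a two-sample proportion test
    using Yates' continuity correction.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
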