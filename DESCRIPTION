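Package: reprecon
Title: Reverse Correlation in Deep Feature Space for Reconstructing
    Conceptual Representations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Generalizes the reverse-correlation paradigm from pixel noise to
    the channel space of a differentiable image-feature extractor. Fits a
    whitened density model of a feature space and draws pseudo-random target
    feature vectors from it; synthesizes feature-noise stimuli and caricature
    reconstructions by optimizing Fourier-parameterized images; maps
    open-ended verbal responses into a word-embedding space and estimates an
    outer-product visual-semantic matrix linking the two spaces; and provides
    permutation max-statistic inference, bootstrap confidence intervals,
    representational similarity analysis, prediction and validation
    statistics, plus a synthetic-world simulator for parameter-recovery
    testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    Matrix,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    vegan,
    png,
    optparse
Config/testthat/edition: 3
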