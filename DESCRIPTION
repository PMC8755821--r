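Package: vispop
Title: Single-Unit and Population Analysis of Avian Visual Forebrain Recordings
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and analysis tools for single-unit recordings from the
    avian visual forebrain (Wulst, entopallium, mesopallium ventrolaterale)
    collected under a go/no-go response-inhibition task with five stimulus
    groupings (faces, grid-scrambled faces, sine gratings). Provides a
    Poisson spike-rate session generator with plantable response classes and
    category tuning, paired-t responsiveness typing, one-way ANOVA + Tukey
    HSD stimulus selectivity with a selectivity index and a randomised-rate
    chance simulation, pseudo-population linear-discriminant decoding with
    permutation resampling and label-shuffled nulls, grid scrambling and
    Fourier spectral characterisation of stimulus images, and contingency
    chi-square comparisons of neuron-class proportions.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    MASS,
    png,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
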