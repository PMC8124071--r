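Package: calciphen
Title: Calcium Imaging Phenotyping and Culture Morphometry
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantitative analysis of fluorescence time-lapse recordings of
    neural cultures and of fixed-culture and organoid images. Detects active
    cells from a cumulative-difference activity map, normalizes traces to
    dF/F0, detects calcium transients and fits each with a two-step
    single-exponential rise / single-exponential decay model to estimate
    onset and decay time constants, classifies active cells into fast and
    slow kinetic populations, and computes event rates, amplitudes and a
    network synchrony index. Also quantifies agonist-evoked responses,
    counts synaptic puncta and their colocalization in two-channel stacks,
    computes background-corrected mean fluorescence per area, and measures
    organoid morphometry (area, perimeter, maximum Feret diameter). A
    synthetic-data generator with full ground truth makes every stage
    testable without raw microscopy data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    EBImage,
    generics,
    ggplot2,
    jsonlite,
    minpack.lm,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    tiff,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
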