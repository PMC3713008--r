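Package: dtpa
Title: Dynamic Texture Parameter Analysis for DSC-MRI Time Series
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Converts dynamic susceptibility contrast enhanced (DSCE) MRI
    image time series into baseline-difference images, normalizes them for
    coil load and cardiac output, segments the bolus passage into four
    physiological time intervals (baseline, inflow, outflow, reperfusion),
    computes eight time-resolved histogram-based texture parameter maps over
    a sliding voxel kernel, extracts per-region statistics averaged per
    interval, and tests for tissue-type differences with an ANOVA-gated,
    Benjamini-Hochberg-corrected Wilcoxon rank-sum battery. Includes a
    seeded synthetic perfusion phantom generator that provides ground truth
    for every pipeline stage, broom-style tidiers, ggplot2 visualisations,
    and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    RNifti,
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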