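Package: canopytraits
Title: Canopy Trait Extraction and Genetics Statistics for Field Phenotyping
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A data-processing pipeline for ground-based high-throughput field
    phenotyping of row crops grown in a single-plant layout. Reconstructs
    colored point clouds from co-registered depth and color frames with a
    pinhole camera model, segments canopy points by the excess-green index,
    and computes canopy-level morphological traits (height, in-row and
    across-row width, projected leaf area, convex-hull canopy volume) and
    their growth rates. Extracts mean canopy temperature from thermal frames
    by Otsu thresholding with connected-component and circumcircle filtering,
    and reports canopy-minus-air temperature. Includes the supporting sensor
    calibration computations (spectral-axis regression, spatial resolution
    and resolvability limits, validation regressions, acquisition bandwidth
    budgets), downstream genetics statistics (Pearson correlations with
    significance stars, genotype ANOVA with Tukey-Kramer compact letters,
    broad-sense heritability from ANOVA mean squares), and a synthetic field
    generator that renders depth, color and thermal frames with ground truth
    so the full pipeline is testable without field data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    readr,
    ggplot2,
    generics,
    withr,
    tiff,
    png,
    stats,
    grDevices,
    utils
Suggests:
    testthat (>= 3.0.0),
    EBImage,
    optparse,
    jsonlite
Config/testthat/edition: 3
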