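Package: ecoeff
Title: Carbon- and Water-Use Efficiency Analysis for Factorial Ecosystem Model Ensembles
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Tools to compute water-use efficiency (GPP/ET) and carbon-use
    efficiency (NPP/GPP) from gridded terrestrial ecosystem model output,
    attribute their changes to climate, CO2 fertilization and nitrogen
    deposition by factorial scenario differencing, and test trends with the
    trend-free pre-whitened Mann-Kendall test and Sen's slope. Includes a
    synthetic multi-model ensemble generator with known injected driver
    effects and AR(1) noise so every stage of the pipeline can be verified
    against ground truth, CF-style NetCDF input/output, latitude-weighted
    aggregation, dominant-driver mapping, and comparison against a reference
    water-use-efficiency product.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    dplyr,
    ggplot2,
    generics,
    jsonlite,
    ncdf4,
    purrr,
    rlang,
    stats,
    utils,
    tibble,
    tidyr,
    yaml
Suggests:
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
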