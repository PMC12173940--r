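Package: spindlescale
Title: Spindle Scaling, Turnover and Astral Microtubule Analysis for
    Differentiating Stem Cells
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Quantitative analysis of mitotic spindle scaling during neural
    differentiation of embryonic stem cells: binned spindle-versus-cell-volume
    subscaling statistics, exponential-recovery fitting of fluorescence
    recovery after photobleaching (FRAP) traces, EB1 plus-end comet track
    filtering and growth-speed analytics, refractive-index based cellular
    mass-density conversion, quantitative immunoblot tubulin-fraction
    estimation, and a limiting-component CPAP-tubulin model that predicts
    astral microtubule number as a saturating (Michaelis-Menten) function of
    cell volume.  A seeded synthetic-data generator reproduces the
    statistical structure of the published two-state (stem cell versus
    early-differentiated) populations so that every analysis stage is
    testable without the deposited imaging data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    minpack.lm,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
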