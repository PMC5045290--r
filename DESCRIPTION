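Package: areakymo
Title: Quantification of Auxin-Induced Hypocotyl Growth and Apoplastic pH
    Dynamics from Time-Lapse Imaging
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for quantifying rapid growth responses of plant hypocotyl
    segments from time-lapse imaging. Implements area-kymograph (AreaKymo)
    ratiometric analysis of apoplastic pH reporters (cell-wall pixel selection
    on a pH-insensitive reference channel, per-pixel sense/reference ratios,
    fixed-width rectangle time-space rendering, and boxplot-style summaries),
    translation-only drift stabilization, segment length measurement by
    maximum-caliper (Feret) diameter with growth traces normalized to the
    initial length, line kymographs, gravitropic tip-angle and flank-asymmetry
    quantification, lag-phase (onset) estimation by two-segment piecewise
    linear changepoint fitting, and region-of-interest luminescence kinetics.
    A synthetic-data generator emulates the imaging inputs with known ground
    truth so that every stage is verifiable by parameter recovery.
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
    pracma,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tiff,
    tools,
    utils,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
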