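Package: transectdsm
Title: Line-Transect Distance Sampling and Density Surface Modelling for Aerial Cetacean Surveys
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Covariate line-transect detection functions (half-normal and
    hazard-rate keys with cosine adjustments), effective strip widths,
    Cramer-von Mises goodness of fit, group-size bias correction, effort
    segmentation with effective-area offsets, terrain covariates from
    bathymetry rasters, Tweedie density surface models with thin-plate
    regression splines selected by GCV, and CV-masked grid prediction of
    group and individual abundance.  Includes a synthetic aerial-survey
    simulator with known truth so every stage of the pipeline can be
    validated at desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    readr,
    jsonlite,
    xml2
Suggests:
    testthat (>= 3.0.0),
    mgcv,
    withr,
    knitr
Config/testthat/edition: 3
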