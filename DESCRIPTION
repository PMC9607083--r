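Package: lagtox
Title: Time-Lagged Correlation Screening for Shellfish Toxicity Surveillance
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing weekly shellfish biotoxin monitoring panels:
    a synthetic monitoring-data generator with planted seasonality, spatial
    gradients and species-specific uptake/elimination kinetics; weekly
    resampling, coverage filtering and automated imputation-method selection
    by RMSE on artificially masked copies; monthly (seasonality) and yearly
    (trend) profiling by area, species and coastal region; time-lagged
    Pearson correlation and multi-scale detrended (partial) cross-correlation
    analysis (DCCA/DPCCA); and threshold-based screening of area, species,
    phytoplankton and environmental predictor pairs.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml,
    zoo
Suggests:
    ggplot2,
    knitr,
    optparse,
    testthat (>= 3.0.0),
    withr
VignetteBuilder: knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
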