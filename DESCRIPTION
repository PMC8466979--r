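Package: heatrisk
Title: Workplace Heat-Stress Forecast Verification with the WBGT Index
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for validating occupational heat-health warning chains.
    Computes the Wet Bulb Globe Temperature (WBGT) heat-stress index in sun
    and in shade from standard hourly meteorological variables (air
    temperature, relative humidity, wind speed, shortwave radiation), maps
    effective WBGT to four occupational risk levels for a configurable
    worker profile (metabolic rate, clothing adjustment, acclimatization),
    and verifies forecast risk levels against station observations with a
    full categorical skill-score suite (hit rate, critical success index,
    probability of detection, lack- and false-alarm ratios) plus continuous
    error metrics (ME, MAE, RMSE). Includes a synthetic station-network and
    forecast generator with a controllable error structure so that every
    stage of the validation pipeline can be exercised without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    purrr,
    tibble,
    rlang,
    readr,
    lubridate,
    ggplot2,
    geosphere,
    yaml,
    generics,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
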