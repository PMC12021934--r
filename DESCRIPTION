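Package: actiscan
Title: Sleep-Anchored Hourly Physical Activity Exposures and Glycaemic
    Association Scans for Wrist Actigraphy
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for studying when during the 24 hour day physical
    activity relates to diabetes and glycaemic markers. Reads minute-level
    wrist-actigraphy records carrying monitor-independent movement summary
    (MIMS) values and wear/sleep classifications, applies valid-day rules
    and a cohort exclusion cascade with a full audit trail, detects nightly
    sleep onset and offset with a rolling 30-minute rule, derives overall
    and weekend sleep midpoints (chronotype), computes hourly mean activity
    in clock-time and sleep-midpoint-relative framings, and scans all 24
    hourly windows for associations with prevalent diabetes (survey-weighted
    logistic regression over activity quintiles) and with log-transformed
    glycaemic biomarkers (weighted linear regression), including trend
    tests, subgroup and sensitivity analyses. A synthetic-data generator
    with known sleep timing, diurnal activity structure and configurable
    window-specific effects provides a test bed and power/type-I-error
    simulation machinery.
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
    readr,
    rlang,
    stringr,
    lubridate,
    stats,
    utils,
    generics,
    ggplot2,
    jsonlite,
    digest
Suggests:
    testthat (>= 3.0.0),
    foreign,
    optparse,
    yaml,
    withr,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
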