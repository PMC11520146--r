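Package: parkrunITS
Title: Interrupted Time-Series Analysis of Weekly parkrun Participation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Segmented quasi-Poisson regression for weekly community event
    participation counts interrupted by a total shutdown. Builds the
    interrupted time-series design (linear and quadratic trend in years,
    13-level four-week seasonality, shutdown and reopening indicators,
    post-reopening trend terms) over weekly finisher counts with a
    log-population offset, fits separate models per deprivation quintile and
    for the total population, extrapolates the pre-shutdown trend as a
    no-interruption counterfactual, and accounts for lost finishes by period.
    Includes a gamma-Poisson synthetic-data generator mirroring the model so
    the whole pipeline is testable without any download, plus ingestion of
    small-area (LSOA) finisher, deprivation and population tables.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    readr,
    ggplot2,
    rlang,
    jsonlite,
    stats,
    utils
Suggests: testthat (>= 3.0.0), withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
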