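Package: pmintr
Title: Minimum Post-Mortem Interval Estimation from Insect Development Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Tools for forensic-entomological estimation of the minimum
    post-mortem interval (PMI-min). Retrodicts death-scene temperatures
    from paired data-logger and weather-station records using quadratic
    regression or support-vector regression correction models compared by
    mean absolute difference and root mean square error; back-calculates
    blowfly oviposition time from the oldest observed developmental stage
    via accumulated degree hours (ADH); adjusts the death-time bound for
    the pre-colonization interval (PCI); and reports signed discrepancies
    against last-known-activity references. Includes a synthetic-data
    module that simulates diurnal temperature series, logger/station
    pairings and insect colonization with known ground truth, plus three
    fully worked urban death-investigation case fixtures.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    e1071,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
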