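Package: sonarramp
Title: Analysis of Sonar Ramp-Up Controlled Exposure Experiments
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing controlled exposure experiments that test
    whether gradual sonar ramp-up ("soft start") reduces the acoustic risk to
    whales approached by a transmitting ship. Builds sonar transmission
    schedules, computes per-pulse received levels and session risk indicators
    (maximum sound pressure level, cumulative sound exposure level, minimum
    source-whale range) with pluggable propagation loss, detects avoidance
    responses in movement tracks against an empirical baseline null, runs a
    Monte Carlo simulation of the exposure reduction achievable by avoidance
    under a full-power protocol, and fits cluster-robust factor models with
    jackknife variance, bootstrap contrasts, Barnard's unconditional test and
    hearing-risk classification. Includes a synthetic-data generator so the
    whole pipeline is testable without field data.
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
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
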