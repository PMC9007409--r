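Package: reachbias
Title: Reward and Success-Likelihood Biases in Go-Before-You-Know Reaching
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for planar reaching experiments in which movement
    must begin before the correct target among two candidates is revealed
    ("go before you know"). Classifies reaches as direct or intermediate from
    hand kinematics (temporal commit-time criterion or geometric interception),
    estimates per-condition choice and initial-direction biases with bimodal and
    unimodal Gaussian fits under a participant-level bootstrap, recovers the
    relative weighting of success likelihood versus monetary reward for each
    reach strategy by a weighted sum of independent axis regressions, fits a
    subjective-value power-law exponent, and estimates individual risk/reward
    attitude from a sure-bet versus gamble assay. A synthetic-data module
    generates kinematic sessions and utility-assay choices with known ground
    truth, and a parameter-recovery harness validates the weight-estimation
    method.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
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
    mclust,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
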