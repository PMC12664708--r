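Package: vrgait
Title: Gait and Balance Analysis for Virtual-Reality Floor Maze Navigation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to turn 6-DoF motion-tracker recordings (two ankle
    trackers and one navel tracker, sampled at 90 Hz) collected while a
    person walks through a grid floor maze into spatiotemporal gait
    parameters, balance metrics based on the extrapolated centre of mass,
    and covariate-adjusted associations with cognitive test scores.
    Includes a maze generator with guaranteed-unique solution paths, a
    synthetic walker that emits tracker streams with known ground truth,
    a cohort simulator with configurable gait-cognition effects, gait
    event detection from shank orientation, straight/turn step
    classification, margin-of-stability computation, and a statistical
    stage with normality screening, adjusted regressions, and
    condition-by-visit linear mixed models.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    emmeans,
    generics,
    ggplot2,
    jsonlite,
    lme4,
    lmerTest,
    purrr,
    readr,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
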