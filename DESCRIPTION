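Package: gazecue
Title: Dual-Route Modelling of Head-Orientation Biases in Perceived Gaze
    Direction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing trinomial (left/direct/right) gaze
    categorization experiments in which head orientation biases perceived
    gaze direction.  Provides factorial trial-design generators, a
    generative dual-route synthetic observer (a repulsive head influence
    inside the eye-region signal plus a direct attractive head cue),
    logistic psychometric fitting of proportion-rightward scores with
    bootstrap confidence intervals for the point of subjectively direct
    gaze, closed-form cue-weight algebra mapping regression slopes to
    eye/head weights and to the dual-route decomposition, and
    maximum-likelihood fitting of a two-criterion Gaussian categorization
    model (peak, width of the cone of direct gaze, sensory noise,
    centroid of direct responses).  A pipeline orchestrates
    design, simulation, fitting and parameter-recovery reporting.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    ggplot2,
    jsonlite,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    withr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
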