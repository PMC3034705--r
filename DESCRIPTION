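Package: footspurt
Title: Timing of the Pubertal Foot Growth Spurt from Longitudinal Shoe Sizes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to analyse longitudinal series of children's shoe sizes as
    an early indicator of the pubertal growth spurt. Implements cohort
    selection criteria for retail shoe-fitting records, detection of the
    "peak increase" in shoe size (the shortest window containing a two-size
    increase) and of the terminal plateau phase marking cessation of foot
    growth, per-sex cohort summaries, and lead-time comparison against
    reference sitting-height peak-growth-velocity ages. A seeded synthetic
    cohort generator based on a double-logistic latent growth curve provides
    ground-truth trajectories for validating the whole pipeline.
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
    tibble
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
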