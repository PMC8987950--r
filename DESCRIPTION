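Package: reachvr
Title: Computational Core of a Graded VR Reaching-Rehabilitation Game Suite
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for designing and analysing graded virtual-reality reaching
    games used in low-back-pain rehabilitation. Computes anthropometry-scaled
    target locations for prescribed trunk-flexion angles, solves ballistic
    launch parameters (fixed-speed low arc and fixed-apex descending arc) so
    projectiles intercept those targets, schedules session protocols with a
    seeded RNG, synthesises minimum-jerk motion-capture-style trial recordings,
    extracts lumbar excursion, peak lumbar flexion velocity and impact location
    through a Savitzky-Golay smoothing/differentiation pipeline, and compares
    games with two-way repeated-measures ANOVA (Mauchly sphericity screening,
    Greenhouse-Geisser correction, partial eta-squared, LSD post hoc and
    per-height simple effects).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    tidyselect,
    utils,
    withr,
    yaml
Suggests:
    car,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
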