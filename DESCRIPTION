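Package: srttci
Title: Contextual-Interference Analysis Pipeline for Serial Reaction Time Tasks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Design generation, synthetic-participant simulation, free-recall
    scoring with Monte Carlo chance calibration, difference-score metrics and
    the full statistical battery for two-day serial reaction time task (SRTT)
    studies of contextual interference, in which three eight-item key
    sequences are practiced under blocked or interleaved schedules on a
    training day and tested on a delayed retention or transfer day. Includes
    implicit/explicit learner classification from typed sequence recall,
    windowed reaction-time retention, learning and transfer scores,
    Mann-Kendall trend tests, Type III factorial ANOVA/ANCOVA with simple
    effects and Tukey-Kramer post hoc comparisons, and a reproducible
    end-to-end experiment runner.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    car,
    graphics,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    ggplot2,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
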