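Package: ncctrial
Title: Non-Concurrent Controls in Platform Trials that Add an Arm
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Design, simulation and analysis tools for two-stage platform
    trials in which a new experimental arm joins an ongoing multi-arm trial
    at the end of stage one.  Quantifies the benefit and risk of including
    non-concurrent control data (control patients enrolled before the new
    arm was added) in the analysis of the added arm, under linear and step
    calendar-time trends.  Provides closed-form operating characteristics
    (z-test power, generalized-least-squares variances and marginal power
    for stage-wise mean-difference models, borrowing of strength), patient
    level trial simulation with restricted within-stage randomization, six
    analysis approaches (independent z-tests, shared-control GLS using all
    or only concurrent control data, and patient-level regressions with a
    linear enrolment-order term or a stage indicator), and a Monte-Carlo
    engine reporting bias, type-I error, marginal power and root mean
    squared error over scenario grids.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: stats, utils, jsonlite, yaml
Suggests: testthat (>= 3.0.0), optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
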