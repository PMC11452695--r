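Package: sefspace
Title: Spike-Train and Behavioral Analysis of Visuospatial Preselection in the Supplementary Eye Field
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analyzing task-aligned single-unit activity and eye behavior
    from oculomotor choice experiments in which a symbolic cue instructs a visual
    hemifield before a saccade target appears. Provides a tabular session data model,
    an inhomogeneous-Poisson synthetic session generator with direction-tuned and
    hemifield-selective neuron archetypes, inverse-interspike-interval (iISI) windowed
    spike metrics, a time-resolved two-stage two-way-ANOVA classifier of task-factor
    selectivity with a consecutive-window persistence rule, preferred-direction tuning
    and population rotation, shuffle-null ROC/AUC tracks with false-discovery-rate
    control, eye-position bias detection and activity/eye-position regression
    disentanglement, and behavioral statistics for microstimulation experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    car,
    jsonlite,
    withr
Config/testthat/edition: 3
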