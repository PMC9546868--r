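Package: restreplay
Title: Detecting Replay of Movement-Evoked Activity Patterns in Resting-State fMRI
Version: 0.1.0
Authors@R:
    person("Tomas", "Levin", email = "tlevin@example.org", role = c("aut", "cre"))
Description: Tools for testing whether spatial activity patterns evoked by hand
    movements in motor cortex re-occur spontaneously during rest. Implements a
    surface-sampled BOLD simulator with a block-design motor task and seeded
    rest-embedded pattern events; frame-exclusion, global-signal-regression and
    per-frame spatial z-scoring preprocessing; adaptive-threshold GLM region-of-
    interest selection with a gamma hemodynamic response model; shrinkage linear
    discriminant decoding of movements under leave-one-run-out cross-validation;
    the 90th-percentile CDF(r^2) task-rest pattern-similarity statistic in
    squared, signed, inverted and spatio-temporal variants; and the matching
    group-level repeated-measures statistics with Holm-Bonferroni and
    Benjamini-Hochberg corrections.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    jsonlite,
    stats,
    tools,
    utils,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
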