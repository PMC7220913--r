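Package: wmcpm
Title: White-Matter Functional Connectome-Based Predictive Modeling of Fluid Intelligence
Version: 1.0.0
Authors@R: person("wmcpm", "developers", email = "wmcpm@example.org", role = c("aut", "cre"))
Description: Connectome-based predictive modeling (CPM) of general fluid
    intelligence (Gf) from white-matter resting-state functional connectomes.
    Provides motion-aware time-series preprocessing (nuisance regression,
    band-pass filtering, framewise-displacement scrubbing, participant-level
    quality control), group white-matter mask construction and equal-size
    spatial parcellation, Fisher r-to-z connectome construction, CPM-style
    edge selection with positive/negative network strengths, leave-one-out
    and repeated k-fold cross-validation, permutation-based inference,
    Steiger's z comparison of dependent correlations, consensus-feature
    generalization to retest and external cohorts, and a synthetic-cohort
    generator with planted ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
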