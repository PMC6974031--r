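Package: preconmvpa
Title: Pattern-Based fMRI Analysis of Sensory Preconditioning
Version: 0.1.0
Authors@R:
    person("Pattern", "Analyst", email = "dev@example.org", role = c("aut", "cre"))
Description: A tested, reusable pipeline for multivoxel pattern analysis of
    sensory preconditioning experiments. Provides a synthetic-data generator
    with known ground truth (cue-cue pattern convergence, an outcome-value
    code, probe-phase reactivation, and context-dependent seed-target
    coupling), first-level GLM pattern estimation with a canonical
    double-gamma HRF, Fisher-z pattern-similarity trajectories, linear
    support-vector-machine decoding with nested leave-one-subject-out
    feature selection and permutation-based empirical chance, searchlight
    machinery, psychophysiological-interaction connectivity, and the
    behavioral statistics (repeated-measures ANOVA with Greenhouse-Geisser
    correction, d-prime, correlations, binomial exclusion tests) used to
    evaluate such experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    data.table,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
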