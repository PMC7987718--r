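Package: flydimorph
Title: Quantitative Analysis of Drosophila Courtship Behavior, Calcium
    Responses, Oviposition Preference and Connectome Input Budgets
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantifying sexually dimorphic behavior and circuitry
    in Drosophila melanogaster. Implements rule-based courtship
    classification from two-fly pose tracks (wing-extension geometry,
    courtship initiation and indices, bout statistics, relative-position
    heatmaps), stimulus-aligned calcium-trace analysis (dF/F, within-fly
    averaging, area under the curve), two-choice oviposition preference
    scoring with its nonparametric and GLM statistical contracts, and
    synaptic input-budget analysis of connectome synapse tables with
    rule-based neuron classification. A companion set of seeded synthetic
    generators produces pose tracks, behavior labels, fluorescence traces,
    egg counts and synapse tables with planted ground truth, so every
    analysis stage can be validated end to end without raw video or
    database access.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    MASS,
    pracma,
    stats,
    survival,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
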