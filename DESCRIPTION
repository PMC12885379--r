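Package: regenquant
Title: Quantification Pipeline for Zebrafish DRG Central Axon Regeneration Assays
Version: 0.1.0
Authors@R:
    person("Regenquant", "Developers", email = "maintainer@regenquant.org",
           role = c("aut", "cre"))
Description: Reusable, tested implementations of the quantification and
    classification procedures used to study the closure of the regenerative
    period of zebrafish dorsal root ganglion (DRG) centrally-projecting
    axons: axon re-entry scoring from dual-channel orthogonal fluorescence
    line profiles, invadopodia event detection and duration classification
    from growth-cone actin (LifeAct) traces, glial migration metrics from
    object tracks, stimulus-locked GCaMP6s z-score synchrony classification,
    cold-evoked shivering quantification from behavioral tracks, and HCR
    puncta/mean-grey quantification. A seeded synthetic-data module
    fabricates every input with ground-truth sidecars, standing in for the
    microscope, and a statistics module provides the group comparisons
    (Fisher's exact, Kruskal-Wallis, Mann-Whitney, Brown-Forsythe and Welch
    ANOVA, paired t, chi-squared) used throughout.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
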