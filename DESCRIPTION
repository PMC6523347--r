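Package: tmsmapr
Title: Accuracy Assessment for Grid-Based TMS Motor Maps by Bootstrapping
Version: 0.1.0
Authors@R:
    person("TMS", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for analysing grid-based navigated transcranial magnetic
    stimulation (nTMS) motor maps. Computes eight muscle-representation
    parameters (thresholded areas, amplitude- and probability-weighted areas,
    and centres of gravity) from per-cell motor evoked potential (MEP)
    amplitude samples with left-censoring below the detection threshold,
    and assesses their accuracy by bootstrap resampling: normalized bias,
    coefficient of variation, between-session variability, and centre-of-
    gravity error as functions of the number of stimuli per grid cell.
    Includes censored-data cell-wise session comparisons (Gehan's
    generalization of the Mann-Whitney test), significance diagrams,
    bootstrap histogram overlap, a bootstrapping-based between-session
    intraclass correlation coefficient, Page's trend test for ordered
    alternatives, stimulation-grid coverage analysis for gridless point
    maps, and a synthetic map generator for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    withr,
    jsonlite
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
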