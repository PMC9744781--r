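Package: erpmarkers
Title: Category-Specific ERP Markers: Simulation, Extraction, Statistics and Decoding
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying category-specific event-related potential (ERP)
    markers of visual and auditory perception. Simulates multichannel (126-site
    10/5 montage) continuous EEG as additive component templates plus 1/f
    background noise and ocular artifacts under a 10-category passive
    stimulation paradigm; performs epoching, peak-to-peak artifact rejection,
    baseline correction and trial averaging; extracts mean-area amplitudes of
    16 ERP markers (N80, N170, N2, P2, P300, N400, CPP, LCPP, AN, AP, LP,
    PN300) over their literature-defined windows and electrode sets; runs
    repeated-measures ANOVAs with Greenhouse-Geisser correction, partial eta
    squared and Tukey HSD post hoc tests; and decodes stimulus category from
    marker features with a two-stage nearest-centroid classifier evaluated by
    leave-one-subject-out cross-validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    tibble,
    dplyr,
    tidyr,
    rlang,
    ggplot2,
    generics,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    yaml,
    jsonlite,
    withr
Config/testthat/edition: 3
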