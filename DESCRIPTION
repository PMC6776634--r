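Package: retinamech
Title: Mechano-Electrophysiology of Retinal Tissue on High-Density
    Multi-Electrode Arrays
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Combined analysis of depth-controlled oscillatory
    micro-indentation rheology and high-density multi-electrode array
    (HD-MEA) spike recordings of retinal ganglion cells. Extracts apparent
    storage and loss moduli and the loss tangent from ferrule-top
    indentation traces under Hertzian contact geometry, detects and
    characterizes mechanically evoked modulation of spiking via
    sliding-window firing rates, correlation-based hierarchical clustering
    with silhouette model selection, ON/OFF/ON-OFF bias-index
    classification from full-field flashes, probe localization from
    light-saturation frames, and decision-tree feature importance for
    stimulus-response prediction. Includes synthetic-data generators for
    both data streams so every stage is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    cluster,
    rpart,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
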