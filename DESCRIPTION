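Package: gonadosync
Title: Synchrony Analysis of Gap-Junction-Coupled Gonadotrope Networks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Quantitative workflow for calcium-imaging studies of
    electrotonically coupled endocrine-cell networks, developed around the
    anterior-pituitary gonadotrope system. Provides fluorescence trace
    normalization (F/F0 against a baseline window), detection and
    classification of stimulus-responding cells, all-pairs Spearman
    rank-correlation synchrony analysis across stimulation time windows,
    distance-resolved correlation regression with between-group slope and
    intercept comparison, short-range (<5 um) synchrony contrasts,
    coupling-coefficient estimation from paired current-clamp recordings,
    and a generic position-weight-matrix promoter scan. A ground-truth
    simulator of coupled versus uncoupled cell networks and of paired
    voltage recordings allows the full pipeline to be exercised and
    validated without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    SummarizedExperiment,
    S4Vectors,
    Biostrings,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    tiff
Config/testthat/edition: 3
RoxygenNote: 7.3.3
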