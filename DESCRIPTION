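Package: hotspotr
Title: Interface Hotspot Calling on Docked Complexes with Cohort and
    Imaging Statistics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Residue-interaction-network analysis of protein-protein docking
    poses: contact networks under a heavy-atom distance window, closeness
    centrality Z-scores, interface residue detection, and consensus hotspot
    calling across poses. Companion cohort statistics for somatic mutation
    tables (protein-change parsing, codon watch-lists, mutational burden per
    patient per megaresidue), clinical sample labeling with a normality-gated
    parametric/nonparametric differential-expression procedure, and summary
    statistics for live-cell imaging (translocation ratios, migration rates,
    calcium peak amplitudes, baseline-normalised fluorescence). Includes
    synthetic-data generators with planted ground truth for every input type.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    bio3d,
    car,
    igraph,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
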