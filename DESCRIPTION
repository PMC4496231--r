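Package: viaquant
Title: Automated Quantification of Cell Viability from Multichannel
    Fluorescence Microscopy and Flow Cytometry
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Implements an automated cell-viability quantification workflow
    for samples co-stained with a chromatin dye (Hoechst 33342 or DAPI), the
    mitochondrial transmembrane-potential probe DiOC6(3) and the
    caspase-dependent uptake dye YO-PRO-3. Provides nucleus and cytoplasm
    segmentation of three-channel epifluorescence fields, FCS 3.1 event
    input/output with robust forward/side-scatter pre-gating, data-driven
    gate derivation and classification of every cell or event into five
    viability phenotypes, absolute viable-cell counting per area or volume,
    four-parameter Hill dose-response fitting, Loewe-additivity combination
    indexes with synergy/antagonism calls, and condition-comparison
    statistics. A synthetic-data generator with known per-cell ground truth
    emulates both acquisition modalities and drug-combination plates.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    grDevices,
    S4Vectors,
    EBImage,
    MASS,
    mclust,
    jsonlite,
    yaml,
    ggplot2,
    rlang
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
biocViews: CellBiology, FlowCytometry, CellBasedAssays, Software,
    SingleCell, Visualization
RoxygenNote: 7.3.3
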