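Package: macnet
Title: Transcriptome Network Analysis of Macrophage Activation Spectra
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A workflow for transcriptome-based network analysis of human
    macrophage activation, built around the spectrum model of activation
    states. Provides sample coregulation networks with Markov clustering and
    3D force-directed layout, condition correlation matrices and spectrum
    displacement vectors anchored at baseline macrophages, self-organizing
    map clustering with exclusive-marker discovery, weighted gene
    coexpression module detection with module-eigengene/trait correlation,
    gene-set enrichment analysis using coexpression modules as gene sets,
    and mutual-information reverse network engineering with data-processing
    inequality pruning and hub analysis. Includes a synthetic-data generator
    with planted modules, markers and hub topologies so every stage can be
    validated against known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    igraph,
    jsonlite,
    yaml,
    MASS,
    stats,
    utils,
    tools,
    grDevices,
    graphics
Suggests:
    testthat (>= 3.0.0),
    mclust,
    withr,
    limma,
    fgsea
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
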