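Package: viabench
Title: Benchmarking Viability Discrimination by Sequencing-Based Microbiome Methods
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for evaluating how well sequencing-based community profiling
    methods distinguish viable from non-viable bacteria using defined (mock)
    communities spiked into a food matrix. Provides abundance-mass confusion
    metrics (accuracy, precision, sensitivity, F-score) scored against
    sequenced control communities, absolute cell-count estimation that anchors
    relative abundances to total-bacteria qPCR, a from-scratch beta-diversity
    stage (Bray-Curtis, principal coordinates, one-way PERMANOVA, agglomerative
    clustering with Newick export), and a seeded generator of complete synthetic
    spike-in studies (live and heat-killed communities observed through
    DNA-based, PMA-treated and RNA-based library types on two sequencing
    platforms) so the whole pipeline runs end to end without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    tools,
    utils,
    grDevices,
    graphics
Suggests:
    testthat (>= 3.0.0),
    withr,
    vegan,
    ape
Config/testthat/edition: 3
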