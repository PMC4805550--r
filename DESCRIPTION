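Package: photoconn
Title: Functional Connectivity Mapping from Photostimulation Electrophysiology
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Converts raw voltage-clamp current traces recorded during
    glutamate-uncaging photostimulation into functional granule-cell input
    maps for cerebellar target neurons. Implements noise-calibrated Z-score
    statistics on integrated synaptic charge, direct-current removal by
    median filtering, matched-filter EPSC event detection, depth-maximum
    projection and triangular-kernel smoothing of mediolateral input
    patterns, registration of cell positions into a standardized zebrin-band
    coordinate frame, sliding-window median patterns, pairwise Pearson
    correlation with a shuffled-pair null, bipartite spectral co-clustering
    of the correlation matrix, and site-by-site delta-Z classification of
    plasticity-induced map changes. A synthetic-experiment generator with
    planted connectivity ground truth makes every stage of the pipeline
    verifiable by parameter recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3.0)
Imports:
    methods,
    stats,
    utils,
    grDevices,
    graphics,
    data.table,
    jsonlite,
    zoo,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    mclust,
    pheatmap
Config/testthat/edition: 3
RoxygenNote: 7.3.3
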