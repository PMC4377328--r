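Package: degnet
Title: Integrative Differential Expression and Network Deregulation Analysis
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Toolkit for integrative cancer transcriptome and interactome
    analysis around a seed gene family (the aminoacyl-tRNA synthetases and
    their associated AIMP scaffolds). Implements expressed-gene filtering by
    a two-component Gaussian mixture, a dual-statistic differential
    expression test (Student t and log2-median-ratio) with permutation-based
    empirical nulls smoothed by kernel density estimation, Stouffer
    meta-combination across tests and datasets, node deregulation and edge
    co-association scoring on seed-centred interaction networks, key-module
    detection by random walk with restart against a degree-preserving
    randomized null, and cross-species conserved-motif discovery by
    ortholog-group collapsing. Seeded synthetic-data generators with known
    ground truth replace external cohort and interactome downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    limma,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
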