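Package: strobosync
Title: Multistability of Delayed Kuramoto Dynamics on Structural Brain Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates noise-free delayed Kuramoto phase oscillators on weighted
    structural brain networks, scores pairwise synchronisation with a
    stroboscopic phase-sampling index, counts the stable synchronisation states
    reachable from random initial conditions via gap-statistic k-means model
    selection, and compares state-count distributions against degree-, strength-
    and length-preserving rewired null networks. Includes a seeded synthetic
    generator of modular, spatially embedded structural networks so the full
    pipeline runs without imaging data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    cluster,
    withr,
    igraph,
    optparse,
    yaml
Config/testthat/edition: 3
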