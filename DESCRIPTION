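Package: regcascade
Title: Regulated Threshold Cascades on Modular Networks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying how community structure interacts with
    process-level regulation of transmission in threshold (complex) contagion.
    Builds modular random networks with prescribed intra- and inter-community
    degree distributions via the configuration model, simulates synchronous
    regulated threshold cascades, solves the tree-like (message-passing)
    approximation for final adoption densities in n-community block models,
    maps diffusion regimes (non-diffusion, localized, global) and their abrupt
    transitions, and computes minimal-cost intervention strategies over the
    controllable region of the regulation plane. Includes readers and writers
    for SNAP-style edge lists and ground-truth community files plus a
    synthetic fixture generator for download-free testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Matrix,
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
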