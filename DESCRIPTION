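Package: eegtda
Title: Topological Data Analysis of EEG Functional Brain Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing multichannel EEG as a functional brain
    network with algebraic topology. Builds channel-by-channel distance
    matrices from phase-locking values or standardized Euclidean distance,
    constructs Vietoris-Rips (clique) filtrations, tracks Euler
    characteristic and Euler entropy to locate topological phase
    transitions, computes persistence barcodes by boundary-matrix reduction
    over the two-element field together with persistent entropy features,
    and compares paired experimental conditions per frequency band.
    Includes a synthetic-EEG generator with planted von Mises phase
    coupling so the full pipeline can be exercised and validated without
    recorded data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    igraph,
    jsonlite,
    signal,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
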