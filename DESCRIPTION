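Package: ictonet
Title: Bistable Network Models of Seizure Transitions and Brain Network
    Ictogenicity
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Simulates networks of bistable complex-valued oscillators in
    which a stable steady state ("background") coexists with a stable limit
    cycle ("seizure"), and quantifies how readily a given connectivity
    structure drives noise-induced transitions into the oscillatory state via
    the brain network ictogenicity (BNI) statistic.  Includes phase-locking
    factor functional-network inference from multichannel band-limited
    signals, graph measures (mean degree, degree variance, clustering),
    mean-degree-preserving binarization with degree-preserving
    randomization, synthetic cohort and coupled-signal generators, and a
    Kruskal-Wallis group-comparison pipeline.
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
LinkingTo: Rcpp
Suggests:
    optparse,
    withr,
    yaml,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
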