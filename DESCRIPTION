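Package: topotest
Title: Topology Tests, Selection-Bias Corrections, and Confidence Sets of
    Phylogenetic Trees
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Likelihood-based tests of phylogenetic tree topologies and the
    confidence sets they induce. Implements the Kishino-Hasegawa (KH) z-test,
    the chi-square test with an optional low-degrees-of-freedom correction,
    the Shimodaira-Hasegawa (SH) test, the approximately unbiased (AU)
    multiscale-bootstrap test with a bootstrap-proportion-zero correction,
    and approximate Bonferroni and Benjamini-Hochberg corrections for the
    selection bias incurred by testing against the maximum-likelihood tree.
    Split support values are derived from any of these tests and compared
    with approximate likelihood-ratio-test (aLRT) supports and their
    multiplicity-corrected variant (aLRTc). A compact HKY+Gamma pruning
    engine, exhaustive topology enumeration for up to eight taxa, a seeded
    sequence simulator, and a Monte Carlo study harness make coverage and
    mean-set-size experiments reproducible without external data; per-site
    log-likelihood matrices from external ML software can be imported for
    analyses under other models.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    ape,
    stats,
    utils,
    tibble,
    dplyr,
    tidyr,
    rlang,
    ggplot2,
    generics
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    phangorn,
    withr,
    jsonlite
Config/testthat/edition: 3
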