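Package: bustede
Title: Error-Aware Branch-Site Tests for Episodic Diversifying Selection
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Branch-site random-effects codon substitution models (the
    BUSTED family) with an optional "error-sink" dN/dS class that jointly
    tests protein-coding alignments for episodic diversifying selection
    and flags codons whose substitution pattern is error-like rather than
    biological. Provides maximum-likelihood fitting of the MG94xREV codon
    model with general discrete distributions of synonymous and
    non-synonymous rates, likelihood-ratio tests with AICc model
    averaging, empirical-Bayes-factor based masking of suspect codons,
    and a parametric codon-alignment simulator.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    ape,
    Biostrings,
    jsonlite,
    lhs,
    stats,
    utils
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    phangorn,
    Matrix,
    optparse,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
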