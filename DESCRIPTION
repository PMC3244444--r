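Package: protsel
Title: Selective Regimes on Protamine Genes from Codon Models and
    Phylogenetic Comparative Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Likelihood inference of selective pressure (dN/dS) on
    protein-coding genes, built around a Goldman-Yang codon substitution
    model with branch-partition (clade) and site-mixture (M0, M1a, M2a,
    M7, M8) omega structures. Provides likelihood-ratio tests separating
    positive selection from relaxation of selective constraint in a focal
    clade, Bayes empirical Bayes classification of sites into purifying,
    neutral and positively selected classes, per-species root-to-tip
    omega from free-ratio fits, phylogenetic generalized least squares
    regression of omega against relative testes mass under an exponential
    phylogenetic covariance, annotation of protamine functional domains
    (DNA-anchoring runs, phosphorylation motifs, cleavage sites), and a
    codon-alignment and trait simulator so the whole pipeline is testable
    without external data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    ape,
    Biostrings,
    jsonlite,
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    nlme,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
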