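Package: introscan
Title: Clade-Wide Phylogenomic Introgression Scans
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects and characterizes hybridization across species radiations
    from per-locus gene trees and alignments. Implements rooted-triplet gene
    tree tests with exact binomial comparison of minor topologies and
    Holm-Bonferroni control, ABBA-BABA D-statistics on thinned biallelic site
    patterns with block-jackknife significance, an f-branch summary that
    assigns excess-allele-sharing signal to terminal and internal branches of
    the species tree, divergence-based polarization of gene-flow direction,
    and collapsing of correlated significant tests into ancestral
    hybridization events. Includes a multispecies-coalescent simulator with
    hybrid edges for generating synthetic gene trees and sequence alignments
    with known introgression histories.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    jsonlite,
    optparse,
    phangorn,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
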