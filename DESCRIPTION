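Package: omegarelax
Title: Branch-Model Ka/Ks Cascades for Detecting Clade-Specific Relaxation of
    Purifying Selection
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects clade-specific relaxation and neutralization of purifying
    selection in bacterial endosymbiont genes. Implements a Goldman-Yang style
    codon substitution model with branch-specific Ka/Ks (omega) classes,
    Felsenstein pruning likelihoods, a nested likelihood-ratio-test cascade
    with a forced-neutral foreground test and a branch-site positive-selection
    check, gene-jackknife tree resampling for phylogenetic robustness,
    alignment preparation filters (coordinate masking, premature-stop gene
    splitting, divergence-based strain deduplication, MaxChi recombination
    scanning), a clade-exclusive substitution scanner with physicochemical
    annotation, and seeded forward simulators so every stage is testable on
    synthetic data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    ape,
    jsonlite,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    phangorn
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
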