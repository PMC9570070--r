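Package: elongeff
Type: Package
Title: Translation Elongation Efficiency Indices and Their Protein-Abundance
    Correlates in Prokaryotes
Version: 0.1.0
Author: elongeff developers
Maintainer: elongeff developers <elongeff-dev@example.org>
Description: Scores every protein-coding gene of an annotated prokaryotic
    genome for predicted translation elongation efficiency using codon
    decoding-time estimates and local mRNA secondary-structure load
    (hairpin counts and energy-weighted hairpin counts), ranks ribosomal
    protein genes on each of five index variants to call the genome's mode
    of translational optimization, and relates the resulting indices to
    protein abundance (Spearman correlation with bootstrap significance),
    growth rate and genome features across organisms (Pearson
    meta-correlations, Welch tests, ordinary least squares with Monte-Carlo
    cross-validation). Ships a seeded synthetic genome and protein-abundance
    simulator plus a packaged 25-organism meta-table so the whole pipeline
    is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Imports: Rcpp, Biostrings, methods, stats, utils
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0), withr, optparse, jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
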