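Package: cytonuc
Title: Cytonuclear Coevolution Analysis of Mitochondrial tRNA Metabolism
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying the coevolution of nuclear-encoded
    aminoacyl-tRNA synthetases (aaRS) with mitochondrially encoded tRNAs.
    Implements two-round profile-based phylogenetic profiling with
    maximum-likelihood placement filtering of fragmentary transcripts on
    annotated reference trees, pairwise maximum-likelihood distances under
    the WAG amino-acid and Kimura two-parameter nucleotide models, the
    compensatory-substitution linear model relating aaRS and mt-tRNA
    substitution rates, and an entropy-filtered scan for mitochondrial
    genetic-code reassignments.  Ships seeded synthetic-data generators so
    the whole pipeline can be exercised against known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    ape,
    Biostrings,
    jsonlite,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    phangorn,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
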