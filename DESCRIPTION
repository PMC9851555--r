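Package: dupshift
Title: Inference of Tandem Gene Duplication and Neofunctionalization from
    Sequences, Synteny, and Expression
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to test whether a gene family member arose from a paralog
    by tandem duplication followed by neofunctionalization, modelled on the
    evidence chain used for Apiaceae flavone synthase I (FNS I) and flavanone
    3-hydroxylase (F3H): candidate discovery by pairwise alignment scoring,
    progressive multiple alignment with occupancy-based column trimming,
    neighbor-joining phylogenetics with Poisson-corrected distances, pairwise
    deletion and bootstrap supports, clade monophyly and nesting tests,
    diagnostic-residue classification against a reference numbering,
    microsynteny block detection from reciprocal-best-hit anchors with a
    six-frame translated genome scan, and thresholded Spearman co-expression.
    Includes a calibrated simulator that generates gene families, annotated
    genomes and expression matrices with full ground truth.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    ape,
    tibble,
    dplyr,
    tidyr,
    purrr,
    readr,
    stringr,
    rlang,
    generics,
    ggplot2,
    jsonlite,
    yaml,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    phangorn,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
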