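Package: cressannot
Title: Annotation and Taxonomic Classification of CRESS DNA Virus Genomes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for annotating circular Rep-encoding single-stranded DNA
    (CRESS DNA) virus genomes and classifying them under the pairwise-identity
    demarcation framework used for these viruses. Finds open reading frames on
    both strands of a circular genome (including origin-spanning and
    intron-interrupted genes), locates the putative origin of replication as a
    nonanucleotide motif at the apex of a stem-loop, identifies the
    replication-associated protein (Rep) by rolling-circle replication and
    superfamily-3 helicase motifs, flags putative capsids from intrinsic
    disorder profiles, computes circular-aware genome-wide and Rep amino-acid
    pairwise identities with an affine-gap global aligner, applies
    family-specific species demarcation thresholds, performs two-stage greedy
    identity clustering, prepares motif-anchored trimmed alignments, builds
    neighbour-joining trees and collapses low-support branches. A seeded
    synthetic-genome generator with a full ground-truth channel makes every
    stage testable without downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    Biostrings,
    ape,
    tibble,
    dplyr,
    purrr,
    stringr,
    rlang,
    ggplot2,
    generics,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    phangorn,
    rtracklayer,
    jsonlite,
    withr
Config/testthat/edition: 3
NeedsCompilation: yes
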