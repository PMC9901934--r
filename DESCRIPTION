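Package: ribodms
Title: Deep Mutational Scanning Analysis of Self-Cleaving Ribozymes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for high-throughput mutate-and-cleave
    experiments on self-cleaving ribozymes. Simulates sequencing reads from
    doped-oligonucleotide libraries undergoing co-transcriptional
    self-cleavage, assigns each read a genotype with a sliding-window
    variant caller, classifies reads as cleaved or uncleaved from the
    5'-leader, and computes fraction cleaved, relative activity, pairwise
    epistasis with a sigma-based reliability filter, structure-mapped
    mismatch categories, Mann-Whitney comparisons, and nearest-neighbor
    duplex free energies for paired regions.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    Biostrings,
    dplyr,
    tibble,
    tidyr,
    readr,
    yaml,
    stats,
    utils,
    rlang
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    ggplot2
Config/testthat/edition: 3
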