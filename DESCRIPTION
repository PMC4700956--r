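Package: mirevo
Title: Discovery and Evolutionary Analysis of Clustered Plant miRNA
    Families Targeting Disease-Resistance Genes
Version: 0.1.0
Authors@R:
    person("mirevo", "developers", email = "mirevo@example.org",
           role = c("aut", "cre"))
Description: Tools for studying the evolution of clustered plant miRNA
    gene families that regulate NBS-LRR disease-resistance genes.
    Provides hairpin-precursor discovery from mature miRNA queries
    (mismatch genome scan, window folding, deterministic trimming and
    structural validation, miR* localisation), structure-partitioned
    per-region substitution-rate estimation against a chronogram,
    expectation-scored miRNA to R-gene target prediction with strict and
    relaxed cutoffs, redundancy statistics over the bipartite
    miRNA-target network with ortholog/paralog homology edges, and
    tandem/segmental duplication calls from flanking-gene synteny.  A
    fully seeded synthetic-data generator emits every input with known
    ground truth so the whole pipeline is testable without external
    genomes.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    ape,
    igraph,
    jsonlite,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
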