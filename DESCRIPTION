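Package: cardmlst
Title: Multi-Locus Sequence Typing Toolkit for Cardinium Endosymbionts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An in-silico toolkit around a four-locus (gyrB, groEL, sufB,
    EF-G) multi-locus sequence typing (MLST) scheme for the arthropod
    endosymbiont Cardinium hertigii. Provides IUPAC-aware degenerate primer
    design from multi-strain alignments with hairpin/dimer/melting-point
    heuristics, in-silico PCR with degenerate primers and primer trimming,
    allele calling and sequence-type assignment, co-infection genotype
    resolution by allelic intersection analysis and by qPCR titer rank
    consistency, and partitioned multi-locus phylogenetics: supermatrix
    concatenation with gene and codon-position partitions, p/JC69 distances,
    neighbor-joining with nonparametric bootstrap, Felsenstein pruning
    likelihood under JC69/K80/HKY85 with AIC model selection, and unrooted
    clade-monophyly tests. A synthetic-data module simulates sequence
    evolution on trees with planted clades, templates with planted primer
    binding sites, and co-infected individuals with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    ape,
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    purrr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    phangorn,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
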