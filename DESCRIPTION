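Package: dinoeve
Title: Detection and Genomic Characterization of Endogenized
    Dinoflagellate RNA Virus Elements
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools to detect, validate and characterize endogenous viral
    elements (EVEs) derived from non-retroviral +ssRNA dinoflagellate
    viruses (dinoRNAVs) in genome and metagenome assemblies.  The package
    provides a six-frame translated homology search against a curated
    viral protein panel with BLAST-style score statistics and filters,
    deterministic ORF calling with panel-based annotation and
    flank-based verification of fragmented candidates, classification of
    single-ORF versus whole-genome (paired MCP/RdRp) integrations,
    a spliced-leader relict scanner, genomic-neighborhood annotation, a
    read-coverage uniformity screen against chimeric assembly artifacts,
    Nei-Gojobori (1986) dN/dS estimation on codon back-alignments, and
    per-assembly count summaries with a linear model across host genera.
    A seeded synthetic-genome generator plants ground-truth EVEs so that
    every stage of the pipeline is verifiable at desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    IRanges,
    GenomicRanges,
    S4Vectors,
    ape,
    car,
    emmeans,
    jsonlite,
    methods,
    Rcpp,
    stats,
    tools,
    utils,
    withr
LinkingTo: Rcpp
Suggests:
    Rsamtools,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
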