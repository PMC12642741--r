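Package: sgescore
Title: Variant Scoring for Saturation Genome Editing Experiments in iPSCs
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: End-to-end analysis of saturation genome editing (SGE) variant
    libraries phenotyped in induced pluripotent stem cells and their
    derivatives. Enumerates and annotates saturation SNV libraries over an
    amplicon, turns FASTQ reads into per-variant counts under single-SNV
    filtering rules, computes FACS sort-seq weighted-bin protein abundance
    scores and growth-based fitness scores anchored to synonymous and nonsense
    variant distributions, calls loss-of-function and dominant-negative
    mechanisms across genetic backgrounds, calibrates functional classes into
    Bayesian OddsPath evidence mapped to ACMG PS3/BS3 strengths with a
    point-based evidence combiner for VUS reclassification, scores pooled
    CRISPR knockout screens against non-targeting controls, and provides a
    seeded synthetic-data generator with known truth for every assay mode.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    S4Vectors,
    jsonlite,
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
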