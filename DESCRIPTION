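Package: frcycle
Title: Forward-Reverse Mutation Cycles in Multi-Stage Cancer Genomes
Version: 0.9.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tracks single-nucleotide variant genotypes (MM/Mm/mm) across
    staged same-patient samples (blood, nontumor, paratumor, tumor, or time
    series), classifies gain- and loss-of-heterozygosity transitions, builds
    patch diagrams with per-step mutation rates and lineage-effect statistics,
    assembles reversal-annotated trinucleotide mutational profiles with
    duplex-context opposing-pair rate diagrams, enumerates the 26-order serial
    taxonomy of window copy-number status with lineage Q statistics and
    recurrent-CNV detection, and measures SNV-CNV co-localization. A
    multi-stage mutation simulator with tunable reversal probabilities,
    lineage fidelity and CpG context bias emits standard-format inputs
    (VCF/FASTA/TSV) and ground truth for every pipeline stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    graphics,
    SummarizedExperiment,
    S4Vectors,
    IRanges,
    GenomicRanges,
    GenomeInfoDb,
    Biostrings,
    VariantAnnotation,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
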