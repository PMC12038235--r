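Package: bclhap
Title: Structural Haplotype Analysis of the Grapevine Berry Color Locus
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for analysing structural haplotypes of the grapevine
    berry color locus (BCL), the MybA transcription-factor cluster on
    chromosome 2 that controls berry skin anthocyanin. Provides a seeded
    synthetic-locus generator for the known BCL haplotype architectures
    (HapA, HapC-N, HapF1, HapF2 and the deleted HapF haplotype), read
    simulators, diagnostic-marker scanning and subhaplotype calling from
    read alignments, an in-silico PCR emulation of INDEL assays,
    private-SNP allele-specific expression with per-allele TPM,
    MybA gene discovery and structural comparison of haplotypes, LTR
    retrotransposon insertion dating, Tamura-Nei/UPGMA bootstrap
    phylogenies, and single-locus genetics statistics (segregation,
    allele frequencies, genotype-phenotype association, haplotype dosage).
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
    Rsamtools,
    rtracklayer,
    ape,
    phangorn,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
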