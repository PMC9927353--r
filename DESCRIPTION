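Package: tfdeam
Title: Transcription-Factor Target Mapping from Deaminase-Directed Mutagenesis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for mapping transcription-factor (TF) binding sites from
    TF-fusion cytidine-deaminase mutagenesis experiments read out by
    whole-genome sequencing. Implements replicate-consensus SNP screening,
    background subtraction, exclusion of hypermutable regions and
    cross-TF-recurrent sites, attribution of TF-guided SNPs to promoter-like
    intergenic regions, and extraction of flanking sequence windows for motif
    discovery. Ships a synthetic-experiment simulator (genome, planted
    TF-binding boxes, distance-decayed directed deamination, serial-passage
    allele-frequency dynamics, binomial read sampling) that provides ground
    truth for every pipeline stage, plus the summary statistics used to
    characterise such experiments: expected stochastic replicate sharing,
    SNP-to-box distances, template/coding strand classification, replicate
    frequency reproducibility, and benchmarking against reference target
    lists.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    BiocGenerics,
    Biostrings,
    methods,
    tools,
    GenomicRanges,
    IRanges,
    S4Vectors,
    jsonlite,
    rtracklayer,
    stats,
    utils,
    vcfR,
    withr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
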