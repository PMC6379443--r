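Package: bystanderscan
Title: Detection of CRISPR Bystander Structural Variants at Edited Loci
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Locus-scale discovery pipeline for unintended "bystander"
    structural mutations adjacent to on-target CRISPR edits. Provides a
    truth-annotated synthetic data generator for edited loci (enhancer
    deletion plus linked tandem duplication, paired-end WGS reads,
    junction-spanning RNA reads, cohort VCFs), a minimal seed-and-extend
    paired-end aligner with windowed coverage profiling and copy-gain
    segmentation, discordant-pair classification and de Bruijn breakpoint
    junction assembly with microhomology and extended-homology scanning,
    off-target-proximity and inheritance-model candidate-variant filters,
    splice-junction k-mer isoform quantification with premature-stop
    prediction, and in-silico PCR genotyping, orchestrated end to end with
    machine-readable reports.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    IRanges,
    data.table,
    jsonlite,
    methods,
    stats,
    utils,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    VariantAnnotation,
    SummarizedExperiment,
    GenomicRanges,
    BiocGenerics
Config/testthat/edition: 3
RoxygenNote: 7.3.3
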