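Package: feralscan
Title: Population-Genomic Scans and Demographic Inference for Crop
    De-Domestication
Version: 0.1.0
Authors@R:
    person("feralscan", "developers", email = "feralscan@example.org",
           role = c("aut", "cre"))
Description: Tools to study the evolution of weedy (feral) crop populations
    that arose from cultivated progenitors.  Provides sliding-window scans of
    nucleotide diversity, Tajima's D, Weir-Cockerham FST and observed
    heterozygosity from multi-sample VCF genotypes; Z(FST)-based detection of
    divergent genomic regions with gene mapping; a detector for Mb-scale
    regions under balancing selection (elevated Tajima's D and heterozygosity
    in the weedy population only); classification of weedy SNPs into standing
    variation versus new mutation with allele-frequency-differentiation
    summaries; site-frequency-spectrum construction with hypergeometric
    projection, folding and singleton masking; and comparison of four
    bottleneck/migration demographic models by simulation-based composite
    likelihood.  A forward Wright-Fisher simulator of the de-domestication
    scenario (cultivated source population, bottlenecked weedy offshoot,
    optional migration, directional and overdominant selection) generates
    fully specified test data with truth tables.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    VariantAnnotation,
    SummarizedExperiment,
    GenomicRanges,
    IRanges,
    S4Vectors,
    BiocGenerics
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
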