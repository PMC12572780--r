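Package: supergenescan
Title: Supergene Detection and Genotyping from Population Genomic Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects non-recombining supergene regions from biallelic SNP
    genotype matrices and assigns per-individual supergene genotypes, as in
    studies of social polymorphism in ants. Implements windowed
    Weir-Cockerham FST scans, rolling-window PCA genotype clustering,
    observed-heterozygosity and linkage-disequilibrium decay contrasts,
    extraction of fixed haplotype-diagnostic coding SNPs against a GFF3
    annotation, genotype-phenotype and genotype-colony association tests,
    and a parsimony estimator of matriline counts from haplodiploid
    microsatellite families. Ships a seeded synthetic-data generator that
    plants a known supergene so the full pipeline can be validated against
    ground truth at desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    vcfR,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    ape,
    mclust
Config/testthat/edition: 3
RoxygenNote: 7.3.3
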