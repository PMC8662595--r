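Package: clonalLOH
Title: Loss of Heterozygosity Detection and Mechanism Deconvolution in
    Clonal Hybrid Genomes
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for studying loss of heterozygosity (LOH) in asexual
    hybrid and polyploid genomes from exome genotype calls and read
    depth. Identifies species-diagnostic SNPs and the standard hybrid
    SNP categories, assigns individuals to multilocus clonal lineages
    from pairwise mismatch distances, calls LOH at diagnostic sites and
    tests its within-gene contiguity by permutation, deconvolves LOH
    mechanisms (gene conversion versus hemizygous or double deletion)
    by fitting fixed-mean Gamma mixtures to relative read-depth
    histograms, tests GC bias of the retained allele, and relates LOH
    to gene expression, allele-specific expression, dN/dS and gene-set
    membership. A synthetic hybrid-genome generator with a full ground
    truth ledger makes every stage testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    methods,
    VariantAnnotation,
    SummarizedExperiment,
    GenomicRanges,
    S4Vectors
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    withr
Config/testthat/edition: 3
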