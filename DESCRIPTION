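Package: poolSDP
Title: Selective DNA Pooling Association Scans from Pooled B-Allele
    Frequencies
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Genome-wide association scanning with selective DNA pooling:
    animals from the two phenotypic extremes of a trait distribution are
    pooled and genotyped on SNP arrays, and the pooled B-allele frequency
    (BAF) estimates the pool allele frequency at every marker. poolSDP
    implements tail selection of sires ranked on deregressed breeding
    values, even/odd sub-pooling with duplicate DNA pools and array
    replicates, quality control of pooled BAF measurements, the
    Dtest/SD(Dnull) chi-square(1) association test with Bonferroni
    family-wise control, assembly of candidate chromosome regions from
    significant SNPs, gene-proximity annotation, Q-Q and Manhattan
    reporting, and a synthetic-data generator that emulates the full
    pooling design for validation without raw array data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    IRanges,
    GenomicRanges,
    SummarizedExperiment,
    rtracklayer,
    yaml,
    nortest,
    ggplot2
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    withr
biocViews: GenomeWideAssociation, SNP, QualityControl, Software
Config/testthat/edition: 3
RoxygenNote: 7.3.3
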