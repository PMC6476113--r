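Package: pedQTL
Title: Variance-Component Heritability, Linkage and Association in Extended Pedigrees
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Quantitative-genetic analysis of traits measured in large
    multigenerational pedigrees. Computes pedigree kinship matrices,
    fits univariate and bivariate polygenic variance-component models by
    maximum likelihood (narrow-sense heritability, genetic and
    environmental correlations, pleiotropy tests), performs multipoint
    variance-component linkage scans over identity-by-descent sharing
    matrices with LOD scores and 1-LOD support intervals, and runs
    measured-genotype association of SNP dosages inside QTL regions with
    Bonferroni correction. A gene-dropping simulator generates pedigrees,
    recombinant genotypes, true IBD tracks and traits with known
    heritability so that every stage can be validated against truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    S4Vectors,
    SummarizedExperiment,
    data.table,
    jsonlite
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
biocViews: Genetics, SNP, Pedigree, QuantitativeTrait, LinkageAnalysis
RoxygenNote: 7.3.3
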