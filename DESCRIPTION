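Package: alfadiv
Title: Phenotypic and Genomic Diversity Analysis for Pooled-Sample Crop Panels
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline linking phenotypic diversity to genetic
    structure in panels of heterogeneous crop accessions genotyped as
    pooled samples (continuous allele frequencies), as in cultivated
    alfalfa diversity panels. Provides spatially adjusted genomic BLUP of
    field-trial phenotypes with a tensor-product B-spline surface, a
    VanRaden-style genomic relationship matrix adapted to pooled allele
    frequencies, phenotypic clustering by k-means/BIC and discriminant
    analysis of principal components, Mantel concordance between
    Mahalanobis phenotypic and Euclidean genetic distances, shadow-feature
    (Boruta-style) trait selection for genetic-group membership, and a
    per-SNP Nei FST scan with an empirical neutral null, FDR control and
    gene-window annotation. A synthetic-data generator reproduces the
    statistical structure of pooled-GBS allele frequencies and
    multi-trial field phenotypes so that every stage can be validated by
    parameter-recovery experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    splines,
    ranger,
    ape,
    GenomicRanges,
    IRanges,
    S4Vectors,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    MASS,
    vegan
Config/testthat/edition: 3
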