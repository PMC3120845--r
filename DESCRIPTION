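Package: hybridDMI
Title: Segregation Distortion and Dobzhansky-Muller Incompatibility
    Models in F2 Hybrid Crosses
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Analysis of hybrid breakdown in F2 intercrosses between
    diverged populations. Provides a genotype-table container for
    stage- and sex-structured F2 cohorts, single-marker segregation
    distortion tests against Mendelian 1:2:1 ratios, Haldane relative
    viabilities with delta-method uncertainty, sex-homogeneity and
    reciprocal-cross contingency tests, a two-locus test for deviations
    from independence with expectations adjusted for each locus's own
    distortion, exact enumeration of multi-locus genotype frequencies
    under configurable Dobzhansky-Muller incompatibility fitness
    schemes, maximum-likelihood fitness estimation, and a forward
    simulator of F2 cohorts with linkage, sexes, cytotypes and
    stage-specific viability selection.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    BiocGenerics,
    S4Vectors,
    SummarizedExperiment,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
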