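Package: ggxe
Title: Environment-Dependent Epistatic Networks and Genetic Capacitance in a
    Haploid Cross
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to dissect genotype-by-genotype-by-environment (G-by-G-by-E)
    interactions in a biparental haploid segregant panel. Provides a
    recombination-based simulator of haploid crosses with environment-dependent
    additive, epistatic and capacitor (hub-masking) architectures; ANOVA
    partitioning of growth variance into genotype and genotype-by-environment
    components; definition of an independent set of additive loci by linkage
    pruning and polygenic FDR selection; joint estimation of per-environment
    additive effects; likelihood-ratio tests for locus-by-environment and
    pairwise epistatic interactions; construction of the across-environment
    epistatic multigraph with hub detection and activity profiling; stratified
    narrow-sense heritability (capacitation) statistics; and population-level
    regressions linking network activity to additive-effect variance and total
    genetic variance.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    lmtest,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
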