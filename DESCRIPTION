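Package: polydiff
Title: Phenotypic and Genetic Differentiation in Mixed-Ploidy Microsatellite Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Population-genetic and phenotypic differentiation analysis for
    mixed-ploidy plant populations genotyped at microsatellite loci with
    ambiguous allele dosage. Provides dosage-ambiguous diversity statistics
    (polymorphism, allelic richness by hypergeometric rarefaction, observed
    and expected heterozygosity, PIC), Bruvo and Nei-Li genotype distances,
    the allele-size variance partition R_ST, nested random-effects variance
    components for morphometric traits with the phenotypic differentiation
    statistic P_ST and a heritability analogue, the P_ST-R_ST contrast
    classification, Duncan's multiple range test, principal coordinates and
    components analyses, neighbor-joining trees, bootstrap-supported
    phenotype clustering, Gaussian-mixture bimodality screening, and Mantel
    tests of isolation by distance. A synthetic-data module generates
    genotype, phenotype, and coordinate tables with the nested statistical
    structure the analysis assumes.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    geosphere,
    jsonlite,
    lme4,
    mclust,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    vegan,
    withr
Config/testthat/edition: 3
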