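Package: karyopairs
Title: Karyotype Composition and Multiple Sex Chromosome Systems in Mammals
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Comparative analysis of mammalian multiple sex chromosome
    systems (X1X2Y from Y-autosome fusions, XY1Y2 from X-autosome fusions)
    against karyotype composition measured as the fraction of acrocentric
    chromosomes. Provides karyotype arithmetic on diploid and fundamental
    numbers, exact nonparametric rank tests implemented from first
    principles (tie-aware Mann-Whitney U and an enumeration-exact Wilcoxon
    signed-rank test), detection of monophyletic same-system species
    clusters on a phylogeny, construction and validation of phylogenetically
    independent cross-system contrast pairs, a cluster-resampling scheme,
    and a synthetic-data generator that operationalizes centromere-associated
    female meiotic drive so the whole pipeline can be exercised and
    calibrated without external data. Ships a 41-species mammalian reference
    dataset, tree, and nine-pair configuration.
License: GPL-3
Encoding: UTF-8
Depends:
    R (>= 4.1)
Imports:
    ape,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    igraph,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
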