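Package: bearid
Title: Noninvasive Microsatellite Genotyping and Population Genetics for
    Brown Bears
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A pipeline for individual identification and population-genetic
    analysis of noninvasively collected microsatellite genotypes, built around
    the Grand Kackar Mountains (GKM) brown bear study system. Implements
    replicate-consensus genotyping with a two-round mismatch-and-discard rule,
    rule-based individual identification allowing up to two allele differences
    attributable to allelic dropout, stutter shift or missing data, per-locus
    diversity and genotyping-error statistics (observed/expected
    heterozygosity, Monte-Carlo exact Hardy-Weinberg tests, Chakraborty
    null-allele estimates, Weir-Cockerham F_IS, probability of identity),
    population-structure analyses (permutation-tested Weir-Cockerham F_ST,
    shared-allele and Kosman-Leonard distances, neighbor-joining trees, PCA,
    genetic dissimilarity versus geographic distance, a Gibbs sampler for the
    Bayesian admixture model), contingency analysis of genotyping success by
    hair-sample source and year, and a synthetic-data generator emulating the
    study's sampling design and error processes.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    geosphere,
    igraph,
    jsonlite,
    stats,
    utils,
    vegan
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
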