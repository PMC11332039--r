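Package: reefpopgen
Title: Population-Genomic Divergence and Genotype-Environment Association in Reef Corals
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An analysis pipeline for hierarchically structured coral
    population genomics: VCF import with minor-allele-frequency, quality,
    missingness and linkage-disequilibrium filters; clonal (multilocus
    lineage) detection and removal; genotype PCA and ancestry-coefficient
    clustering with a cross-entropy criterion for the number of ancestral
    populations; per-site and 500 bp windowed Weir-Cockerham FST with
    genomic-islands-of-differentiation calling; f2/f4 statistics with
    block-jackknife errors; isolation-by-distance and -environment Mantel
    tests on FST/(1-FST); redundancy-analysis genotype-environment
    association with Mahalanobis outlier detection; a hierarchical F-model
    scan for divergent selection with posterior-based FDR; and an
    enrichment synthesis joining temperature outliers, differentiation
    islands and selection calls. Includes a two-level Balding-Nichols
    simulator that emulates a multi-island, multi-species sampling design
    with environmental clines and clonal replicates.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    vcfR,
    vegan,
    geosphere
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
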