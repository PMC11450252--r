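Package: genoffset
Title: Invasion Genomics: Ancestry, Diversity, Genotype-Environment
    Association and Genetic Offset
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end toolkit for invasion population genomics from a
    filtered SNP matrix: genotype filtering (minor-allele count, site and
    individual missingness, one SNP per RAD locus), admixture ancestry
    estimation with masked-entry cross-validation, genotype PCA, pairwise
    Weir-Cockerham and population-specific (Weir-Goudet beta) Fst with
    neighbour-joining and multidimensional-scaling summaries, per-population
    diversity metrics (Ho, He, Pi, private alleles) with status-plus-ancestry
    models, a latent-factor genome scan and partial redundancy analysis with
    variance partitioning for genotype-environment association, and
    extrapolation of a genotype-environment index over climate rasters to
    compute genetic offsets of introduced populations relative to their
    Fst-nearest native source. A synthetic-data generator reproduces the
    statistical structure the analysis assumes (two divergent ancestral
    clusters with an admixture cline, environment-correlated adaptive loci,
    founder-effect introductions) so every stage is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    ape,
    dplyr,
    emmeans,
    generics,
    ggplot2,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    vcfR,
    vegan,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
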