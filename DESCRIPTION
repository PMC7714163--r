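Package: deltascan
Title: Information-Theoretic Dependency Scans for Genotype-Phenotype Cohorts
Version: 0.1.0
Authors@R:
    person("Cohort Methods", "Maintainers", email = "maintainers@example.org",
           role = c("aut", "cre"))
Description: Detects pairwise and three-way (pleiotropic) dependencies between
    genetic variants and discrete phenotypes using exact plug-in information
    measures: mutual information, interaction information, asymmetric deltas
    and the symmetric delta. Includes a synthetic cohort generator
    (Hardy-Weinberg genotypes with group-specific allele frequencies, planted
    additive and XOR-pleiotropic effects, Gompertz-type growth trajectories),
    genotype/phenotype preprocessing with mutual-information SNP collapsing and
    integer-programming subset selection under missingness, a nonlinear
    mixed-effects head-circumference growth model yielding per-subject growth
    phenotypes, pooled permutation p-values with family-wise error rates,
    ethnicity-standardized mutual information, and Kolmogorov-Smirnov
    genotype-stratified phenotype profiling.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    nlme,
    jsonlite,
    optparse
Suggests:
    testthat (>= 3.0.0),
    withr,
    rtracklayer,
    GenomicRanges,
    VariantAnnotation,
    SummarizedExperiment,
    IRanges
Config/testthat/edition: 3
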