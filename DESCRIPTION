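Package: mvassoc
Title: Bayesian Model Comparison for Association of a Genetic Variant with
    Multiple Related Phenotypes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for assessing association between a single genetic variant
    and several related quantitative phenotypes by Bayesian model comparison
    and model averaging over partition models. Each phenotype is classified as
    unassociated, directly associated, or indirectly associated with genotype;
    per-partition Bayes factors are computed analytically under conjugate
    Bayesian multivariate regression (matrix-t marginal likelihoods), with a
    limiting prior that connects them to classical likelihood-ratio and MANOVA
    statistics. Supports exact sufficient-statistic input from raw data as
    well as approximate input from GWAS summary statistics (Z-scores, minor
    allele frequency, sample size), empirical-Bayes estimation of partition
    and effect-size weights by EM, a two-stage genome scan with distance
    pruning, and simulation tools for power and size evaluation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    MASS
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate:
    'partitions.R'
    'bmvr.R'
    'sufficient.R'
    'inference.R'
    'eb.R'
    'simulate.R'
    'io.R'
    'scan.R'
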