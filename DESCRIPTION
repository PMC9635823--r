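Package: paleokin
Title: Population-Genetic and Kinship Inference for Low-Coverage Ancient DNA
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing pseudo-haploid genotypes from low-coverage
    ancient genomes: EIGENSTRAT input/output and SNP-panel construction,
    outgroup f3- and D-statistics with weighted block-jackknife standard
    errors, qpAdm-style admixture-weight estimation against a reference set,
    READ-style pairwise-mismatch kinship with separate autosomal and
    X-chromosomal estimates, analytic pedigree kinship coefficients
    (autosomal and X) with relationship-hypothesis enumeration and ranking,
    multidimensional scaling on (1 - f3) dissimilarities, isolation-by-distance
    regression, permutation tests for burial and diversity structure,
    read-count genetic sexing, calibrated-date resampling, and a synthetic-data
    generator with full truth tables for validating every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    geosphere,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
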