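Package: chalcomp
Title: Phylogenetic Comparative Analysis of Host Use and Morphology in
    Parasitoid Wasps
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for phylogenetic comparative analysis of morphology and
    host use in parasitoid wasps (Chalcidoidea) and similar clades: tree
    assembly from heterogeneous sources (sibling-tip insertion, grafting of
    intrageneric subtrees with branch-length rescaling, penalized-likelihood
    ultrametricization), phylogenetic signal for continuous traits (Pagel's
    lambda by maximum likelihood) and binary traits (the Fritz-Purvis D
    statistic with permutation and Brownian-threshold nulls), phylogenetic
    generalized least squares regression with maximum-likelihood lambda,
    AIC-based model selection and evidence ratios, Fitch parsimony counts of
    trait origins, and a synthetic-data generator that emulates the study
    design so every stage can be exercised without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    dplyr,
    generics,
    ggplot2,
    phytools,
    purrr,
    rlang,
    stats,
    tibble,
    utils,
    yaml
Suggests:
    jsonlite,
    nlme,
    phangorn,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
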