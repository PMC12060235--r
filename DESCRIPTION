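Package: clonalpred
Title: Clonal Identity Verification and Genomic Prediction for
    Vegetatively Propagated Breeding Programmes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for low-input breeding analysis of clonally propagated
    trees genotyped with a biallelic SNP array. Verifies ramet identity
    against clone consensus genotypes and estimates per-sample and per-SNP
    genotyping error rates from clonal replicates, collapses multilocus
    genotypes into lineages with an automatically predicted similarity
    cutoff, computes the VanRaden genomic relationship matrix with
    inbreeding and F_IS summaries, corrects repeated-measure cone
    phenotypes for masting years and allometry to obtain clonal BLUPs and
    broad-sense heritability, and fits GBLUP genomic prediction models
    with k-fold cross-validated predictive ability and permutation
    significance. Includes a synthetic clone/ramet cohort generator with a
    full truth record for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    lme4,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    vcfR
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
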