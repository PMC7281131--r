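Package: tnhf
Title: Genetic-Ancestry-Associated Expression and Heterogenic TNBC Subtyping
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying African-ancestry-associated gene expression in
    triple-negative breast cancer (TNBC). Implements supervised maximum-likelihood
    estimation of individual admixture proportions from biallelic SNV dosages
    against fixed reference-population allele frequencies (EM on a binomial
    likelihood), a gene-by-gene linear-regression screen for association between
    expression and continuous ancestry proportions with Benjamini-Hochberg FDR
    control, a self-reported-race two-group contrast, and the TNHF (Triple
    Negative Hetero-Fluid) subtyping method: rank-based signature scoring with
    minimum-rank tie handling, correlation scores for the four valid TNBC
    subtypes (BL1, BL2, LAR, M), reassignment of retired IM/MSL calls, and
    Ward clustering of the correlation-score matrix into heterogenic category
    nodes with +/-/IND status labels. A synthetic-cohort generator with known
    ground truth (Balding-Nichols reference panels, admixed genotypes, planted
    ancestry-effect genes, planted subtype signatures, negative-binomial count
    noise) supports end-to-end validation of every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    tibble,
    dplyr,
    tidyr,
    readr,
    rlang,
    ggplot2,
    generics,
    jsonlite,
    vcfR,
    fgsea
Suggests:
    testthat (>= 3.0.0),
    mclust,
    withr
Config/testthat/edition: 3
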