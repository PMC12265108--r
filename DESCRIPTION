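Package: cisegene
Title: Ultrafast cis-eGene Identification with Permutation and Contrastive FDR Control
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Identifies cis-eGenes (genes whose expression is associated with at
    least one local genetic variant) from an expression matrix, genotype dosages
    and covariates. Implements two gene-level testing variants built on the
    partial-correlation/P-value correspondence in linear models: a standard
    permutation variant (direct permutation scheme with proportion-based gene
    P values and Storey q-values) and a Clipper variant that uses a contrastive,
    P-value-free FDR estimator requiring as little as one permutation for large
    sample sizes. Also provides comparator gene-level procedures (beta
    approximation of permutation minima, effective-number-of-tests Bonferroni,
    Simes' rule, and a naive all-pairs caller), expression-PC covariate
    selection by parallel analysis or the elbow method, single-cell pseudobulk
    preparation, and a synthetic-data generator with ground-truth FDR/power
    evaluation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    utils,
    vcfR
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
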