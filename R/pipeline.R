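#' Run the full eGene identification pipeline from files
#'
#' Reads the expression BED, genotypes (VCF or dosage TSV, auto-detected by
#' extension) and optional covariates; intersects samples (expression order
#' preserved); extracts and filters cis blocks; optionally appends inferred
#' expression-PC covariates; runs the chosen gene-level method and FDR
#' procedure; and writes the per-gene results TSV. Stage-by-stage sample,
#' gene and SNP counts are logged via `message()`.
#'
#' @param expression Path to a FastQTL-style expression BED.
#' @param genotypes Path to a VCF (`.vcf`/`.vcf.gz`) or dosage TSV.
#' @param covariates Optional path to a covariate TSV.
#' @param method `"auto"` (clipper when n > 450, else standard),
#'   `"standard"`, `"clipper"`, `"beta"`, `"eigenmt"`, `"simes"` or
#'   `"naive"`.
#' @param B Number of permutations (`NULL` = variant default).
#' @param target_fdr Target FDR (default 0.05).
#' @param window Cis window half-width in bp.
#' @param maf_min,ma_samples_min SNP filters.
#' @param n_pcs Number of expression PCs to append as inferred covariates:
#'   an integer, `"be"`, `"elbow"`, or `NULL` for none.
#' @param fdr_procedure FDR procedure for P-value based methods.
#' @param seed Master seed.
#' @param out Optional path for the results TSV.
#' @return A tibble of per-gene results (invisibly the `egene_fit` is
#'   attached as attribute `"fit"` for the model-based methods).
#' @export
run_pipeline <- function(expression, genotypes, covariates = NULL,
                         method = c("auto", "standard", "clipper", "beta",
                                    "eigenmt", "simes", "naive"),
                         B = NULL, target_fdr = 0.05, window = 1e6L,
                         maf_min = 0.01, ma_samples_min = 10L,
                         n_pcs = NULL,
                         fdr_procedure = c("storey", "bh", "by"),
                         seed = 1L, out = NULL) {
  method <- match.arg(method)
  fdr_procedure <- match.arg(fdr_procedure)
  expr <- read_expression_bed(expression)
  geno <- if (grepl("\\.vcf(\\.gz)?$", genotypes))
    read_genotype_vcf(genotypes) else read_dosage_tsv(genotypes)
  message(sprintf("expression: %d samples x %d genes; genotypes: %d samples x %d SNPs",
                  nrow(expr$values), ncol(expr$values),
                  nrow(geno$dosages), ncol(geno$dosages)))
  covs <- if (!is.null(covariates))
    read_covariates_tsv(covariates, sample_ids(expr)) else NULL
  aligned <- align_samples(expr, geno, covs)
  expr <- aligned$expr; geno <- aligned$blocks; covs <- aligned$covariates
  n <- nrow(expr$values)
  message(sprintf("after sample intersection: n = %d", n))
  if (method == "auto") {
    method <- if (n > 450L) "clipper" else "standard"
    message("method 'auto' resolved to '", method, "' (n ",
            if (n > 450L) ">" else "<=", " 450)")
  }
  if (!is.null(n_pcs)) {
    k <- if (identical(n_pcs, "be")) choose_k_be(expr, seed = seed)
         else if (identical(n_pcs, "elbow")) choose_k_elbow(expr)
         else as.integer(n_pcs)
    message("appending ", k, " expression PC(s) as inferred covariates")
    if (k > 0L) {
      pcs <- expression_pcs(expr, k)
      base <- if (is.null(covs)) NULL else covs$values
      covs <- covariate_matrix(cbind(base, pcs), sample_ids(expr))
    }
  }
  blocks <- build_cis_blocks(expr, geno, window, maf_min, ma_samples_min)
  qj <- vapply(blocks, function(b) ncol(b$dosages), integer(1))
  message(sprintf("cis blocks: %d/%d genes with >= 1 SNP; mean SNPs/gene %.1f; K = %d",
                  sum(qj > 0), length(qj), mean(qj),
                  if (is.null(covs)) 0L else ncol(covs$values)))
  variant <- if (method == "clipper") "clipper" else "standard"
  config <- method_config(variant, B = B, target_fdr = target_fdr,
                          cis_window_bp = window, maf_min = maf_min,
                          ma_samples_min = ma_samples_min, seed = seed,
                          fdr_procedure = fdr_procedure)
  if (sum(qj > 0) == 0L) {
    warning("zero genes with cis SNPs after filtering; writing header-only ",
            "results", call. = FALSE)
    res <- tibble(gene_id = character(), lead_snp = character(),
                  statistic = numeric(), gene_pvalue = numeric(),
                  q_value = numeric(), is_egene = logical())
    if (!is.null(out)) write_results_tsv(res, out)
    return(res)
  }
  fit <- switch(method,
    standard = run_standard(expr, blocks, covs, config),
    clipper = run_clipper(expr, blocks, covs, config),
    beta = ,
    eigenmt = ,
    simes = run_comparator(expr, blocks, covs, method, config),
    naive = NULL)
  if (method == "naive") {
    pairs <- nominal_pass(expr, blocks, covs)
    calls <- naive_matrixeqtl_egenes(pairs, target_fdr)
    best <- dplyr::slice_min(dplyr::group_by(pairs, .data$gene_id),
                             .data$p, n = 1, with_ties = FALSE)
    res <- dplyr::left_join(calls, best, by = "gene_id")
    res <- tibble(gene_id = res$gene_id, lead_snp = res$snp_id,
                  statistic = abs(res$r), gene_pvalue = res$p,
                  q_value = NA_real_, is_egene = res$is_egene)
  } else {
    res <- fit$results
  }
  message(sum(res$is_egene, na.rm = TRUE), " eGene(s) at target FDR ",
          target_fdr)
  if (!is.null(out)) {
    if (method == "naive") {
      tmp <- res
      tmp$q_value <- ifelse(is.na(tmp$q_value), 1, tmp$q_value)
      write_results_tsv(tmp, out)
    } else {
      write_results_tsv(res, out)
    }
    message("results written to ", out)
  }
  if (!is.null(fit)) attr(res, "fit") <- fit
  res
}
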