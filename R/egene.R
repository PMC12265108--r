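#' Generate the shared permutation stream
#'
#' One uniform random permutation of the sample rows per replicate `b`,
#' reproducible from the master seed. The same permutation is applied to all
#' genes within a replicate — this is what allows the per-gene statistics to
#' be computed with matrix products instead of per-gene loops, and it
#' preserves each gene's marginal permutation null.
#'
#' @param n Number of samples.
#' @param B Number of permutations.
#' @param seed Integer master seed.
#' @return Integer matrix `n x B`; column `b` is the permutation for
#'   replicate `b`.
#' @export
permutation_indices <- function(n, B, seed) {
  stopifnot(B >= 1L, n >= 2L)
  old <- globalenv()$.Random.seed
  on.exit({
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  vapply(seq_len(B), function(b) sample.int(n), integer(n))
}

# Shared scan: per gene, the observed max-|partial correlation| statistic and
# B background statistics. `order` selects the variant-defining step order:
#   "permute_first":   permute raw expression, then residualize (standard)
#   "residualize_first": residualize once, then permute residuals (clipper)
# Genotype residuals are computed once and held fixed across replicates.
egene_scan <- function(expr, blocks, X, B, seed,
                       order = c("permute_first", "residualize_first")) {
  order <- match.arg(order)
  Y <- expr$values
  n <- nrow(Y)
  ids <- gene_ids(expr)
  Xv <- if (inherits(X, "CovariateMatrix")) X$values else X
  if (is.null(Xv)) Xv <- matrix(0, n, 0L)
  K <- ncol(Xv)
  if (n - K - 2L < 1L) stop("too few samples for ", K, " covariates")
  basis <- resid_basis(Xv)
  Q <- basis$Q
  perms <- permutation_indices(n, B, seed)
  E_obs <- Y - Q %*% crossprod(Q, Y)   # residualized observed expression

  t_exp <- rep(NA_real_, length(ids))
  lead <- rep(NA_character_, length(ids))
  q_j <- integer(length(ids))
  t_bg <- matrix(NA_real_, length(ids), B)
  skipped <- character(0)

  for (j in seq_along(ids)) {
    g <- ids[j]
    b <- blocks[[g]]
    if (is.null(b) || ncol(b$dosages) == 0L) next
    G <- b$dosages - Q %*% crossprod(Q, b$dosages)
    gs <- standardize_resid(G)
    q_j[j] <- ncol(gs$values)
    if (q_j[j] == 0L) next
    e_obs <- E_obs[, j]
    en <- sqrt(sum(e_obs^2))
    if (en <= 1e-12) {
      skipped <- c(skipped, g)
      next
    }
    r_obs <- abs(as.numeric(crossprod(gs$values, e_obs / en)))
    best <- which.max(r_obs)
    t_exp[j] <- r_obs[best]
    lead[j] <- b$snp_ids[!gs$dropped][best]
    if (order == "permute_first") {
      # raw column permuted per replicate, then residualized and rescaled
      Yp <- matrix(Y[, j][perms], n, B)
      Ep <- Yp - Q %*% crossprod(Q, Yp)
      norms <- sqrt(colSums(Ep^2))
      norms[norms <= 1e-12] <- NA_real_
      R <- abs(crossprod(gs$values, Ep))
      t_bg[j, ] <- apply(R, 2, max) / norms
    } else {
      # residuals permuted; norm is permutation-invariant
      Ep <- matrix((e_obs / en)[perms], n, B)
      R <- abs(crossprod(gs$values, Ep))
      t_bg[j, ] <- apply(R, 2, max)
    }
  }
  if (length(skipped))
    warning("gene(s) with degenerate expression residuals excluded: ",
            paste(head(skipped, 5), collapse = ", "), call. = FALSE)
  list(gene_id = ids, t_exp = t_exp, t_bg = t_bg, lead_snp = lead, q_j = q_j,
       n = n, K = K, tested = !is.na(t_exp))
}

finish_fit <- function(scan, results, method, config) {
  structure(list(results = results, method = method, config = config,
                 n = scan$n, K = scan$K, B = ncol(scan$t_bg),
                 stats = scan), class = "egene_fit")
}

#' Standard permutation variant (direct scheme + proportions)
#'
#' For each gene, the observed statistic is the maximum absolute partial
#' correlation over its cis SNPs. For each of `B` replicates the raw
#' expression column is permuted first and then residualized (matching the
#' FastQTL direct permutation scheme), and the same statistic is recomputed
#' against the fixed genotype residuals. The gene-level P value is the
#' proportion `(1 + #\{b: T_bg >= T_exp\}) / (B + 1)`; q-values follow the
#' configured FDR procedure (Storey by default) and genes with
#' `q <= target_fdr` are called eGenes.
#'
#' @param expr An [expression_matrix()].
#' @param blocks Named list of filtered [cis_genotype_block()]s.
#' @param X A [covariate_matrix()] or `NULL`.
#' @param config A [method_config()]; `config$B` permutations (default 1000).
#' @return An `egene_fit`; `tidy()` gives the per-gene table. Genes with no
#'   SNPs after filtering are excluded from testing and from the
#'   multiple-testing denominator and reported with `NA` results.
#' @export
run_standard <- function(expr, blocks, X = NULL,
                         config = method_config("standard")) {
  if (config$B < 100L)
    warning("B = ", config$B, " is low for the standard variant",
            call. = FALSE)
  scan <- egene_scan(expr, blocks, X, config$B, config$seed, "permute_first")
  p <- proportions_pvalue(scan$t_exp, scan$t_bg)
  results <- assemble_pvalue_results(scan, p, config,
                                     method = "standard_proportions")
  finish_fit(scan, results, "standard", config)
}

# permutation proportions formula, rowwise
proportions_pvalue <- function(t_exp, t_bg) {
  B <- ncol(t_bg)
  exceed <- rowSums(t_bg >= t_exp, na.rm = TRUE)
  ifelse(is.na(t_exp), NA_real_, (1 + exceed) / (B + 1))
}

assemble_pvalue_results <- function(scan, p, config, method) {
  tested <- scan$tested & !is.na(p)
  q <- rep(NA_real_, length(p))
  q[tested] <- apply_fdr_procedure(p[tested], config$fdr_procedure)
  tibble(gene_id = scan$gene_id, lead_snp = scan$lead_snp,
         statistic = scan$t_exp, n_snps = scan$q_j, gene_pvalue = p,
         q_value = q, is_egene = call_egenes(q, config$target_fdr),
         method = method)
}

#' Clipper (contrastive) variant
#'
#' Expression is residualized once; each replicate permutes the residuals
#' (one shared permutation per replicate). Per gene the contrast score
#' `T_exp - max_b T_bg` is thresholded by the contrastive FDR estimator
#' ([clipper_threshold()]) — no P values are computed. Recommended for large
#' sample sizes (n > 450) with `B = 1` or `B` in 20..100.
#'
#' @inheritParams run_standard
#' @param config A [method_config()]; `config$B` defaults to 1.
#' @return An `egene_fit` whose results carry `contrast_score` instead of
#'   `gene_pvalue`.
#' @export
run_clipper <- function(expr, blocks, X = NULL,
                        config = method_config("clipper")) {
  if (nrow(expr$values) <= 450L)
    warning("the Clipper variant is recommended for sample sizes > 450; ",
            "n = ", nrow(expr$values), call. = FALSE)
  scan <- egene_scan(expr, blocks, X, config$B, config$seed,
                     "residualize_first")
  ct <- clipper_threshold(scan$t_exp, scan$t_bg, config$target_fdr)
  results <- tibble(gene_id = scan$gene_id, lead_snp = scan$lead_snp,
                    statistic = scan$t_exp, n_snps = scan$q_j,
                    contrast_score = ct$contrast_scores,
                    q_value = ct$q_values,
                    is_egene = !is.na(ct$q_values) &
                      call_egenes(ct$q_values, config$target_fdr),
                    method = "clipper")
  fit <- finish_fit(scan, results, "clipper", config)
  fit$cutoff <- ct$cutoff
  fit
}

#' @export
print.egene_fit <- function(x, ...) {
  cat(sprintf(
    "<egene_fit> method %s: n = %d, %d genes tested, B = %d, %d eGene(s) at FDR %.3g\n",
    x$method, x$n, sum(x$stats$tested), x$B,
    sum(x$results$is_egene, na.rm = TRUE), x$config$target_fdr))
  invisible(x)
}

#' Tidy per-gene results of an eGene fit
#'
#' @param x An `egene_fit`.
#' @param ... Unused.
#' @return A tibble with one row per gene.
#' @method tidy egene_fit
#' @export
tidy.egene_fit <- function(x, ...) x$results

#' One-row summary of an eGene fit
#'
#' @param x An `egene_fit`.
#' @param ... Unused.
#' @return A tibble with the sample size, gene counts, permutation count and
#'   number of eGenes.
#' @method glance egene_fit
#' @export
glance.egene_fit <- function(x, ...) {
  tibble(method = x$method, n = x$n, n_covariates = x$K,
         n_genes = nrow(x$results), n_tested = sum(x$stats$tested),
         mean_n_snps = mean(x$stats$q_j[x$stats$tested]), B = x$B,
         target_fdr = x$config$target_fdr,
         n_egenes = sum(x$results$is_egene, na.rm = TRUE))
}

#' Plot an eGene fit
#'
#' For the Clipper variant, a histogram of contrast scores with the FDR
#' cutoff; for P-value based methods, a histogram of gene-level P values.
#'
#' @param object An `egene_fit`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot egene_fit
#' @export
autoplot.egene_fit <- function(object, ...) {
  res <- object$results
  if ("contrast_score" %in% names(res)) {
    p <- ggplot2::ggplot(dplyr::filter(res, !is.na(.data$contrast_score)),
                         ggplot2::aes(x = .data$contrast_score)) +
      ggplot2::geom_histogram(bins = 50, fill = "grey40") +
      ggplot2::labs(x = "contrast score", y = "genes",
                    title = "Contrast scores (null genes symmetric about 0)")
    if (is.finite(object$cutoff))
      p <- p + ggplot2::geom_vline(xintercept = object$cutoff,
                                   linetype = "dashed", colour = "red")
    p
  } else {
    ggplot2::ggplot(dplyr::filter(res, !is.na(.data$gene_pvalue)),
                    ggplot2::aes(x = .data$gene_pvalue)) +
      ggplot2::geom_histogram(boundary = 0, bins = 40, fill = "grey40") +
      ggplot2::labs(x = "gene-level P value", y = "genes")
  }
}

#' @export
plot.egene_fit <- function(x, ...) print(autoplot(x, ...))
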