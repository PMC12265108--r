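#' Residualize a matrix against covariates
#'
#' Removes the least-squares projection of each column of `M` onto
#' `[1 | X]` (intercept plus covariates). All gene-level statistics in this
#' package are partial correlations computed on such residuals, so the
#' degrees of freedom for the corresponding SNP t-test are
#' `df = n - K - 2` (intercept, K covariates, and the SNP itself).
#'
#' @param M Numeric matrix `n x m` (columns are genes or SNPs).
#' @param X A [covariate_matrix()], a plain numeric matrix, or `NULL` for
#'   intercept-only residualization (column centering).
#' @return A list of class `ResidualizedMatrix` with `values` (the residuals)
#'   and `df_resid = n - K - 2`.
#' @export
residualize <- function(M, X = NULL) {
  M <- as.matrix(M)
  if (inherits(X, "CovariateMatrix")) X <- X$values
  n <- nrow(M)
  if (is.null(X)) X <- matrix(0, n, 0L)
  X <- as.matrix(X)
  stopifnot(nrow(X) == n)
  basis <- resid_basis(X)
  structure(list(values = M - basis$Q %*% crossprod(basis$Q, M),
                 df_resid = n - ncol(X) - 2L),
            class = "ResidualizedMatrix")
}

# orthonormal basis of span([1 | X]); errors on rank deficiency
resid_basis <- function(X) {
  D <- cbind(`(intercept)` = 1, X)
  qx <- qr(D)
  if (qx$rank < ncol(D)) {
    bad <- colnames(D)[qx$pivot[-seq_len(qx$rank)]]
    if (is.null(bad) || !length(bad)) bad <- "unknown"
    stop("[intercept | covariates] is rank deficient; collinear column(s): ",
         paste(bad, collapse = ", "))
  }
  list(Q = qr.Q(qx), rank = qx$rank)
}

# scale residual columns to unit Euclidean norm; returns the rescaled matrix
# plus a logical vector marking dropped (zero-variance) columns
standardize_resid <- function(R, tol = 1e-12) {
  norms <- sqrt(colSums(R^2))
  zero <- norms <= tol * max(1, if (length(norms)) max(norms) else 0)
  out <- sweep(R[, !zero, drop = FALSE], 2, norms[!zero], "/")
  list(values = out, dropped = zero)
}

#' Maximum absolute partial correlation between a gene and its cis SNPs
#'
#' Both inputs must be residualized against the same covariates. Zero-variance
#' residual SNP columns are dropped before taking the maximum.
#'
#' @param expr_resid Numeric vector: the gene's residualized expression.
#' @param geno_resid Numeric matrix `n x q`: residualized dosages.
#' @return List with `t` (max \eqn{|r|}), `lead_snp` (column index into the
#'   original matrix; first index on ties). If the expression residual or all
#'   SNP residuals are degenerate, `t` is `NA` and the gene should be
#'   excluded.
#' @export
max_abs_corr <- function(expr_resid, geno_resid) {
  if (inherits(expr_resid, "ResidualizedMatrix")) expr_resid <- expr_resid$values
  if (inherits(geno_resid, "ResidualizedMatrix")) geno_resid <- geno_resid$values
  e <- as.numeric(expr_resid)
  G <- as.matrix(geno_resid)
  en <- sqrt(sum(e^2))
  if (en <= 1e-12) return(list(t = NA_real_, lead_snp = NA_integer_))
  gs <- standardize_resid(G)
  if (ncol(gs$values) == 0L) return(list(t = NA_real_, lead_snp = NA_integer_))
  r <- abs(as.numeric(crossprod(gs$values, e / en)))
  best <- which.max(r)
  list(t = r[best], lead_snp = which(!gs$dropped)[best])
}

#' Convert a partial correlation to a two-sided linear-model P value
#'
#' Uses the one-to-one correspondence between the absolute partial correlation
#' of a SNP with expression (both residualized on the covariates) and the
#' two-sided P value of the SNP coefficient in the linear model
#' `y ~ 1 + snp + covariates`: `t = r * sqrt(df) / sqrt(1 - r^2)` with
#' `df = n - K - 2`.
#'
#' @param r Partial correlation(s) in `[-1, 1]` (vectorized).
#' @param n Sample size.
#' @param K Number of covariates (excluding the intercept).
#' @return Two-sided P value(s) in `[0, 1]`; `|r| = 1` maps to 0.
#' @export
corr_to_pvalue <- function(r, n, K = 0L) {
  df <- n - K - 2L
  if (df < 1L) stop("degrees of freedom n - K - 2 = ", df, " must be >= 1")
  if (any(abs(r) > 1 + 1e-8, na.rm = TRUE)) stop("|r| must be <= 1")
  r <- pmin(1, pmax(-1, r))
  p <- ifelse(abs(r) >= 1, 0,
              2 * pt(-abs(r) * sqrt(df) / sqrt(1 - r^2), df = df))
  pmin(1, p)
}

#' All-pairs nominal association scan
#'
#' Matrix-eQTL-style pass: for every retained gene-SNP pair, the partial
#' correlation (expression and dosage both residualized on the covariates)
#' and its linear-model P value.
#'
#' @param expr An [expression_matrix()].
#' @param blocks Named list of [cis_genotype_block()]s (one per gene; genes
#'   without a block or with zero SNPs are skipped).
#' @param X A [covariate_matrix()] or `NULL`.
#' @return A tibble with columns `gene_id`, `snp_id`, `r`, `p`.
#' @export
nominal_pass <- function(expr, blocks, X = NULL) {
  n <- nrow(expr$values)
  K <- if (is.null(X)) 0L else ncol(if (inherits(X, "CovariateMatrix")) X$values else X)
  E <- residualize(expr$values, X)$values
  ids <- gene_ids(expr)
  rows <- purrr::map(ids, function(g) {
    b <- blocks[[g]]
    if (is.null(b) || ncol(b$dosages) == 0L) return(NULL)
    G <- residualize(b$dosages, X)$values
    gs <- standardize_resid(G)
    e <- E[, g]
    en <- sqrt(sum(e^2))
    if (en <= 1e-12) return(NULL)
    r <- as.numeric(crossprod(gs$values, e / en))
    tibble(gene_id = g, snp_id = b$snp_ids[!gs$dropped], r = r,
           p = corr_to_pvalue(r, n, K))
  })
  dplyr::bind_rows(rows)
}
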