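#' Beta-approximation gene-level P value
#'
#' Fits a Beta(a, b) distribution by maximum likelihood (moment-matched
#' start) to the per-permutation minimum P values and evaluates its CDF at
#' the observed minimum. This interpolates a higher-resolution gene-level P
#' value than the raw proportion when `B` is moderate.
#'
#' @param p_min_obs Observed minimum nominal P value across the gene's SNPs.
#' @param p_min_perm Numeric vector (length `B`) of minimum P values from
#'   permuted data; values must lie strictly inside (0, 1).
#' @return List with `pvalue`, and the `BetaFit` (`a`, `b`, `converged`).
#'   On non-convergence the proportions formula is used with a warning.
#' @export
beta_gene_pvalue <- function(p_min_obs, p_min_perm) {
  x <- p_min_perm
  stopifnot(length(x) >= 2)
  eps <- 1e-12
  x <- pmin(1 - eps, pmax(eps, x))
  mu <- mean(x); v <- var(x)
  # method-of-moments start
  common <- mu * (1 - mu) / max(v, 1e-12) - 1
  start <- log(pmax(c(mu * common, (1 - mu) * common), 1e-3))
  nll <- function(par) {
    a <- exp(par[1]); b <- exp(par[2])
    -sum(stats::dbeta(x, a, b, log = TRUE))
  }
  opt <- tryCatch(optim(start, nll, method = "Nelder-Mead"),
                  error = function(e) NULL)
  converged <- !is.null(opt) && opt$convergence == 0 &&
    all(is.finite(opt$par))
  if (!converged) {
    warning("beta fit did not converge; falling back to proportions",
            call. = FALSE)
    B <- length(p_min_perm)
    return(list(pvalue = (1 + sum(p_min_perm <= p_min_obs)) / (B + 1),
                fit = list(a = NA_real_, b = NA_real_, converged = FALSE)))
  }
  a <- exp(opt$par[1]); b <- exp(opt$par[2])
  list(pvalue = pbeta(p_min_obs, a, b),
       fit = list(a = a, b = b, converged = TRUE))
}

#' eigenMT-style gene-level P value
#'
#' Bonferroni correction with the *effective* number of local SNPs: SNPs are
#' partitioned into consecutive windows of at most `window` SNPs; within each
#' window the correlation matrix of the dosages is eigendecomposed and the
#' window's effective test count is the smallest `k` whose top-`k`
#' eigenvalues explain at least `var_threshold` of the total variance.
#' `M_eff` is the sum over windows and the gene-level P value is
#' `min(1, p_min * M_eff)`.
#'
#' @param block A [cis_genotype_block()] (post filtering).
#' @param p_min Minimum nominal P value across the gene's SNPs.
#' @param var_threshold Fraction of variance to capture (default 0.99).
#' @param window Maximum SNPs per window (default 200).
#' @return List with `pvalue` and `m_eff`.
#' @export
eigenmt_gene_pvalue <- function(block, p_min, var_threshold = 0.99,
                                window = 200L) {
  d <- block$dosages
  keep <- apply(d, 2, sd) > 0
  d <- d[, keep, drop = FALSE]
  q <- ncol(d)
  if (q == 0L) stop("no polymorphic SNPs in block for gene ", block$gene_id)
  starts <- seq(1L, q, by = window)
  m_eff <- sum(vapply(starts, function(s) {
    w <- d[, s:min(q, s + window - 1L), drop = FALSE]
    if (ncol(w) == 1L) return(1)
    ev <- eigen(cor(w), symmetric = TRUE, only.values = TRUE)$values
    ev <- pmax(ev, 0)
    as.numeric(which(cumsum(ev) / sum(ev) >= var_threshold)[1])
  }, numeric(1)))
  list(pvalue = min(1, p_min * m_eff), m_eff = m_eff)
}

#' Simes' rule gene-level P value
#'
#' `min_k m * p_(k) / k`, capped at 1.
#'
#' @param p Numeric vector of the gene's per-SNP nominal P values.
#' @return The Simes combined P value.
#' @export
simes_gene_pvalue <- function(p) {
  m <- length(p)
  stopifnot(m >= 1)
  min(1, min(m * sort(p) / seq_len(m)))
}

#' Naive all-pairs eGene calls (Matrix eQTL style)
#'
#' BH across all gene-SNP pairs at `target_fdr`; a gene is called an eGene
#' if at least one of its pairs is significant. This treats every pair as an
#' equal testing unit and does not control the gene-level FDR — it is
#' included as the miscalibrated baseline.
#'
#' @param pairs Tibble from [nominal_pass()] (columns `gene_id`, `p`).
#' @param target_fdr Target FDR applied at the pair level.
#' @return Tibble with `gene_id` and logical `is_egene`, one row per gene
#'   present in `pairs`.
#' @export
naive_matrixeqtl_egenes <- function(pairs, target_fdr = 0.05) {
  pairs <- dplyr::mutate(pairs, .pair_q = bh_adjust(.data$p))
  dplyr::summarise(dplyr::group_by(pairs, .data$gene_id),
                   is_egene = any(.data$.pair_q <= target_fdr),
                   .groups = "drop")
}

#' Run a P-value based comparator end to end
#'
#' Shared driver for the beta-approximation, eigenMT-style and Simes
#' gene-level procedures: computes per-gene P values, applies the configured
#' FDR procedure, and returns an `egene_fit`. The beta method reuses the
#' standard variant's permutation scan (converting background statistics to
#' per-permutation minimum P values via the partial-correlation
#' correspondence); eigenMT and Simes need no permutations.
#'
#' @param expr An [expression_matrix()].
#' @param blocks Named list of filtered [cis_genotype_block()]s.
#' @param X A [covariate_matrix()] or `NULL`.
#' @param method One of `"beta"`, `"eigenmt"`, `"simes"`.
#' @param config A [method_config()] (the `variant` field is ignored).
#' @param scan Optional precomputed scan from a standard-variant run with the
#'   same seed (beta method only; avoids re-permuting).
#' @return An `egene_fit`.
#' @export
run_comparator <- function(expr, blocks, X = NULL,
                           method = c("beta", "eigenmt", "simes"),
                           config = method_config("standard"),
                           scan = NULL) {
  method <- match.arg(method)
  n <- nrow(expr$values)
  Xv <- if (inherits(X, "CovariateMatrix")) X$values else X
  K <- if (is.null(Xv)) 0L else ncol(Xv)
  if (method == "beta") {
    if (is.null(scan))
      scan <- egene_scan(expr, blocks, X, config$B, config$seed,
                         "permute_first")
    p <- rep(NA_real_, length(scan$gene_id))
    for (j in seq_along(p)) {
      if (!scan$tested[j]) next
      p_min_obs <- corr_to_pvalue(scan$t_exp[j], n, K)
      p_min_perm <- corr_to_pvalue(scan$t_bg[j, ], n, K)
      p[j] <- beta_gene_pvalue(p_min_obs, p_min_perm)$pvalue
    }
    results <- assemble_pvalue_results(scan, p, config, method = "beta")
    return(finish_fit(scan, results, "beta", config))
  }
  # permutation-free methods share the observed-data scan (B = 1 for shape)
  scan <- egene_scan(expr, blocks, X, 1L, config$seed, "permute_first")
  p <- rep(NA_real_, length(scan$gene_id))
  for (j in seq_along(p)) {
    if (!scan$tested[j]) next
    g <- scan$gene_id[j]
    b <- blocks[[g]]
    Gr <- residualize(b$dosages, Xv)$values
    gs <- standardize_resid(Gr)
    e <- residualize(expr$values[, j, drop = FALSE], Xv)$values
    r <- as.numeric(crossprod(gs$values, e / sqrt(sum(e^2))))
    p_snp <- corr_to_pvalue(r, n, K)
    p[j] <- if (method == "eigenmt") {
      bf <- b
      bf$dosages <- b$dosages[, !gs$dropped, drop = FALSE]
      bf$snp_ids <- b$snp_ids[!gs$dropped]
      bf$snp_positions <- b$snp_positions[!gs$dropped]
      eigenmt_gene_pvalue(bf, min(p_snp))$pvalue
    } else {
      simes_gene_pvalue(p_snp)
    }
  }
  results <- assemble_pvalue_results(scan, p, config, method = method)
  finish_fit(scan, results, method, config)
}
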