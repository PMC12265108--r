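#' Benjamini-Hochberg adjusted P values
#'
#' @param p Numeric vector of P values in `[0, 1]`.
#' @return Step-up adjusted values (monotone), same length as `p`.
#' @export
bh_adjust <- function(p) {
  if (length(p) == 0L) return(numeric(0))
  stats::p.adjust(p, method = "BH")
}

#' Benjamini-Yekutieli adjusted P values
#'
#' BH multiplied by the harmonic number `H_m`, capped at 1.
#'
#' @inheritParams bh_adjust
#' @return Adjusted values, same length as `p`.
#' @export
by_adjust <- function(p) {
  if (length(p) == 0L) return(numeric(0))
  stats::p.adjust(p, method = "BY")
}

#' Storey q-values
#'
#' Estimates the null proportion as
#' `pi0 = min(1, #\{p > lambda\} / ((1 - lambda) * m))` and returns
#' monotone-enforced `pi0 * m * p_(i) / i`. With `pi0 = 1` this reduces to BH.
#'
#' @param p Numeric vector of P values in `[0, 1]`.
#' @param lambda Tuning parameter for the pi0 estimate (default 0.5).
#' @return q-values, same length and order as `p`.
#' @export
storey_qvalue <- function(p, lambda = 0.5) {
  m <- length(p)
  if (m == 0L) return(numeric(0))
  stopifnot(all(p >= 0 & p <= 1))
  pi0 <- min(1, sum(p > lambda) / ((1 - lambda) * m))
  if (pi0 == 0) {
    warning("all P values <= lambda; clamping pi0 to 1/m", call. = FALSE)
    pi0 <- 1 / m
  }
  pi0 * stats::p.adjust(p, method = "BH")
}

apply_fdr_procedure <- function(p, procedure = c("storey", "bh", "by")) {
  procedure <- match.arg(procedure)
  switch(procedure,
         storey = storey_qvalue(p),
         bh = bh_adjust(p),
         by = by_adjust(p))
}

#' Contrastive (Clipper-style) FDR thresholding of gene statistics
#'
#' Computes per-gene contrast scores `C_j = T_exp,j - mean_b T_bg,j,b`
#' (for `B = 1` simply the experimental minus the background score; for
#' `B > 1` the background average — aggregating by the background maximum
#' instead would make the null contrasts grossly asymmetric,
#' `P(C > 0) = 1/(B+1)`, and destroy the estimator). Under
#' the null the contrast scores are roughly symmetric about zero, so for a
#' threshold `t > 0` the FDR among `\{C_j >= t\}` is estimated by the
#' Barber-Candes-style ratio
#' `FDRhat(t) = (1 + #\{j: C_j <= -t\}) / max(1, #\{j: C_j >= t\})`.
#' The cutoff is the smallest `t` among the observed `|C_j|` with
#' `FDRhat(t) <= target_fdr`; each gene's q-value is the smallest estimated
#' FDR over thresholds `t <= C_j` (1 for genes with `C_j <= 0`), clamped to
#' `[0, 1]`. Ties at the cutoff are all discovered.
#'
#' With several background replicates (`B >= 2`) the experimental and
#' background roles are no longer exchangeable one-to-one, and the skew of
#' the max-correlation null makes the count estimator anti-conservative; in
#' that case (`method = "gz"`, the default for `B >= 2`) the null
#' distribution of the contrast scores is instead modeled as Gaussian, with
#' center and spread estimated robustly from the lower half of the contrast
#' distribution (which is signal-free), and q-values are Storey q-values of
#' the resulting one-sided P values.
#'
#' @param t_exp Numeric vector, length `p`: experimental (observed) scores.
#' @param t_bg Numeric matrix `p x B` (or vector when `B = 1`): background
#'   scores from permuted data.
#' @param target_fdr Target FDR.
#' @param method `"bc"` (count-based estimator; default for `B = 1`) or
#'   `"gz"` (Gaussian null; default for `B >= 2`).
#' @return A list of class `ContrastResult` with `contrast_scores`,
#'   `q_values`, `cutoff` (`Inf` when no threshold achieves the target) and
#'   `discoveries` (logical).
#' @export
clipper_threshold <- function(t_exp, t_bg, target_fdr = 0.05,
                              method = NULL) {
  if (is.null(dim(t_bg))) t_bg <- matrix(t_bg, ncol = 1L)
  stopifnot(length(t_exp) == nrow(t_bg))
  if (is.null(method)) method <- if (ncol(t_bg) == 1L) "bc" else "gz"
  method <- match.arg(method, c("bc", "gz"))
  contrast <- t_exp - rowMeans(t_bg)
  if (method == "gz") return(gz_threshold(contrast, target_fdr))
  ok <- !is.na(contrast)
  cand <- sort(unique(abs(contrast[ok & contrast != 0])))
  q <- rep(NA_real_, length(contrast))
  cutoff <- Inf
  if (length(cand)) {
    n_neg <- vapply(cand, function(t) sum(contrast[ok] <= -t), numeric(1))
    n_pos <- vapply(cand, function(t) sum(contrast[ok] >= t), numeric(1))
    fdr_hat <- (1 + n_neg) / pmax(1, n_pos)
    # gene j belongs to the rejection set {C >= t} for every t <= C_j, so its
    # q-value is the running min of FDRhat over candidates up to C_j
    run_min <- pmin(1, cummin(fdr_hat))
    pass <- fdr_hat <= target_fdr
    if (any(pass)) cutoff <- min(cand[pass])
    idx <- match(abs(contrast), cand)
    q[ok] <- ifelse(contrast[ok] > 0, run_min[idx[ok]], 1)
  } else {
    q[ok] <- 1
  }
  structure(list(contrast_scores = contrast, q_values = q, cutoff = cutoff,
                 discoveries = !is.na(contrast) & contrast >= cutoff),
            class = "ContrastResult")
}

# Gaussian-null thresholding of contrast scores: the null center and spread
# are estimated from quantiles of the lower half of the contrast
# distribution (signal lives only in the right tail), then one-sided normal
# P values feed Storey q-values.
gz_threshold <- function(contrast, target_fdr) {
  ok <- !is.na(contrast)
  x <- contrast[ok]
  mu <- stats::median(x)
  # spread from the 10th percentile, which is unaffected by right-tail signal
  sigma <- (mu - quantile(x, 0.1, names = FALSE)) / stats::qnorm(0.9)
  if (!is.finite(sigma) || sigma <= 0) sigma <- stats::mad(x)
  p <- stats::pnorm(contrast, mean = mu, sd = sigma, lower.tail = FALSE)
  q <- rep(NA_real_, length(contrast))
  q[ok] <- storey_qvalue(p[ok])
  disc <- !is.na(q) & q <= target_fdr
  cutoff <- if (any(disc)) min(contrast[disc]) else Inf
  structure(list(contrast_scores = contrast, q_values = q, cutoff = cutoff,
                 discoveries = disc),
            class = "ContrastResult")
}

#' Call eGenes from q-values
#'
#' @param q Numeric vector of q-values.
#' @param target_fdr Target FDR.
#' @return Logical vector: `q <= target_fdr` (`NA` q gives `FALSE`).
#' @export
call_egenes <- function(q, target_fdr = 0.05) {
  !is.na(q) & q <= target_fdr
}
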