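#' Top principal components of the expression matrix
#'
#' PCs are computed on the column-standardized expression matrix (constant
#' gene columns dropped). Signs follow a deterministic convention: within
#' each component the loading with the largest magnitude is made positive.
#'
#' @param expr An [expression_matrix()].
#' @param k Number of components (`k <= min(n, p)`).
#' @return Numeric matrix `n x k` of PC scores, columns `PC1..PCk`.
#' @export
expression_pcs <- function(expr, k) {
  Z <- standardized_expression(expr)
  stopifnot(k >= 1, k <= min(dim(Z)))
  pc <- prcomp(Z, center = FALSE, scale. = FALSE)
  flip <- vapply(seq_len(k), function(i) {
    l <- pc$rotation[, i]
    sign(l[which.max(abs(l))])
  }, numeric(1))
  scores <- sweep(pc$x[, seq_len(k), drop = FALSE], 2, flip, "*")
  colnames(scores) <- paste0("PC", seq_len(k))
  rownames(scores) <- sample_ids(expr)
  scores
}

standardized_expression <- function(expr) {
  Y <- expr$values
  sds <- apply(Y, 2, sd)
  keep <- sds > 0
  scale(Y[, keep, drop = FALSE])
}

# per-PC fraction of variance explained (squared singular values, normalized)
variance_explained <- function(Z) {
  d2 <- svd(Z, nu = 0, nv = 0)$d^2
  d2 / sum(d2)
}

#' Choose the number of expression PCs by parallel analysis (BE algorithm)
#'
#' Buja-Eyuboglu permutation scheme: each gene column is permuted
#' independently `n_perm` times; the chosen number of PCs is the count of
#' leading components whose observed variance explained exceeds the
#' `(1 - alpha)` quantile of the permuted variance explained at the same
#' component index, stopping at the first failure (so the retained set is
#' always the contiguous leading block).
#'
#' @param expr An [expression_matrix()].
#' @param n_perm Number of permutations (default 20).
#' @param alpha Per-component test level (default 0.05).
#' @param seed Optional seed for the permutations.
#' @return The chosen number of PCs (possibly 0).
#' @export
choose_k_be <- function(expr, n_perm = 20L, alpha = 0.05, seed = NULL) {
  stopifnot(n_perm >= 10L)
  if (!is.null(seed)) set.seed(seed)
  Z <- standardized_expression(expr)
  obs <- variance_explained(Z)
  m <- length(obs)
  null_ve <- matrix(NA_real_, m, n_perm)
  for (b in seq_len(n_perm)) {
    Zp <- apply(Z, 2, sample)
    null_ve[, b] <- variance_explained(Zp)
  }
  thresh <- apply(null_ve, 1, quantile, probs = 1 - alpha, names = FALSE)
  pass <- obs > thresh
  if (!pass[1]) return(0L)
  first_fail <- which(!pass)[1]
  if (is.na(first_fail)) m else first_fail - 1L
}

#' Choose the number of expression PCs by the elbow method
#'
#' The elbow is the scree-curve index (variance explained against component
#' index) with maximum perpendicular distance from the chord joining the
#' curve's endpoints. Scale-invariant in the variances.
#'
#' @param expr An [expression_matrix()], or a numeric vector of variances
#'   (scree values) to locate the elbow of directly.
#' @return The chosen number of PCs (>= 1).
#' @export
choose_k_elbow <- function(expr) {
  v <- if (is.numeric(expr)) as.numeric(expr)
       else variance_explained(standardized_expression(expr))
  m <- length(v)
  if (m < 3L) return(1L)
  x <- seq_len(m)
  # perpendicular distance from (x, v) to the chord (1, v1) -- (m, vm)
  dx <- m - 1
  dv <- v[m] - v[1]
  dist <- abs(dv * x - dx * v + dx * v[1] - dv) / sqrt(dx^2 + dv^2)
  which.max(dist)
}
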