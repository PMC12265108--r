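test_that("residualization reproduces per-column OLS residuals", {
  set.seed(10)
  M <- matrix(rnorm(20 * 3), 20, 3)
  X <- matrix(rnorm(20 * 2), 20, 2)
  rr <- residualize(M, X)
  expect_equal(rr$df_resid, 20 - 2 - 2)
  for (j in 1:3) {
    ref <- stats::residuals(stats::lm(M[, j] ~ X))
    expect_equal(unname(rr$values[, j]), unname(ref), tolerance = 1e-10)
  }
  # orthogonality to intercept and covariates
  expect_lt(max(abs(crossprod(cbind(1, X), rr$values))), 1e-8)
})

test_that("residualize handles the degenerate spans", {
  M <- matrix(rnorm(30), 10, 3)
  expect_equal(residualize(M, NULL)$values, scale(M, scale = FALSE),
               ignore_attr = TRUE)
  X <- matrix(rnorm(10), 10, 1)
  expect_lt(max(abs(residualize(X, X)$values)), 1e-10)
  expect_error(residualize(M, cbind(a = X, b = 2 * X)), "rank deficient")
})

test_that("max_abs_corr equals the naive per-SNP loop", {
  set.seed(11)
  n <- 30
  X <- matrix(rnorm(n * 2), n, 2)
  e <- residualize(matrix(rnorm(n), n, 1), X)$values[, 1]
  G <- residualize(matrix(rnorm(n * 5), n, 5), X)$values
  got <- max_abs_corr(e, G)
  ref <- abs(apply(G, 2, cor, y = e))
  expect_equal(got$t, max(ref), tolerance = 1e-10)
  expect_equal(got$lead_snp, unname(which.max(ref)))
  # single SNP and duplicated-column invariance
  expect_equal(max_abs_corr(e, G[, 2, drop = FALSE])$t, ref[2],
               tolerance = 1e-12)
  expect_equal(max_abs_corr(e, cbind(G, G[, which.max(ref)]))$t, max(ref),
               tolerance = 1e-12)
})

test_that("corr_to_pvalue matches the linear-model SNP t-test", {
  set.seed(12)
  n <- 20; K <- 2
  X <- matrix(rnorm(n * K), n, K)
  snp <- rbinom(n, 2, 0.4)
  y <- 0.3 * snp + rnorm(n)
  fit <- summary(stats::lm(y ~ snp + X))
  p_ref <- fit$coefficients["snp", "Pr(>|t|)"]
  er <- residualize(matrix(y), X)$values[, 1]
  gr <- residualize(matrix(snp), X)$values[, 1]
  r <- cor(er, gr)
  expect_equal(corr_to_pvalue(r, n, K), p_ref, tolerance = 1e-10)
  expect_equal(corr_to_pvalue(0, n, K), 1)
  expect_equal(corr_to_pvalue(1, n, K), 0)
  expect_error(corr_to_pvalue(0.5, 4, 2), "degrees of freedom")
  grid <- corr_to_pvalue(seq(0.05, 0.95, by = 0.05), 50, 3)
  expect_true(all(diff(grid) < 0))
})

test_that("nominal pass equals per-pair OLS refits and is relabel-invariant", {
  fx <- null_fixture(n = 25, p = 2, q = 3, K = 2, seed = 13)
  tab <- nominal_pass(fx$expr, fx$blocks, fx$covs)
  expect_equal(nrow(tab), 6L)
  for (i in seq_len(nrow(tab))) {
    y <- fx$expr$values[, tab$gene_id[i]]
    s <- fx$blocks[[tab$gene_id[i]]]$dosages[, tab$snp_id[i]]
    fit <- summary(stats::lm(y ~ s + fx$covs$values))
    expect_equal(tab$p[i], fit$coefficients["s", "Pr(>|t|)"],
                 tolerance = 1e-10)
  }
  ord <- sample(fx$n)
  expr2 <- fx$expr; expr2$values <- expr2$values[ord, ]
  blocks2 <- lapply(fx$blocks, function(b) {
    b$dosages <- b$dosages[ord, , drop = FALSE]; b
  })
  covs2 <- fx$covs; covs2$values <- covs2$values[ord, , drop = FALSE]
  expect_equal(nominal_pass(expr2, blocks2, covs2), tab, tolerance = 1e-12)
})

test_that("max-|r| and min-p are interchangeable through the correspondence", {
  fx <- null_fixture(n = 40, p = 3, q = 6, K = 2, seed = 14)
  tab <- nominal_pass(fx$expr, fx$blocks, fx$covs)
  E <- residualize(fx$expr$values, fx$covs)$values
  for (g in colnames(fx$expr$values)) {
    G <- residualize(fx$blocks[[g]]$dosages, fx$covs)$values
    t_g <- max_abs_corr(E[, g], G)$t
    expect_equal(corr_to_pvalue(t_g, fx$n, fx$K),
                 min(tab$p[tab$gene_id == g]), tolerance = 1e-12)
  }
})
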