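test_that("beta approximation recovers the order-statistic law", {
  set.seed(40)
  # minima of m = 50 independent uniforms are Beta(1, 50)
  mins <- vapply(1:400, function(i) min(runif(50)), numeric(1))
  out <- beta_gene_pvalue(0.01, mins)
  expect_true(out$fit$converged)
  expect_lt(abs(out$fit$a - 1) / 1, 0.2)
  expect_lt(abs(out$fit$b - 50) / 50, 0.2)
  # Beta(1,1) fit on uniforms: gene p ~ the observed value itself
  unif <- runif(500)
  out2 <- beta_gene_pvalue(0.3, unif)
  expect_equal(out2$pvalue, 0.3, tolerance = 0.05)
})

test_that("beta and proportion P values agree within Monte-Carlo error", {
  set.seed(41)
  B <- 300
  for (trial in 1:5) {
    mins <- rbeta(B, 1.2, 30)
    obs <- quantile(mins, runif(1, 0.05, 0.9), names = FALSE)
    pb <- beta_gene_pvalue(obs, mins)$pvalue
    pp <- (1 + sum(mins <= obs)) / (B + 1)
    expect_lt(abs(pb - pp), 2 / sqrt(B))
  }
})

test_that("effective test counts behave at the rank extremes", {
  n <- 100
  base <- rbinom(n, 2, 0.4)
  dup <- cis_genotype_block("g", cbind(base, base, base),
                            paste0("s", 1:3), 1:3)
  out <- eigenmt_gene_pvalue(dup, p_min = 0.004)
  expect_equal(out$m_eff, 1)
  expect_equal(out$pvalue, 0.004)
  # independent SNPs at threshold 0.99: k/q first reaches 0.99 at q - 2
  q <- 200
  ident <- cis_genotype_block("g", matrix(rbinom(n * q, 2, 0.5), n, q),
                              paste0("s", 1:q), 1:q)
  ev <- rep(1, q)  # idealized identity-correlation eigenvalues
  expect_equal(which(cumsum(ev) / sum(ev) >= 0.99)[1], 198)
  out2 <- eigenmt_gene_pvalue(ident, p_min = 1e-4)
  expect_lte(out2$m_eff, q)          # never more than the actual count
  expect_lte(out2$pvalue, min(1, 1e-4 * q))  # dominates Bonferroni
})

test_that("Simes' rule matches hand evaluation", {
  expect_equal(simes_gene_pvalue(0.2), 0.2)
  expect_equal(simes_gene_pvalue(c(0.01, 0.02, 0.9)), 0.03)
  expect_equal(simes_gene_pvalue(rep(0.4, 7)), 0.4)
})

test_that("Simes and m_eff-Bonferroni P values are null-uniform", {
  set.seed(42)
  n <- 60; q <- 8; reps <- 300
  p_simes <- numeric(reps)
  p_eig <- numeric(reps)
  for (i in seq_len(reps)) {
    G <- matrix(rbinom(n * q, 2, 0.35), n, q)
    y <- rnorm(n)
    r <- suppressWarnings(apply(G, 2, cor, y = y))
    pv <- corr_to_pvalue(r, n, 0)
    p_simes[i] <- simes_gene_pvalue(pv)
    blk <- cis_genotype_block("g", G, paste0("s", 1:q), 1:q)
    p_eig[i] <- eigenmt_gene_pvalue(blk, min(pv))$pvalue
  }
  expect_gt(stats::ks.test(p_simes, "punif")$p.value, 0.01)
  # Bonferroni-style correction is conservative, never anti-conservative
  expect_lt(mean(p_eig <= 0.05), 0.05 + 2 * sqrt(0.05 * 0.95 / reps))
})

test_that("naive all-pairs calls flag exactly the significant genes", {
  pairs <- tibble::tibble(
    gene_id = rep(c("g1", "g2", "g3"), each = 3),
    snp_id = rep(paste0("s", 1:3), 3),
    r = 0,
    p = c(1e-8, 0.5, 0.6, 0.2, 0.3, 0.4, 0.7, 0.8, 0.9))
  calls <- naive_matrixeqtl_egenes(pairs, 0.05)
  expect_equal(calls$is_egene[calls$gene_id == "g1"], TRUE)
  expect_equal(sum(calls$is_egene), 1L)
  none <- naive_matrixeqtl_egenes(dplyr::mutate(pairs, p = pmax(p, 0.2)),
                                  0.05)
  expect_equal(sum(none$is_egene), 0L)
})
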