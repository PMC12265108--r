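small_cfg <- function(seed = 1, ...) {
  sim_config(n = 120, p = 30, K_true = 4, snps_per_gene = 10, seed = seed,
             ...)
}

test_that("simulation is deterministic in the seed", {
  a <- simulate_dataset(small_cfg(seed = 5))
  b <- simulate_dataset(small_cfg(seed = 5))
  c <- simulate_dataset(small_cfg(seed = 6))
  expect_identical(a$expr$values, b$expr$values)
  expect_identical(a$blocks[["gene0003"]]$dosages,
                   b$blocks[["gene0003"]]$dosages)
  expect_false(identical(a$expr$values, c$expr$values))
})

test_that("realized genotype variance fractions match the target", {
  sim <- simulate_dataset(sim_config(n = 300, p = 60, K_true = 5,
                                     snps_per_gene = 20, seed = 8))
  pves <- sim$truth$realized_pve[sim$truth$is_egene]
  expect_lt(abs(mean(pves) - 0.02), 0.005)
  expect_true(all(is.na(sim$truth$realized_pve[!sim$truth$is_egene])))
  expect_lt(abs(mean(sim$truth$is_egene) - 0.2), 0.02)
})

test_that("covariate variance fraction is honored in every gene", {
  sim <- simulate_dataset(small_cfg(seed = 9))
  # refit the covariate component per gene; R^2 close to pve_covariates
  X <- sim$covariates$values
  r2 <- apply(sim$expr$values, 2, function(y) {
    summary(stats::lm(y ~ X))$r.squared
  })
  expect_lt(abs(mean(r2) - 0.5), 0.05)
})

test_that("a zero-genotype-effect design is all null", {
  cfg <- sim_config(n = 100, p = 20, K_true = 3, snps_per_gene = 5,
                    pve_genotype = 0, egene_fraction = 0.2, seed = 10)
  sim <- simulate_dataset(cfg)
  # eGene labels exist but realized genotype variance is zero everywhere
  expect_true(all(sim$truth$realized_pve[sim$truth$is_egene] == 0))
})

test_that("simulated SNPs fall inside their gene's cis window and LD decays", {
  sim <- simulate_dataset(small_cfg(seed = 11))
  for (g in c("gene0001", "gene0020")) {
    blk <- sim$blocks[[g]]
    tss <- sim$expr$tss$tss[sim$expr$tss$gene_id == g]
    expect_true(all(abs(blk$snp_positions - tss) <= 1e6))
  }
  big <- simulate_dataset(sim_config(n = 500, p = 2, snps_per_gene = 50,
                                     seed = 12))
  d <- big$blocks[[1]]$dosages
  cc <- abs(cor(d))
  adjacent <- mean(cc[cbind(1:49, 2:50)])
  distant <- mean(cc[cbind(1:30, 21:50)])
  expect_gt(adjacent, 0.6)
  expect_lt(distant, adjacent - 0.3)
})

test_that("FDP and power bookkeeping counts correctly", {
  truth <- tibble::tibble(gene_id = paste0("g", 1:10),
                          is_egene = rep(c(TRUE, FALSE), c(2, 8)))
  perfect <- evaluate_calls(truth, truth$is_egene)
  expect_equal(perfect$fdp, 0)
  expect_equal(perfect$power, 1)
  all_called <- evaluate_calls(truth, rep(TRUE, 10))
  expect_equal(all_called$fdp, 0.8)
  expect_equal(all_called$power, 1)
  none <- evaluate_calls(truth, rep(FALSE, 10))
  expect_equal(none$fdp, 0)
  expect_equal(none$power, 0)
})

test_that("simulated data round-trip through the file formats", {
  sim <- simulate_dataset(small_cfg(seed = 13))
  dir <- withr::local_tempdir()
  write_simulated_dataset(sim, dir)
  expr <- read_expression_bed(file.path(dir, "expression.bed"))
  expect_equal(expr$values, sim$expr$values, tolerance = 1e-12)
  src <- read_dosage_tsv(file.path(dir, "dosages.tsv"))
  blk <- extract_cis_block(src, "gene0002", expr$tss)
  expect_equal(unname(blk$dosages),
               unname(sim$blocks[["gene0002"]]$dosages))
})
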