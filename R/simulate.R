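#' Simulation configuration
#'
#' Defaults reproduce the study conditions used to benchmark the callers:
#' `n = 838` individuals, `p = 1000` genes, `K_true = 20` known covariates,
#' genotype variance fraction 0.02 in eGenes (cis effect only), covariate
#' variance fraction 0.5 in all genes, 20% eGenes with one causal SNP each,
#' 500 local SNPs per gene with AR(1)-correlated latent genotypes
#' (`ld_rho = 0.9`: adjacent-SNP LD r^2 around 0.75 at the ~10 kb spacing
#' the generator produces, so the effective number of tests per gene is far
#' below the SNP count, as in real cis windows) and MAFs uniform on
#' (0.05, 0.5).
#'
#' @param n Sample size.
#' @param p Number of genes.
#' @param K_true Number of (known) covariates.
#' @param pve_genotype Realized fraction of expression variance from the
#'   causal genotype component in eGenes.
#' @param pve_covariates Realized fraction of expression variance from the
#'   covariate component (all genes).
#' @param egene_fraction Fraction of genes that are eGenes.
#' @param snps_per_gene Local SNPs simulated per gene.
#' @param causal_snps_per_egene Causal SNPs per eGene.
#' @param ld_rho AR(1) correlation of the latent Gaussians underlying
#'   adjacent SNPs (linkage-disequilibrium strength).
#' @param maf_range Range (low, high) of simulated MAFs.
#' @param seed Integer seed.
#' @return A list of class `SimConfig`.
#' @export
sim_config <- function(n = 838L, p = 1000L, K_true = 20L,
                       pve_genotype = 0.02, pve_covariates = 0.5,
                       egene_fraction = 0.2, snps_per_gene = 500L,
                       causal_snps_per_egene = 1L, ld_rho = 0.9,
                       maf_range = c(0.05, 0.5), seed = 1L) {
  stopifnot(pve_genotype >= 0, pve_genotype < 1,
            pve_covariates >= 0, pve_covariates < 1,
            pve_genotype + pve_covariates < 1,
            egene_fraction > 0, egene_fraction < 1,
            ld_rho >= 0, ld_rho < 1,
            maf_range[1] > 0, maf_range[2] <= 0.5)
  structure(list(n = as.integer(n), p = as.integer(p),
                 K_true = as.integer(K_true), pve_genotype = pve_genotype,
                 pve_covariates = pve_covariates,
                 egene_fraction = egene_fraction,
                 snps_per_gene = as.integer(snps_per_gene),
                 causal_snps_per_egene = as.integer(causal_snps_per_egene),
                 ld_rho = ld_rho, maf_range = maf_range,
                 seed = as.integer(seed)),
            class = "SimConfig")
}

# dosages for one gene: latent AR(1) Gaussians thresholded at Hardy-Weinberg
# quantiles per SNP (Gaussian copula), giving hard-call dosages 0/1/2
simulate_gene_dosages <- function(n, q, rho, maf) {
  Z <- matrix(rnorm(n * q), n, q)
  if (q > 1 && rho > 0) {
    s <- sqrt(1 - rho^2)
    for (k in 2:q) Z[, k] <- rho * Z[, k - 1] + s * Z[, k]
  }
  c1 <- qnorm((1 - maf)^2)            # P(dosage = 0) under HWE
  c2 <- qnorm(1 - maf^2)              # P(dosage <= 1)
  D <- matrix(0, n, q)
  D <- D + (Z > rep(c1, each = n)) + (Z > rep(c2, each = n))
  D
}

#' Simulate an eQTL dataset with known ground truth
#'
#' Expression for gene `j` is generated as intercept + genotype effect +
#' covariate effect + Gaussian noise. For eGenes, the causal SNP component is
#' rescaled so its realized (in-sample) variance fraction equals
#' `pve_genotype`; the covariate component is scaled to `pve_covariates` in
#' every gene; the residual noise carries the remainder. Non-eGenes have no
#' genotype component. All covariates are returned as known covariates.
#' Genes are placed on one chromosome with disjoint cis windows so the data
#' round-trip through the file formats unchanged.
#'
#' At the full default scale (1000 genes x 500 SNPs) the dosage matrices
#' total several GB; reduce `p`/`snps_per_gene` on small machines.
#'
#' @param config A [sim_config()].
#' @return List with `expr` ([expression_matrix()]), `blocks` (named list of
#'   [cis_genotype_block()]s), `covariates` ([covariate_matrix()]),
#'   `genotypes` (a `GenotypeSource` over all SNPs), and `truth` (tibble
#'   `gene_id`, `is_egene`, `causal_snps` list-column, `realized_pve`).
#' @export
simulate_dataset <- function(config = sim_config()) {
  stopifnot(inherits(config, "SimConfig"))
  set.seed(config$seed)
  n <- config$n; p <- config$p; q <- config$snps_per_gene
  sample_ids <- sprintf("indiv%03d", seq_len(n))
  gene_ids <- sprintf("gene%04d", seq_len(p))
  gene_spacing <- 2L * 1e6L + 2L * q + 10L
  tss <- tibble(gene_id = gene_ids, chrom = "1",
                tss = 1e6L + gene_spacing * (seq_len(p) - 1L) + 1L)

  Xt <- matrix(rnorm(n * config$K_true), n, config$K_true)
  n_egene <- round(p * config$egene_fraction)
  egene_idx <- sort(sample.int(p, n_egene))
  is_egene <- seq_len(p) %in% egene_idx

  Y <- matrix(NA_real_, n, p)
  blocks <- vector("list", p)
  causal <- vector("list", p)
  realized <- rep(NA_real_, p)
  scale_to <- function(x, target_var) {
    s <- sd(x)
    if (s == 0) return(NULL)
    (x - mean(x)) * sqrt(target_var) / s
  }
  for (j in seq_len(p)) {
    maf <- runif(q, config$maf_range[1], config$maf_range[2])
    D <- simulate_gene_dosages(n, q, config$ld_rho, maf)
    pos <- tss$tss[j] - 1e6L + round(seq(0, 2e6, length.out = q))
    blocks[[j]] <- cis_genotype_block(
      gene_ids[j], D, sprintf("%s_snp%04d", gene_ids[j], seq_len(q)), pos,
      sample_ids = sample_ids)
    cov_part <- scale_to(Xt %*% rnorm(config$K_true),
                         config$pve_covariates)
    noise_var <- 1 - config$pve_covariates -
      if (is_egene[j]) config$pve_genotype else 0
    y <- cov_part + rnorm(n, sd = sqrt(noise_var))
    if (is_egene[j]) {
      cs <- sort(sample.int(q, config$causal_snps_per_egene))
      geno_part <- scale_to(D[, cs, drop = FALSE] %*%
                              rnorm(config$causal_snps_per_egene),
                            config$pve_genotype)
      tries <- 0L
      while (is.null(geno_part)) {   # monomorphic draw; resample the SNP(s)
        tries <- tries + 1L
        if (tries > 50L) stop("could not draw a polymorphic causal SNP")
        warning("zero-variance causal SNP resampled for ", gene_ids[j],
                call. = FALSE)
        cs <- sort(sample.int(q, config$causal_snps_per_egene))
        geno_part <- scale_to(D[, cs, drop = FALSE] %*%
                                rnorm(config$causal_snps_per_egene),
                              config$pve_genotype)
      }
      causal[[j]] <- cs
      y <- y + geno_part
      realized[j] <- var(geno_part) / var(y)
    } else {
      causal[[j]] <- integer(0)
    }
    Y[, j] <- y
  }
  names(blocks) <- gene_ids
  all_snps <- do.call(rbind, lapply(blocks, function(b)
    data.frame(snp_id = b$snp_ids, pos = b$snp_positions)))
  genotypes <- structure(
    list(snp_ids = all_snps$snp_id, chrom = rep("1", nrow(all_snps)),
         pos = all_snps$pos, sample_ids = sample_ids,
         dosages = do.call(cbind, lapply(blocks, `[[`, "dosages"))),
    class = "GenotypeSource")
  colnames(genotypes$dosages) <- genotypes$snp_ids
  rownames(genotypes$dosages) <- sample_ids
  list(expr = expression_matrix(Y, sample_ids, gene_ids, tss),
       blocks = blocks,
       covariates = covariate_matrix(Xt, sample_ids,
                                     paste0("cov", seq_len(config$K_true))),
       genotypes = genotypes,
       truth = tibble(gene_id = gene_ids, is_egene = is_egene,
                      causal_snps = causal, realized_pve = realized),
       config = config)
}

#' Evaluate eGene calls against simulation truth
#'
#' @param truth Truth tibble from [simulate_dataset()] (columns `gene_id`,
#'   `is_egene`).
#' @param calls Logical vector of calls aligned to `truth$gene_id`, or a
#'   tibble with `gene_id` and `is_egene`.
#' @return One-row tibble: `n_discoveries`, `fdp` (false discoveries over
#'   `max(1, discoveries)`) and `power` (true discoveries over true eGenes).
#' @export
evaluate_calls <- function(truth, calls) {
  if (is.data.frame(calls)) {
    calls <- calls$is_egene[match(truth$gene_id, calls$gene_id)]
  }
  stopifnot(length(calls) == nrow(truth))
  calls <- !is.na(calls) & calls
  disc <- sum(calls)
  false_disc <- sum(calls & !truth$is_egene)
  true_disc <- sum(calls & truth$is_egene)
  tibble(n_discoveries = disc,
         fdp = false_disc / max(1, disc),
         power = true_disc / max(1, sum(truth$is_egene)))
}

#' Write a simulated dataset to disk in the standard formats
#'
#' Writes `expression.bed` (FastQTL-style), `dosages.tsv`, `covariates.tsv`
#' and `truth.tsv` into `dir`; the files feed straight into
#' [run_pipeline()].
#'
#' @param sim Output of [simulate_dataset()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_simulated_dataset <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_expression_bed(sim$expr, file.path(dir, "expression.bed"))
  write_dosage_tsv(sim$genotypes, file.path(dir, "dosages.tsv"))
  cov <- tibble(sample_id = rownames(sim$covariates$values))
  cov <- dplyr::bind_cols(cov, as_tibble(sim$covariates$values))
  readr::write_tsv(cov, file.path(dir, "covariates.tsv"), progress = FALSE)
  truth <- dplyr::mutate(sim$truth,
                         causal_snps = purrr::map_chr(.data$causal_snps,
                                                      paste, collapse = ","))
  readr::write_tsv(truth, file.path(dir, "truth.tsv"), progress = FALSE)
  invisible(dir)
}
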