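# Small in-code fixtures shared across test files.

# random expression/genotype/covariate triple with no signal
null_fixture <- function(n = 30, p = 4, q = 5, K = 2, seed = 42) {
  set.seed(seed)
  expr <- expression_matrix(matrix(rnorm(n * p), n, p),
                            sample_ids = sprintf("s%02d", 1:n),
                            gene_ids = paste0("g", 1:p),
                            tss = tibble::tibble(gene_id = paste0("g", 1:p),
                                                 chrom = "1",
                                                 tss = 1e6L * (1:p)))
  blocks <- lapply(1:p, function(j) {
    cis_genotype_block(paste0("g", j),
                       matrix(rbinom(n * q, 2, 0.3), n, q),
                       sprintf("g%d_snp%d", j, 1:q),
                       1e6L * j + (1:q) * 100L,
                       sample_ids = sprintf("s%02d", 1:n))
  })
  names(blocks) <- paste0("g", 1:p)
  covs <- if (K > 0) {
    covariate_matrix(matrix(rnorm(n * K), n, K),
                     sprintf("s%02d", 1:n), paste0("c", seq_len(K)))
  } else NULL
  list(expr = expr, blocks = blocks, covs = covs, n = n, p = p, q = q, K = K)
}

# tiny VCF text written to a temp file; biallelic unless alt has a comma
write_toy_vcf <- function(path, pos, samples = c("s1", "s2", "s3"),
                          alt = rep("T", length(pos)),
                          gts = NULL) {
  if (is.null(gts))
    gts <- matrix("0/1", length(pos), length(samples))
  hdr <- c("##fileformat=VCFv4.2",
           "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
           paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                   "INFO", "FORMAT", samples), collapse = "\t"))
  body <- vapply(seq_along(pos), function(i) {
    paste(c("1", pos[i], paste0("snp", i), "A", alt[i], ".", "PASS", ".",
            "GT", gts[i, ]), collapse = "\t")
  }, character(1))
  writeLines(c(hdr, body), path)
  path
}

# per-gene, per-permutation reference implementation of the standard variant
# using plain lm residuals and cor(); deliberately naive
naive_standard_pvalues <- function(expr, blocks, covs, B, seed) {
  n <- nrow(expr$values)
  X <- if (is.null(covs)) matrix(0, n, 0) else covs$values
  perms <- permutation_indices(n, B, seed)
  res_col <- function(y) stats::residuals(stats::lm(y ~ X))
  vapply(colnames(expr$values), function(g) {
    b <- blocks[[g]]
    gr <- apply(b$dosages, 2, res_col)
    y <- expr$values[, g]
    t_exp <- max(abs(apply(gr, 2, function(s) cor(res_col(y), s))))
    t_bg <- vapply(seq_len(B), function(k) {
      yp <- res_col(y[perms[, k]])
      max(abs(apply(gr, 2, function(s) cor(yp, s))))
    }, numeric(1))
    (1 + sum(t_bg >= t_exp)) / (B + 1)
  }, numeric(1))
}
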