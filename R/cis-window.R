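#' Extract the cis genotype block for one gene
#'
#' Returns all SNPs on the gene's chromosome with position within
#' `window` bp of the TSS (closed interval, `|pos - TSS| <= window`),
#' before any statistical filters.
#'
#' @param source A `GenotypeSource` (see [read_dosage_tsv()]).
#' @param gene_id Gene identifier.
#' @param tss TSS table (`gene_id`, `chrom`, `tss`) or an
#'   [expression_matrix()] carrying one.
#' @param window Half-width of the cis window in bp (default 1 Mb).
#' @return A [cis_genotype_block()]; zero columns if no SNP falls in the
#'   window (the gene is then excluded from testing downstream).
#' @export
extract_cis_block <- function(source, gene_id, tss, window = 1e6L) {
  if (inherits(tss, "ExpressionMatrix")) tss <- tss$tss
  if (is.null(tss)) stop("no TSS annotation available")
  row <- tss[tss$gene_id == gene_id, , drop = FALSE]
  if (nrow(row) == 0L) stop("gene without TSS: ", gene_id)
  keep <- source$chrom == row$chrom[1] &
    abs(source$pos - row$tss[1]) <= window
  cis_genotype_block(gene_id,
                     source$dosages[, keep, drop = FALSE],
                     source$snp_ids[keep], source$pos[keep],
                     sample_ids = source$sample_ids)
}

#' Minor allele frequency of a dosage vector
#'
#' `maf = min(m, 1 - m)` with `m = mean(dosage) / 2` (folded to <= 0.5).
#'
#' @param dosage Numeric vector of dosages in `[0, 2]`.
#' @return Folded MAF in `[0, 0.5]`.
#' @export
snp_maf <- function(dosage) {
  m <- mean(dosage) / 2
  pmin(m, 1 - m)
}

#' Filter SNPs by MAF and minor-allele carrier count
#'
#' Keeps SNPs with folded MAF >= `maf_min` AND at least `ma_samples_min`
#' individuals carrying the minor allele (both conditions must hold).
#' With fractional dosages, an individual counts as a carrier when its
#' dosage on the minor-allele scale is >= 0.5.
#'
#' @param block A [cis_genotype_block()].
#' @param maf_min Minimum folded MAF (default 0.01).
#' @param ma_samples_min Minimum carrier count (default 10).
#' @return The filtered block; SNP order preserved. May have zero columns.
#' @export
filter_snps <- function(block, maf_min = 0.01, ma_samples_min = 10L) {
  d <- block$dosages
  if (ncol(d) == 0L) return(block)
  m <- colMeans(d) / 2
  maf <- pmin(m, 1 - m)
  # fold so that carrier counting is on the minor allele
  minor_dosage <- d
  flip <- m > 0.5
  if (any(flip)) minor_dosage[, flip] <- 2 - d[, flip, drop = FALSE]
  ma_samples <- colSums(minor_dosage >= 0.5)
  keep <- maf >= maf_min & ma_samples >= ma_samples_min
  block$dosages <- d[, keep, drop = FALSE]
  block$snp_ids <- block$snp_ids[keep]
  block$snp_positions <- block$snp_positions[keep]
  block
}

#' Build filtered cis blocks for all genes
#'
#' Convenience wrapper: [extract_cis_block()] then [filter_snps()] per gene.
#'
#' @param expr [expression_matrix()] with TSS annotation.
#' @param source A `GenotypeSource`.
#' @param window,maf_min,ma_samples_min Passed through.
#' @return Named list of [cis_genotype_block()] objects, one per gene.
#' @export
build_cis_blocks <- function(expr, source, window = 1e6L, maf_min = 0.01,
                             ma_samples_min = 10L) {
  ids <- gene_ids(expr)
  blocks <- lapply(ids, function(g)
    filter_snps(extract_cis_block(source, g, expr$tss, window),
                maf_min, ma_samples_min))
  names(blocks) <- ids
  blocks
}
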