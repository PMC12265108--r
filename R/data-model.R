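#' Construct an expression matrix container
#'
#' Holds the fully processed individual-by-gene expression matrix `Y` together
#' with sample identifiers and (optionally) per-gene transcription start site
#' (TSS) coordinates. The TSS is required only by operations that extract cis
#' windows; pseudobulk matrices may carry `tss = NULL` until annotated.
#'
#' @param values Numeric matrix, `n` samples by `p` genes. No missing values.
#' @param sample_ids Character vector of length `n`; unique.
#' @param gene_ids Character vector of length `p`; unique.
#' @param tss Optional tibble/data frame with columns `gene_id`, `chrom`,
#'   `tss` (1-based position in bp), one row per gene.
#' @return An object of class `ExpressionMatrix`: a list with elements
#'   `values` (dimnames set to sample and gene ids) and `tss`.
#' @examples
#' y <- matrix(rnorm(6), 2, 3)
#' expression_matrix(y, c("s1", "s2"), c("g1", "g2", "g3"))
#' @export
expression_matrix <- function(values, sample_ids, gene_ids, tss = NULL) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (anyNA(values)) stop("expression matrix contains missing values")
  if (nrow(values) < 2L) stop("need at least 2 samples")
  if (ncol(values) < 1L) stop("need at least 1 gene")
  sample_ids <- as.character(sample_ids)
  gene_ids <- as.character(gene_ids)
  if (length(sample_ids) != nrow(values))
    stop("length(sample_ids) != nrow(values)")
  if (length(gene_ids) != ncol(values))
    stop("length(gene_ids) != ncol(values)")
  if (anyDuplicated(sample_ids))
    stop("duplicate sample ids: ",
         paste(unique(sample_ids[duplicated(sample_ids)]), collapse = ", "))
  if (anyDuplicated(gene_ids))
    stop("duplicate gene ids: ",
         paste(unique(gene_ids[duplicated(gene_ids)]), collapse = ", "))
  dimnames(values) <- list(sample_ids, gene_ids)
  if (!is.null(tss)) {
    tss <- tibble::as_tibble(tss)
    stopifnot(all(c("gene_id", "chrom", "tss") %in% names(tss)))
    tss$gene_id <- as.character(tss$gene_id)
    tss$chrom <- as.character(tss$chrom)
    tss$tss <- as.integer(tss$tss)
    missing_tss <- setdiff(gene_ids, tss$gene_id)
    if (length(missing_tss))
      stop("genes without TSS: ", paste(head(missing_tss, 5), collapse = ", "))
    tss <- tss[match(gene_ids, tss$gene_id), , drop = FALSE]
  }
  structure(list(values = values, tss = tss), class = "ExpressionMatrix")
}

#' @export
print.ExpressionMatrix <- function(x, ...) {
  cat(sprintf("<ExpressionMatrix> %d samples x %d genes%s\n",
              nrow(x$values), ncol(x$values),
              if (is.null(x$tss)) " (no TSS annotation)" else ""))
  invisible(x)
}

#' @export
dim.ExpressionMatrix <- function(x) dim(x$values)

sample_ids <- function(x) rownames(x$values)
gene_ids <- function(x) colnames(x$values)

#' Construct a covariate matrix container
#'
#' Holds the `n x K` matrix of known plus inferred covariates `X`. An intercept
#' must not be included; it is added internally by the residualization step.
#' `[1 | X]` must have full column rank and `K < n - 2` so that the SNP t-test
#' retains at least one degree of freedom.
#'
#' @param values Numeric matrix `n x K` (a `K = 0` matrix is allowed).
#' @param sample_ids Character vector of length `n`.
#' @param covariate_ids Optional character vector of length `K`.
#' @return An object of class `CovariateMatrix`.
#' @export
covariate_matrix <- function(values, sample_ids,
                             covariate_ids = colnames(values)) {
  values <- as.matrix(values)
  if (length(values) == 0L) values <- matrix(0, length(sample_ids), 0L)
  storage.mode(values) <- "double"
  if (anyNA(values)) stop("covariate matrix contains missing values")
  sample_ids <- as.character(sample_ids)
  if (length(sample_ids) != nrow(values))
    stop("length(sample_ids) != nrow(values)")
  if (is.null(covariate_ids) && ncol(values) > 0L)
    covariate_ids <- paste0("covariate", seq_len(ncol(values)))
  k <- ncol(values)
  n <- nrow(values)
  if (k >= n - 2L)
    stop("number of covariates K = ", k, " must be < n - 2 = ", n - 2L)
  if (qr(cbind(1, values))$rank < k + 1L) {
    stop("[intercept | covariates] is rank deficient; ",
         "drop collinear columns among: ",
         paste(collinear_columns(values), collapse = ", "))
  }
  dimnames(values) <- list(sample_ids, covariate_ids)
  structure(list(values = values), class = "CovariateMatrix")
}

# names the covariate columns whose removal restores full rank
collinear_columns <- function(x) {
  qx <- qr(cbind(1, x))
  bad <- qx$pivot[-seq_len(qx$rank)] - 1L
  bad <- bad[bad >= 1L]
  ids <- colnames(x)
  if (is.null(ids)) ids <- paste0("covariate", seq_len(ncol(x)))
  if (length(bad)) ids[bad] else ids
}

#' @export
print.CovariateMatrix <- function(x, ...) {
  cat(sprintf("<CovariateMatrix> %d samples x %d covariates\n",
              nrow(x$values), ncol(x$values)))
  invisible(x)
}

#' Construct a cis genotype block
#'
#' The `n x q_j` dosage matrix of local SNPs for one gene. Dosages are
#' real-valued in `[0, 2]` (imputed dosages permitted).
#'
#' @param gene_id Gene identifier.
#' @param dosages Numeric matrix `n x q_j`, entries in `[0, 2]`.
#' @param snp_ids Character vector of SNP identifiers, length `q_j`.
#' @param snp_positions Integer vector of 1-based positions (bp), length `q_j`.
#' @param sample_ids Optional character vector of row (sample) ids.
#' @return An object of class `CisGenotypeBlock`.
#' @export
cis_genotype_block <- function(gene_id, dosages, snp_ids, snp_positions,
                               sample_ids = rownames(dosages)) {
  dosages <- as.matrix(dosages)
  storage.mode(dosages) <- "double"
  if (anyNA(dosages)) stop("dosage matrix contains missing values")
  if (length(dosages) && (min(dosages) < 0 || max(dosages) > 2))
    stop("dosages must lie in [0, 2]")
  snp_ids <- as.character(snp_ids)
  snp_positions <- as.integer(snp_positions)
  if (ncol(dosages) != length(snp_ids) ||
      ncol(dosages) != length(snp_positions))
    stop("snp_ids/snp_positions length must match ncol(dosages)")
  colnames(dosages) <- snp_ids
  if (!is.null(sample_ids)) rownames(dosages) <- as.character(sample_ids)
  structure(list(gene_id = as.character(gene_id), dosages = dosages,
                 snp_ids = snp_ids, snp_positions = snp_positions),
            class = "CisGenotypeBlock")
}

#' @export
print.CisGenotypeBlock <- function(x, ...) {
  cat(sprintf("<CisGenotypeBlock> gene %s: %d samples x %d SNPs\n",
              x$gene_id, nrow(x$dosages), ncol(x$dosages)))
  invisible(x)
}

#' Method configuration
#'
#' Bundles the tuning parameters shared by the eGene callers. Defaults follow
#' common cis-eQTL practice: a 1 Mb cis window around the TSS, minor allele
#' frequency at least 0.01 and at least 10 minor-allele carriers, target FDR
#' 0.05. The standard permutation variant defaults to `B = 1000` permutations;
#' the Clipper variant is designed for `B = 1` or `B` between 20 and 100.
#'
#' @param variant `"standard"` or `"clipper"`.
#' @param B Number of permutations (default 1000 for standard, 1 for clipper).
#' @param target_fdr Target false discovery rate in (0, 1).
#' @param cis_window_bp Half-width of the cis window around the TSS (bp).
#' @param maf_min Minimum folded minor allele frequency.
#' @param ma_samples_min Minimum number of individuals carrying at least one
#'   copy of the minor allele (dosage >= 0.5 counts as a carrier).
#' @param seed Integer master seed; replicate `b` uses permutation `b` of a
#'   stream generated once from this seed.
#' @param fdr_procedure FDR procedure applied to gene-level P values for the
#'   standard variant and P-value based comparators: `"storey"` (default),
#'   `"bh"` or `"by"`. Ignored by the Clipper variant.
#' @return A list of class `MethodConfig`.
#' @export
method_config <- function(variant = c("standard", "clipper"),
                          B = NULL,
                          target_fdr = 0.05,
                          cis_window_bp = 1e6L,
                          maf_min = 0.01,
                          ma_samples_min = 10L,
                          seed = 1L,
                          fdr_procedure = c("storey", "bh", "by")) {
  variant <- match.arg(variant)
  fdr_procedure <- match.arg(fdr_procedure)
  if (is.null(B)) B <- if (variant == "standard") 1000L else 1L
  B <- as.integer(B)
  if (B < 1L) stop("B must be a positive integer")
  if (variant == "clipper" && B != 1L && (B < 20L || B > 100L))
    warning("for the Clipper variant, B = 1 or 20 <= B <= 100 is recommended",
            call. = FALSE)
  if (variant == "standard" && B < 100L)
    warning("for the standard variant, B >= 100 is recommended", call. = FALSE)
  stopifnot(target_fdr > 0, target_fdr < 1, maf_min >= 0, maf_min < 0.5)
  structure(list(variant = variant, B = B, target_fdr = target_fdr,
                 cis_window_bp = as.integer(cis_window_bp),
                 maf_min = maf_min,
                 ma_samples_min = as.integer(ma_samples_min),
                 seed = as.integer(seed), fdr_procedure = fdr_procedure),
            class = "MethodConfig")
}

#' Align samples across expression, genotypes and covariates
#'
#' Restricts all matrices to the common samples, preserving the order in which
#' they appear in the expression matrix. Genotype blocks without sample ids are
#' assumed already aligned.
#'
#' @param expr An [expression_matrix()].
#' @param blocks List of [cis_genotype_block()] objects (or a genotype source
#'   from [read_dosage_tsv()] / [read_genotype_vcf()]).
#' @param covariates A [covariate_matrix()] or `NULL`.
#' @return List with elements `expr`, `blocks`, `covariates`, all restricted
#'   to the shared samples.
#' @export
align_samples <- function(expr, blocks = NULL, covariates = NULL) {
  ids <- sample_ids(expr)
  common <- ids
  pick_ids <- function(x) {
    if (inherits(x, "CisGenotypeBlock")) rownames(x$dosages)
    else if (inherits(x, "GenotypeSource")) x$sample_ids
    else if (inherits(x, "CovariateMatrix")) rownames(x$values)
    else NULL
  }
  others <- c(if (!is.null(blocks)) {
    if (inherits(blocks, "GenotypeSource")) list(blocks) else blocks
  }, if (!is.null(covariates)) list(covariates))
  for (obj in others) {
    oid <- pick_ids(obj)
    if (!is.null(oid)) common <- common[common %in% oid]
  }
  if (length(common) < 2L)
    stop("fewer than 2 samples shared across expression, genotypes and ",
         "covariates")
  out_expr <- expr
  out_expr$values <- expr$values[match(common, ids), , drop = FALSE]
  out_blocks <- blocks
  if (!is.null(blocks)) {
    if (inherits(blocks, "GenotypeSource")) {
      keep <- match(common, blocks$sample_ids)
      out_blocks$dosages <- blocks$dosages[keep, , drop = FALSE]
      out_blocks$sample_ids <- common
    } else {
      out_blocks <- lapply(blocks, function(b) {
        if (!is.null(rownames(b$dosages)))
          b$dosages <- b$dosages[match(common, rownames(b$dosages)), ,
                                 drop = FALSE]
        b
      })
      names(out_blocks) <- names(blocks)
    }
  }
  out_cov <- covariates
  if (!is.null(covariates)) {
    out_cov$values <- covariates$values[match(common, rownames(covariates$values)), ,
                                        drop = FALSE]
  }
  list(expr = out_expr, blocks = out_blocks, covariates = out_cov)
}
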