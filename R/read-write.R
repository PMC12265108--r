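#' Read a FastQTL-style expression BED file
#'
#' Tab-separated with a header row; the first four columns are
#' `chrom`, `start`, `end`, `gene_id` and the remaining columns are samples.
#' BED coordinates are 0-based half-open, so the TSS is taken as `start + 1`
#' (the GTEx convention places the TSS at the interval start). Values are
#' transposed to samples x genes.
#'
#' @param path Path to the BED file (plain or gzip).
#' @return An [expression_matrix()] with TSS annotation.
#' @export
read_expression_bed <- function(path) {
  tab <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE,
                         comment = "")
  if (ncol(tab) < 5L)
    stop("expression BED needs 4 coordinate columns plus >= 1 sample column")
  names(tab)[1:4] <- c("chrom", "start", "end", "gene_id")
  gid <- as.character(tab$gene_id)
  if (anyDuplicated(gid))
    stop("duplicate gene id in expression BED: ",
         paste(unique(gid[duplicated(gid)]), collapse = ", "))
  vals <- tab[, -(1:4), drop = FALSE]
  bad <- !vapply(vals, is.numeric, logical(1))
  if (any(bad)) {
    col <- names(vals)[which(bad)[1]]
    row <- which(is.na(suppressWarnings(as.numeric(vals[[which(bad)[1]]]))))[1]
    stop("non-numeric expression value in sample column '", col,
         "', data row ", if (is.na(row)) "?" else row)
  }
  m <- t(as.matrix(vals))
  expression_matrix(m, sample_ids = names(vals), gene_ids = gid,
                    tss = tibble(gene_id = gid, chrom = as.character(tab$chrom),
                                 tss = as.integer(tab$start) + 1L))
}

#' Write an expression matrix as a FastQTL-style BED file
#'
#' Inverse of [read_expression_bed()]: column 2 is `tss - 1` (0-based) and
#' column 3 is `tss`.
#'
#' @param expr An [expression_matrix()] with TSS annotation.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_expression_bed <- function(expr, path) {
  if (is.null(expr$tss)) stop("expression matrix has no TSS annotation")
  out <- tibble(`#chr` = expr$tss$chrom, start = expr$tss$tss - 1L,
                end = expr$tss$tss, gene_id = gene_ids(expr))
  vals <- as_tibble(t(expr$values), .name_repair = "minimal")
  names(vals) <- sample_ids(expr)
  readr::write_tsv(dplyr::bind_cols(out, vals), path, progress = FALSE)
  invisible(path)
}

#' Read a plain dosage matrix TSV
#'
#' Expected columns: `snp_id`, `chrom`, `pos`, then one column per sample
#' holding dosages in `[0, 2]`.
#'
#' @param path Path to the TSV.
#' @return A `GenotypeSource`: list with `snp_ids`, `chrom`, `pos`,
#'   `sample_ids` and an `n x q` dosage matrix `dosages`.
#' @export
read_dosage_tsv <- function(path) {
  tab <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  stopifnot(all(c("snp_id", "chrom", "pos") %in% names(tab)))
  samp <- setdiff(names(tab), c("snp_id", "chrom", "pos"))
  dos <- t(as.matrix(tab[, samp, drop = FALSE]))
  rownames(dos) <- samp
  colnames(dos) <- tab$snp_id
  structure(list(snp_ids = as.character(tab$snp_id),
                 chrom = as.character(tab$chrom),
                 pos = as.integer(tab$pos),
                 sample_ids = samp, dosages = dos),
            class = "GenotypeSource")
}

#' Write a dosage matrix TSV
#'
#' @param source A `GenotypeSource` (see [read_dosage_tsv()]).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_dosage_tsv <- function(source, path) {
  dos <- as_tibble(t(source$dosages), .name_repair = "minimal")
  names(dos) <- source$sample_ids
  out <- dplyr::bind_cols(tibble(snp_id = source$snp_ids,
                                 chrom = source$chrom, pos = source$pos), dos)
  readr::write_tsv(out, path, progress = FALSE)
  invisible(path)
}

#' Read genotypes from a VCF into a dosage source
#'
#' Uses the `DS` FORMAT field when present, otherwise counts alternate alleles
#' in `GT`. Multiallelic records are skipped with a warning.
#'
#' @param path Path to a VCF (optionally bgzipped).
#' @return A `GenotypeSource` (see [read_dosage_tsv()]).
#' @export
read_genotype_vcf <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  as_fix_matrix <- function(f) {
    if (is.null(dim(f))) matrix(f, nrow = 1, dimnames = list(NULL, names(f)))
    else f
  }
  fix <- as_fix_matrix(vcfR::getFIX(v))
  alt <- fix[, "ALT"]
  multi <- grepl(",", alt, fixed = TRUE)
  if (any(multi)) {
    warning(sum(multi), " multiallelic VCF record(s) skipped", call. = FALSE)
    v <- v[!multi, ]
    fix <- as_fix_matrix(vcfR::getFIX(v))
  }
  has_ds <- "DS" %in% vcfR::vcf_field_names(v, tag = "FORMAT")$ID
  if (has_ds) {
    dos <- vcfR::extract.gt(v, element = "DS", as.numeric = TRUE)
  } else {
    gt <- vcfR::extract.gt(v, element = "GT")
    dos <- apply(gt, c(1, 2), function(g) {
      if (is.na(g)) return(NA_real_)
      sum(as.numeric(strsplit(g, "[/|]")[[1]]) > 0)
    })
  }
  if (anyNA(dos)) stop("missing genotypes in VCF; impute or filter upstream")
  ids <- fix[, "ID"]
  ids[is.na(ids) | ids == "."] <- paste0(fix[, "CHROM"], ":",
                                         fix[, "POS"])[is.na(ids) | ids == "."]
  src <- structure(list(snp_ids = unname(ids), chrom = unname(fix[, "CHROM"]),
                        pos = as.integer(fix[, "POS"]),
                        sample_ids = colnames(dos), dosages = unname(t(dos))),
                   class = "GenotypeSource")
  rownames(src$dosages) <- src$sample_ids
  colnames(src$dosages) <- src$snp_ids
  src
}

#' Read a covariate TSV
#'
#' Accepts either orientation (samples x covariates or covariates x samples);
#' the orientation is auto-detected by matching the supplied sample ids
#' against the header or the first column.
#'
#' @param path Path to the TSV. First column holds row ids.
#' @param sample_ids Character vector of expected sample ids.
#' @return A [covariate_matrix()] restricted to `sample_ids` (in that order).
#' @export
read_covariates_tsv <- function(path, sample_ids) {
  tab <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  header_hits <- sum(sample_ids %in% names(tab)[-1])
  column_hits <- sum(sample_ids %in% as.character(tab[[1]]))
  if (header_hits == 0 && column_hits == 0)
    stop("covariate file matches none of the expected sample ids")
  if (header_hits >= column_hits) {  # covariates x samples
    miss <- setdiff(sample_ids, names(tab)[-1])
    if (length(miss)) stop("covariate file missing samples: ",
                           paste(head(miss, 5), collapse = ", "))
    m <- t(as.matrix(tab[, sample_ids, drop = FALSE]))
    covariate_matrix(m, sample_ids, covariate_ids = as.character(tab[[1]]))
  } else {                           # samples x covariates
    ids <- as.character(tab[[1]])
    miss <- setdiff(sample_ids, ids)
    if (length(miss)) stop("covariate file missing samples: ",
                           paste(head(miss, 5), collapse = ", "))
    m <- as.matrix(tab[match(sample_ids, ids), -1, drop = FALSE])
    covariate_matrix(m, sample_ids, covariate_ids = names(tab)[-1])
  }
}

#' Write per-gene eGene results to a TSV
#'
#' One row per gene, ordered by `gene_id`; columns `gene_id`, `lead_snp`,
#' `statistic`, then `gene_pvalue` or `contrast_score` (whichever the method
#' produced), `q_value`, `is_egene`.
#'
#' @param results Tibble of per-gene results (as returned by [tidy()] on a
#'   fit, or the `$results` element of an `egene_fit`).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_results_tsv <- function(results, path) {
  results <- as_tibble(results)
  score_col <- intersect(c("gene_pvalue", "contrast_score"), names(results))
  cols <- c("gene_id", "lead_snp", "statistic", score_col, "q_value",
            "is_egene")
  missing_cols <- setdiff(cols, names(results))
  if (length(missing_cols))
    stop("results are missing columns: ", paste(missing_cols, collapse = ", "))
  out <- dplyr::arrange(results[, cols], .data$gene_id)
  out$is_egene <- ifelse(out$is_egene, "true", "false")
  readr::write_tsv(out, path, progress = FALSE)
  invisible(path)
}

#' Read a results TSV written by [write_results_tsv()]
#'
#' @param path Path to the TSV.
#' @return A tibble with `is_egene` restored to logical.
#' @export
read_results_tsv <- function(path) {
  tab <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  if (!is.logical(tab$is_egene))
    tab$is_egene <- tolower(as.character(tab$is_egene)) == "true"
  tab
}
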