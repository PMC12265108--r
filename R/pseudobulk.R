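#' Pseudobulk a single-cell count matrix for one cell type
#'
#' Each count is normalized as `log(count / per-cell total * 10000 + 1)`
#' (natural log). For each gene-individual combination the average is then
#' taken in the non-log space, i.e. over `exp(normalized) - 1 =
#' count / total * 10000` across that individual's cells of the given type.
#' This mirrors the NormalizeData + AverageExpression pseudobulk convention
#' used for per-individual single-cell eQTL analysis.
#'
#' @param counts Nonnegative integer matrix, genes x cells.
#' @param cell_to_individual Character vector, length `ncol(counts)`: the
#'   individual each cell belongs to.
#' @param cell_to_type Character vector, length `ncol(counts)`: cell-type
#'   label per cell.
#' @param cell_type The cell type to aggregate.
#' @param individuals Optional character vector of individuals to keep;
#'   individuals with zero cells of the type are dropped with a warning.
#' @return An [expression_matrix()] (individuals x genes, no TSS annotation).
#' @export
pseudobulk <- function(counts, cell_to_individual, cell_to_type, cell_type,
                       individuals = NULL) {
  counts <- as.matrix(counts)
  stopifnot(length(cell_to_individual) == ncol(counts),
            length(cell_to_type) == ncol(counts))
  sel <- cell_to_type == cell_type
  if (!any(sel)) stop("no cells of type '", cell_type, "'")
  counts <- counts[, sel, drop = FALSE]
  indiv <- as.character(cell_to_individual[sel])
  totals <- colSums(counts)
  if (any(totals == 0)) stop("cells with zero total count must be removed")
  if (is.null(individuals)) individuals <- unique(indiv)
  absent <- setdiff(individuals, indiv)
  if (length(absent)) {
    warning("individual(s) with zero cells of type '", cell_type,
            "' excluded: ", paste(head(absent, 5), collapse = ", "),
            call. = FALSE)
    individuals <- setdiff(individuals, absent)
  }
  # exp(log(c/T * 1e4 + 1)) - 1 == c/T * 1e4, so average that directly
  delog <- sweep(counts, 2, totals, "/") * 1e4
  agg <- vapply(individuals, function(id) {
    cols <- which(indiv == id)
    rowMeans(delog[, cols, drop = FALSE])
  }, numeric(nrow(counts)))
  gene_ids <- rownames(counts)
  if (is.null(gene_ids)) gene_ids <- paste0("gene", seq_len(nrow(counts)))
  expression_matrix(t(agg), sample_ids = individuals, gene_ids = gene_ids)
}

#' Keep genes expressed in a minimum fraction of individuals
#'
#' Retains genes with nonzero expression in at least `min_fraction` of
#' individuals (boundary inclusive: exactly 90% passes at the default).
#'
#' @param expr An [expression_matrix()] with nonnegative values.
#' @param min_fraction Minimum fraction of individuals with value > 0.
#' @return The filtered [expression_matrix()]; may have zero genes.
#' @export
filter_genes_nonzero <- function(expr, min_fraction = 0.9) {
  frac <- colMeans(expr$values > 0)
  keep <- frac >= min_fraction
  expr$values <- expr$values[, keep, drop = FALSE]
  if (!is.null(expr$tss)) expr$tss <- expr$tss[keep, , drop = FALSE]
  expr
}
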