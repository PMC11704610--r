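#' Genes-by-cells count matrix with cell metadata
#'
#' A light container for UMI (or spot) count data: a sparse genes x cells
#' matrix plus a per-cell metadata tibble. Per-cell QC covariates (total
#' UMI, detected genes, mitochondrial fraction) are computed on construction
#' so downstream filters never recompute them inconsistently.
#'
#' @param counts Non-negative numeric matrix or `Matrix` (genes x cells) with
#'   row and column names; coerced to `dgCMatrix`.
#' @param cell_meta Optional tibble with a `cell_id` column matching the
#'   matrix columns; typically carries `condition` and `replicate`.
#' @param mito_prefix Prefix identifying mitochondrial genes for the
#'   `mito_frac` covariate (default `"mt-"`, case-insensitive).
#'
#' @return An object of class `"count_matrix"` with elements `counts`
#'   (dgCMatrix), `gene_ids`, `cell_ids` and `cell_meta`.
#' @export
#' @examples
#' m <- count_matrix(matrix(0:3, 2, 2,
#'   dimnames = list(c("g1", "g2"), c("c1", "c2"))
#' ))
#' m
count_matrix <- function(counts, cell_meta = NULL, mito_prefix = "mt-") {
  counts <- methods::as(methods::as(Matrix::Matrix(counts, sparse = TRUE),
    "generalMatrix"
  ), "CsparseMatrix")
  if (is.null(rownames(counts)) || is.null(colnames(counts))) {
    abort("`counts` must have gene (row) and cell (column) names.")
  }
  if (nrow(counts) == 0 || ncol(counts) == 0) {
    abort("`counts` is empty (zero genes or zero cells).")
  }
  if (anyDuplicated(rownames(counts))) abort("duplicate gene ids in `counts`.")
  if (anyDuplicated(colnames(counts))) abort("duplicate cell ids in `counts`.")
  if (any(counts@x < 0)) abort("`counts` must be non-negative.")
  gene_ids <- rownames(counts)
  cell_ids <- colnames(counts)
  if (is.null(cell_meta)) {
    cell_meta <- tibble(cell_id = cell_ids)
  } else {
    cell_meta <- as_tibble(cell_meta)
    if (!"cell_id" %in% names(cell_meta)) {
      abort("`cell_meta` must contain a `cell_id` column.")
    }
    if (!setequal(cell_meta$cell_id, cell_ids)) {
      abort("`cell_meta$cell_id` must match the matrix columns.")
    }
    cell_meta <- cell_meta[match(cell_ids, cell_meta$cell_id), , drop = FALSE]
  }
  mito <- grepl(paste0("^", mito_prefix), gene_ids, ignore.case = TRUE)
  total <- Matrix::colSums(counts)
  cell_meta$total_umi <- as.numeric(total)
  cell_meta$detected_genes <- as.integer(Matrix::colSums(counts > 0))
  cell_meta$mito_frac <- ifelse(
    total > 0, as.numeric(Matrix::colSums(counts[mito, , drop = FALSE])) / total, 0
  )
  structure(
    list(
      counts = counts, gene_ids = gene_ids, cell_ids = cell_ids,
      cell_meta = cell_meta
    ),
    class = "count_matrix"
  )
}

#' @export
print.count_matrix <- function(x, ...) {
  cat(sprintf(
    "<count_matrix> %d genes x %d cells\n",
    length(x$gene_ids), length(x$cell_ids)
  ))
  if ("condition" %in% names(x$cell_meta)) {
    tab <- table(x$cell_meta$condition)
    cat("  conditions:", paste(names(tab), tab, sep = "=", collapse = ", "), "\n")
  }
  cat(sprintf(
    "  median UMI/cell: %.4g | median detected genes: %.4g\n",
    median(x$cell_meta$total_umi), median(x$cell_meta$detected_genes)
  ))
  invisible(x)
}

#' @export
dim.count_matrix <- function(x) dim(x$counts)

# subset cells, keeping metadata aligned
subset_cells <- function(m, keep) {
  cm <- m
  cm$counts <- m$counts[, keep, drop = FALSE]
  cm$cell_ids <- colnames(cm$counts)
  cm$cell_meta <- m$cell_meta[match(cm$cell_ids, m$cell_meta$cell_id), ,
    drop = FALSE
  ]
  cm
}

subset_genes <- function(m, keep) {
  cm <- m
  cm$counts <- m$counts[keep, , drop = FALSE]
  cm$gene_ids <- rownames(cm$counts)
  cm
}
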