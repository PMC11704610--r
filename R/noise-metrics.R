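#' Quality-control filtering of cells
#'
#' Removes low-quality cells from a UMI count matrix using the standard
#' covariates: number of detected genes, total UMI counts, and the fraction
#' of counts mapping to mitochondrial genes. Minimum thresholds are
#' inclusive (`>=`); maximum thresholds and the mitochondrial fraction are
#' strict (`<`). Typical presets: deeply sequenced mESC-style data uses
#' `min_genes = 4000, min_umi = 10000, max_mito_frac = 0.1`; a
#' moderate-depth Jurkat-style run uses strict ranges, e.g.
#' `min_genes = 3001, max_genes = 5000, min_umi = 8001, max_umi = 15000`.
#'
#' @param m A [count_matrix()].
#' @param min_genes,min_umi Inclusive lower bounds (`NULL` disables).
#' @param max_genes,max_umi Strict upper bounds (`NULL` disables).
#' @param max_mito_frac Strict upper bound on mitochondrial fraction
#'   (`NULL` disables).
#' @param mito_prefix Prefix identifying mitochondrial genes (re-applied so
#'   the fraction matches the prefix asked for here).
#'
#' @return The filtered [count_matrix()]; attribute `"qc_report"` is a
#'   tibble counting cells removed per criterion.
#' @export
qc_filter_cells <- function(m, min_genes = 4000, min_umi = 10000,
                            max_genes = NULL, max_umi = NULL,
                            max_mito_frac = 0.1, mito_prefix = "mt-") {
  stopifnot(inherits(m, "count_matrix"))
  meta <- count_matrix(m$counts, m$cell_meta[, setdiff(
    names(m$cell_meta), c("total_umi", "detected_genes", "mito_frac")
  ), drop = FALSE], mito_prefix = mito_prefix)$cell_meta
  pass <- list(
    min_genes = if (is.null(min_genes)) NULL else meta$detected_genes >= min_genes,
    max_genes = if (is.null(max_genes)) NULL else meta$detected_genes < max_genes,
    min_umi = if (is.null(min_umi)) NULL else meta$total_umi >= min_umi,
    max_umi = if (is.null(max_umi)) NULL else meta$total_umi < max_umi,
    max_mito_frac = if (is.null(max_mito_frac)) {
      NULL
    } else {
      meta$mito_frac < max_mito_frac
    }
  )
  pass <- pass[!vapply(pass, is.null, logical(1))]
  report <- tibble(
    criterion = names(pass),
    n_removed = unname(vapply(pass, function(p) sum(!p), integer(1)))
  )
  keep <- if (length(pass)) Reduce(`&`, pass) else rep(TRUE, ncol(m$counts))
  if (!any(keep)) {
    abort(paste0(
      "qc_filter_cells removed every cell. Removed per criterion: ",
      paste(report$criterion, report$n_removed, sep = "=", collapse = ", ")
    ))
  }
  out <- subset_cells(m, keep)
  attr(out, "qc_report") <- report
  out
}

#' Filter genes for sufficient sequencing coverage
#'
#' Restricts the matrix to genes with enough coverage for reliable noise
#' quantification: mean count and detection fraction must both clear their
#' thresholds, and (when a `condition` column is present) must do so within
#' every condition separately (intersection rule), so fold changes are never
#' computed on a gene that is unreliable in one arm.
#'
#' @param m A [count_matrix()].
#' @param min_mean_count Minimum per-condition mean raw count (default 0.1).
#' @param min_detect_frac Minimum per-condition fraction of cells with a
#'   nonzero count, in \[0, 1\] (default 0.05).
#'
#' @return The filtered [count_matrix()] (possibly with zero genes, with a
#'   warning).
#' @export
gene_coverage_filter <- function(m, min_mean_count = 0.1,
                                 min_detect_frac = 0.05) {
  stopifnot(inherits(m, "count_matrix"))
  check_param(min_detect_frac, "min_detect_frac", min = 0, max = 1)
  check_param(min_mean_count, "min_mean_count", min = 0)
  groups <- if ("condition" %in% names(m$cell_meta)) {
    split(seq_along(m$cell_ids), m$cell_meta$condition)
  } else {
    list(all = seq_along(m$cell_ids))
  }
  keep <- rep(TRUE, length(m$gene_ids))
  for (idx in groups) {
    sub <- m$counts[, idx, drop = FALSE]
    keep <- keep &
      Matrix::rowMeans(sub) >= min_mean_count &
      Matrix::rowMeans(sub > 0) >= min_detect_frac
  }
  if (!any(keep)) {
    warn("gene_coverage_filter retained zero genes.")
  }
  subset_genes(m, keep)
}

#' Depth normalization ("raw" method)
#'
#' The simplest normalization: each cell's counts are divided by that cell's
#' total and rescaled, so every cell's normalized values sum to `scale`
#' (default 1e4). Within-cell proportions are preserved exactly.
#'
#' @param m A [count_matrix()].
#' @param scale Per-cell total after normalization.
#'
#' @return A [count_matrix()] whose `counts` hold normalized (real-valued)
#'   expression; per-cell metadata is retained from the input.
#' @export
raw_normalize <- function(m, scale = 1e4) {
  stopifnot(inherits(m, "count_matrix"))
  check_param(scale, "scale", min = 0, strict = TRUE)
  totals <- Matrix::colSums(m$counts)
  if (any(totals == 0)) {
    abort(paste0(
      "raw_normalize: zero-total cell(s): ",
      paste(head(m$cell_ids[totals == 0], 5), collapse = ", ")
    ))
  }
  out <- m
  out$counts <- m$counts %*% Matrix::Diagonal(
    n = length(totals), x = scale / totals
  )
  dimnames(out$counts) <- dimnames(m$counts)
  out$counts <- methods::as(out$counts, "CsparseMatrix")
  attr(out, "normalized") <- TRUE
  out
}

# mean/var/cv2/fano for a genes x cells (sparse) block
block_noise_stats <- function(counts) {
  n <- ncol(counts)
  mu <- as.numeric(Matrix::rowMeans(counts))
  ssq <- as.numeric(Matrix::rowSums(counts^2))
  v <- (ssq - n * mu^2) / (n - 1)
  v <- pmax(v, 0) # guard float round-off for constant rows
  tibble(
    gene_id = rownames(counts),
    n_cells = n,
    mean = mu,
    var = v,
    cv2 = ifelse(mu > 0, v / mu^2, NA_real_),
    fano = ifelse(mu > 0, v / mu, NA_real_),
    undefined = mu == 0
  )
}

#' Per-gene noise summary (mean, variance, CV-squared, Fano factor)
#'
#' Computes, for every gene, the sample mean, unbiased (n-1) variance,
#' squared coefficient of variation `cv2 = var / mean^2` and Fano factor
#' `fano = var / mean` across cells. Genes with zero mean are flagged
#' `undefined` (their `cv2`/`fano` are `NA`), never silently dropped. The
#' identity `fano == cv2 * mean` holds to machine precision.
#'
#' @param x A [count_matrix()], a per-cell tibble with `count_<gene>`
#'   columns (smFISH-style cell table), or a numeric vector of counts for a
#'   single gene.
#' @param by Character vector of metadata columns to group by before
#'   summarising (e.g. `c("condition", "replicate")`); `NULL` summarises
#'   across all cells. Ignored for numeric input.
#' @param ... Unused.
#'
#' @return A tibble with columns `gene_id`, `n_cells`, `mean`, `var`,
#'   `cv2`, `fano`, `undefined`, plus any `by` columns.
#' @export
#' @examples
#' noise_summary(c(2, 4, 6, 8)) # mean 5, var 20/3, fano 4/3, cv2 4/15
noise_summary <- function(x, ...) UseMethod("noise_summary")

#' @rdname noise_summary
#' @export
noise_summary.default <- function(x, ...) {
  if (!is.numeric(x)) abort("no noise_summary() method for this input.")
  if (length(x) < 2) abort("noise_summary needs at least 2 cells.")
  mat <- matrix(x, nrow = 1, dimnames = list("gene", NULL))
  block_noise_stats(Matrix::Matrix(mat, sparse = TRUE))
}

#' @rdname noise_summary
#' @export
noise_summary.count_matrix <- function(x, by = NULL, ...) {
  groups <- group_index(x$cell_meta, by)
  out <- purrr::map(groups, function(idx) {
    if (length(idx) < 2) abort("noise_summary needs at least 2 cells per group.")
    block_noise_stats(x$counts[, idx, drop = FALSE])
  })
  bind_group_results(out, groups, x$cell_meta, by)
}

#' @rdname noise_summary
#' @export
noise_summary.data.frame <- function(x, by = intersect(
                                       c("condition", "replicate"), names(x)
                                     ), ...) {
  count_cols <- grep("^count_", names(x), value = TRUE)
  if (length(count_cols) == 0) {
    abort("cell table has no `count_<gene>` columns.")
  }
  if (length(by) == 0) by <- NULL
  groups <- group_index(x, by)
  out <- purrr::map(groups, function(idx) {
    if (length(idx) < 2) abort("noise_summary needs at least 2 cells per group.")
    counts <- t(as.matrix(x[idx, count_cols, drop = FALSE]))
    rownames(counts) <- sub("^count_", "", count_cols)
    block_noise_stats(Matrix::Matrix(counts, sparse = TRUE))
  })
  bind_group_results(out, groups, x, by)
}

group_index <- function(meta, by) {
  if (is.null(by)) {
    return(list(seq_len(nrow(meta))))
  }
  missing <- setdiff(by, names(meta))
  if (length(missing)) {
    abort(paste0("grouping column(s) not found: ", paste(missing, collapse = ", ")))
  }
  split(seq_len(nrow(meta)), meta[, by, drop = FALSE], drop = TRUE, sep = "\r")
}

bind_group_results <- function(results, groups, meta, by) {
  if (is.null(by)) {
    return(results[[1]])
  }
  keys <- purrr::map(groups, function(idx) meta[idx[1], by, drop = FALSE])
  dplyr::bind_rows(purrr::map2(
    results, keys,
    function(res, key) dplyr::bind_cols(key[rep(1, nrow(res)), , drop = FALSE], res)
  ))
}

#' Treated/control fold changes of noise metrics
#'
#' Joins two per-gene noise summaries and reports per-gene fold changes
#' `d_mean`, `d_cv2`, `d_fano` (treated / control). If both summaries carry
#' a `replicate` column, genes are matched within replicate. Genes whose
#' control metrics are zero, undefined or missing in one summary are
#' excluded; the exclusions and reasons are kept in the `"excluded"`
#' attribute.
#'
#' @param treated,control Noise summaries from [noise_summary()].
#' @param method Provenance label stored in the `method` column.
#'
#' @return A tibble `gene_id` (+ `replicate` if present), `d_mean`,
#'   `d_cv2`, `d_fano`, `method`.
#' @export
fold_change_table <- function(treated, control, method = "raw") {
  keys <- c("gene_id", intersect(
    intersect("replicate", names(treated)), names(control)
  ))
  joined <- dplyr::inner_join(
    treated, control,
    by = keys, suffix = c("_t", "_c")
  )
  if (nrow(joined) == 0) abort("no overlapping genes between summaries.")
  bad_undefined <- joined$undefined_t | joined$undefined_c
  bad_zero <- !bad_undefined &
    (joined$mean_c <= 0 | joined$cv2_c <= 0 | joined$fano_c <= 0 |
      joined$cv2_t <= 0 | joined$fano_t <= 0)
  excluded <- tibble(
    gene_id = joined$gene_id[bad_undefined | bad_zero],
    reason = c(
      rep("undefined metrics (zero mean)", sum(bad_undefined)),
      rep("zero control or treated metric", sum(bad_zero))
    )[order(c(which(bad_undefined), which(bad_zero)))]
  )
  keep <- !(bad_undefined | bad_zero)
  out <- tibble(
    gene_id = joined$gene_id[keep]
  )
  for (k in setdiff(keys, "gene_id")) out[[k]] <- joined[[k]][keep]
  out$d_mean <- joined$mean_t[keep] / joined$mean_c[keep]
  out$d_cv2 <- joined$cv2_t[keep] / joined$cv2_c[keep]
  out$d_fano <- joined$fano_t[keep] / joined$fano_c[keep]
  out$method <- method
  attr(out, "excluded") <- excluded
  out
}

#' Average noise metrics across biological replicates
#'
#' Collapses a per-replicate noise summary (or fold-change table) to one row
#' per gene by the arithmetic mean of each metric over replicates. A gene
#' must be present in every replicate to be retained (intersection rule; no
#' imputation).
#'
#' @param x A tibble with `gene_id`, a `replicate` column and numeric metric
#'   columns (e.g. from `noise_summary(..., by = c("condition","replicate"))`
#'   grouped within one condition, or from [fold_change_table()]).
#'
#' @return A tibble with one row per gene; `n_replicates` records how many
#'   replicates were averaged.
#' @export
replicate_average <- function(x) {
  if (!"replicate" %in% names(x)) {
    return(as_tibble(x)) # single replicate: identity
  }
  n_rep <- length(unique(x$replicate))
  metric_cols <- names(x)[vapply(x, is.numeric, logical(1))]
  metric_cols <- setdiff(metric_cols, "replicate")
  x |>
    dplyr::group_by(.data$gene_id) |>
    dplyr::filter(dplyr::n_distinct(.data$replicate) == n_rep) |>
    dplyr::summarise(
      dplyr::across(dplyr::all_of(metric_cols), mean),
      n_replicates = n_rep,
      .groups = "drop"
    )
}

#' Random split negative control
#'
#' Splits the cells of one condition into two random, disjoint halves and
#' compares their per-gene noise metrics by rank-sum tests. On unperturbed
#' data no significant difference in CV-squared or Fano should be found;
#' this is the negative control for any claimed treatment effect.
#'
#' @param m A [count_matrix()].
#' @param seed Integer seed (same seed, same split).
#'
#' @return A list: `half_a`, `half_b` ([count_matrix()]s of equal size, +/-
#'   one cell) and `report`, a tibble of rank-sum p-values for `cv2` and
#'   `fano` across genes.
#' @export
negative_control_split <- function(m, seed = 1L) {
  stopifnot(inherits(m, "count_matrix"))
  n <- length(m$cell_ids)
  if (n < 4) abort("need at least 4 cells to split.")
  set.seed(seed)
  idx_a <- sort(sample.int(n, n %/% 2))
  half_a <- subset_cells(m, idx_a)
  half_b <- subset_cells(m, setdiff(seq_len(n), idx_a))
  sa <- noise_summary(half_a)
  sb <- noise_summary(half_b)
  shared <- dplyr::inner_join(sa, sb, by = "gene_id", suffix = c("_a", "_b")) |>
    dplyr::filter(!.data$undefined_a, !.data$undefined_b)
  report <- dplyr::bind_rows(lapply(c("cv2", "fano"), function(metric) {
    res <- compare_populations(
      shared[[paste0(metric, "_a")]], shared[[paste0(metric, "_b")]],
      test = "rank_sum", alternative = "two_sided"
    )
    dplyr::mutate(res, metric = metric, .before = 1)
  }))
  list(half_a = half_a, half_b = half_b, report = report)
}

#' Fraction of genes with amplified noise
#'
#' The penetrance statistic: the fraction of genes whose fold change in a
#' chosen metric exceeds a threshold (default 1, i.e. any amplification).
#'
#' @param fc A fold-change tibble from [fold_change_table()].
#' @param metric Column to threshold (default `"d_fano"`).
#' @param threshold Strict threshold (`>`).
#'
#' @return A single numeric fraction in \[0, 1\].
#' @export
#' @examples
#' fc <- tibble::tibble(gene_id = letters[1:3], d_fano = c(0.5, 1.5, 2))
#' amplified_fraction(fc) # 2/3
amplified_fraction <- function(fc, metric = "d_fano", threshold = 1) {
  if (!metric %in% names(fc)) {
    abort(sprintf("metric column `%s` not found.", metric))
  }
  vals <- fc[[metric]]
  vals <- vals[is.finite(vals)]
  if (length(vals) == 0) abort("no finite fold changes.")
  mean(vals > threshold)
}
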