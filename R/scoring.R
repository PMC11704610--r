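#' Median squared relative deviation from a reference
#'
#' The per-metric deviation statistic used to score a normalization method
#' against the smFISH reference: for aligned per-gene fold changes `D`
#' (method) and `E` (reference), `chi = median(((D - E) / E)^2)` over genes.
#' It is zero when the method reproduces the reference, 1 when it doubles
#' every reference fold change, and — being a median of per-gene terms — is
#' insensitive to arbitrary corruption of fewer than half the genes.
#'
#' @param d Numeric vector of the method's per-gene values (aligned to `e`).
#' @param e Numeric vector of reference per-gene values; entries with
#'   `e == 0` or non-finite pairs are excluded pairwise.
#'
#' @return A single non-negative number.
#' @export
#' @examples
#' chi_metric(c(2, 1.5, 1), c(1, 1.5, 2)) # median of (1, 0, 0.25) = 0.25
chi_metric <- function(d, e) {
  if (length(d) != length(e)) abort("`d` and `e` must be aligned (same length).")
  keep <- is.finite(d) & is.finite(e) & e != 0
  if (!any(keep)) abort("no usable gene pairs (reference zero or non-finite).")
  median(((d[keep] - e[keep]) / e[keep])^2)
}

#' Combined deviation score
#'
#' The linear sum of the three per-metric medians: `S = chi_mean + chi_cv2 +
#' chi_fano`. The method with minimal `S` matches the smFISH reference most
#' closely.
#'
#' @param chi_mean,chi_cv2,chi_fano Non-negative per-metric deviations from
#'   [chi_metric()].
#'
#' @return A single non-negative number.
#' @export
combined_score <- function(chi_mean, chi_cv2, chi_fano) {
  vals <- c(chi_mean, chi_cv2, chi_fano)
  check_param(vals, "chi values", min = 0)
  sum(vals)
}

score_one_method <- function(method_tbl, reference) {
  joined <- dplyr::inner_join(
    method_tbl, reference,
    by = "gene_id", suffix = c("_d", "_e")
  )
  if (nrow(joined) == 0) abort("method shares no genes with the reference.")
  chis <- vapply(c("d_mean", "d_cv2", "d_fano"), function(col) {
    chi_metric(joined[[paste0(col, "_d")]], joined[[paste0(col, "_e")]])
  }, numeric(1))
  tibble(
    chi_mean = chis[["d_mean"]],
    chi_cv2 = chis[["d_cv2"]],
    chi_fano = chis[["d_fano"]],
    score = combined_score(chis[["d_mean"]], chis[["d_cv2"]], chis[["d_fano"]]),
    n_genes = nrow(joined)
  )
}

#' Score and rank methods against an smFISH reference
#'
#' Computes, for every method's fold-change table, the per-metric deviations
#' `chi_mean`, `chi_cv2`, `chi_fano` against the reference and the combined
#' score `S`, then ranks methods by ascending `S` (ties broken
#' lexicographically by method name).
#'
#' @param methods Named list of fold-change tibbles (columns `gene_id`,
#'   `d_mean`, `d_cv2`, `d_fano`), one per method; names are the method
#'   labels.
#' @param reference The smFISH reference fold-change tibble (same columns).
#'
#' @return A tibble sorted by `score`: `method`, `chi_mean`, `chi_cv2`,
#'   `chi_fano`, `score`, `n_genes`, `rank`.
#' @export
rank_methods <- function(methods, reference) {
  if (!is.list(methods) || is.null(names(methods)) ||
    any(names(methods) == "")) {
    abort("`methods` must be a named list of fold-change tables.")
  }
  out <- purrr::imap_dfr(methods, function(tbl, name) {
    dplyr::mutate(score_one_method(tbl, reference), method = name, .before = 1)
  })
  out <- dplyr::arrange(out, .data$score, .data$method)
  out$rank <- seq_len(nrow(out))
  out
}

#' Systematic underestimation diagnostic
#'
#' Quantifies, per method and metric, how often the method's fold change is
#' strictly closer to 1 than the reference's — `|log2 D| < |log2 E|`, ties
#' counting as neither — together with the median attenuation
#' `median(|log2 D| - |log2 E|)` (negative when the method compresses fold
#' changes toward 1, the signature of capture/depth thinning in sequencing
#' data).
#'
#' @inheritParams rank_methods
#'
#' @return A tibble per method x metric: `method`, `metric`,
#'   `frac_underestimated`, `median_log2_attenuation`, `n_genes`.
#' @export
underestimation_report <- function(methods, reference) {
  purrr::imap_dfr(methods, function(tbl, name) {
    joined <- dplyr::inner_join(tbl, reference,
      by = "gene_id", suffix = c("_d", "_e")
    )
    purrr::map_dfr(c("d_mean", "d_cv2", "d_fano"), function(col) {
      d <- joined[[paste0(col, "_d")]]
      e <- joined[[paste0(col, "_e")]]
      keep <- is.finite(d) & is.finite(e) & d > 0 & e > 0
      ld <- abs(log2(d[keep]))
      le <- abs(log2(e[keep]))
      tibble(
        method = name,
        metric = sub("^d_", "", col),
        frac_underestimated = mean(ld < le),
        median_log2_attenuation = median(ld - le),
        n_genes = sum(keep)
      )
    })
  })
}

#' Pairwise correlation of log fold-change vectors
#'
#' Convenience utility: Pearson correlations between methods' per-gene
#' `log2` fold changes for one metric, as used to compare how similarly
#' methods rank genes.
#'
#' @inheritParams rank_methods
#' @param metric Fold-change column to correlate (default `"d_fano"`).
#'
#' @return A symmetric correlation matrix (methods x methods).
#' @export
method_fold_change_correlation <- function(methods, metric = "d_fano") {
  tbl <- purrr::imap(methods, function(m, name) {
    tibble(gene_id = m$gene_id, value = log2(m[[metric]]), method = name)
  }) |>
    dplyr::bind_rows() |>
    tidyr::pivot_wider(names_from = "method", values_from = "value")
  cor(as.matrix(tbl[, -1]), use = "pairwise.complete.obs")
}
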