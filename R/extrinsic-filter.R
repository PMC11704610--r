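#' Two-sample permutation test on group means
#'
#' Tests whether two samples (e.g. cell areas of control and treated
#' populations) share a location, using the absolute difference of group
#' means as the statistic. The default mode resamples group labels *with
#' replacement* from the pooled values (bootstrap-style); a classical
#' without-replacement permutation mode and an exhaustive enumeration mode
#' (all `choose(n, n_a)` relabelings) are also provided. The sampled p-value
#' uses the add-one estimator `p = (1 + #{stat* >= stat}) / (1 + n_perm)`;
#' the exhaustive p is the exact tail fraction.
#'
#' @param a,b Numeric vectors (non-empty).
#' @param n_perm Number of resamples (ignored in exhaustive mode).
#' @param mode `"bootstrap"` (with replacement), `"permutation"` (without
#'   replacement) or `"exhaustive"`.
#' @param seed Optional integer seed for the resampling modes.
#'
#' @return A one-row tibble: `statistic` (observed |mean(a) - mean(b)|),
#'   `p_value`, `n_perm`, `mode`.
#' @export
#' @examples
#' permutation_test(rnorm(20), rnorm(20), n_perm = 1000, seed = 1)
permutation_test <- function(a, b, n_perm = 10000,
                             mode = c("bootstrap", "permutation", "exhaustive"),
                             seed = NULL) {
  mode <- match.arg(mode)
  a <- as.numeric(a)
  b <- as.numeric(b)
  if (length(a) == 0 || length(b) == 0) abort("both groups must be non-empty.")
  observed <- abs(mean(a) - mean(b))
  pooled <- c(a, b)
  na <- length(a)
  n <- length(pooled)
  eps <- 1e-12 * (1 + observed)
  if (mode == "exhaustive") {
    if (choose(n, na) > 2e5) {
      abort("exhaustive mode infeasible for these group sizes.")
    }
    comb <- combn(n, na)
    tot <- sum(pooled)
    means_a <- colSums(matrix(pooled[comb], nrow = na)) / na
    stats <- abs(means_a - (tot - means_a * na) / (n - na))
    p <- mean(stats >= observed - eps)
    return(tibble(
      statistic = observed, p_value = p, n_perm = ncol(comb), mode = mode
    ))
  }
  if (!is.null(seed)) set.seed(seed)
  stats <- if (mode == "bootstrap") {
    ma <- matrix(sample(pooled, n_perm * na, replace = TRUE), ncol = na)
    mb <- matrix(sample(pooled, n_perm * (n - na), replace = TRUE), ncol = n - na)
    abs(rowMeans(ma) - rowMeans(mb))
  } else {
    vapply(seq_len(n_perm), function(i) {
      idx <- sample.int(n, na)
      abs(mean(pooled[idx]) - mean(pooled[-idx]))
    }, numeric(1))
  }
  p <- (1 + sum(stats >= observed - eps)) / (1 + n_perm)
  tibble(statistic = observed, p_value = p, n_perm = n_perm, mode = mode)
}

resolve_gene_column <- function(cells, gene) {
  col <- if (gene %in% names(cells)) gene else paste0("count_", gene)
  if (!col %in% names(cells)) {
    abort(sprintf("gene `%s` not found in cell table.", gene))
  }
  col
}

check_cell_table_cols <- function(cells, need = c("condition", "area")) {
  missing <- setdiff(need, names(cells))
  if (length(missing)) {
    abort(paste0(
      "cell table lacks column(s): ", paste(missing, collapse = ", ")
    ))
  }
  if ("area" %in% need && any(cells$area <= 0)) {
    abort("cell areas must be positive.")
  }
  invisible(cells)
}

#' Trim cells by pooled area percentiles
#'
#' Removes outlier cells whose area falls outside percentile bounds computed
#' on the pooled (both-condition) area vector. Percentiles use linear
#' interpolation between order statistics (`stats::quantile` type 7);
#' boundary cells exactly at a bound are retained, so the degenerate
#' all-equal-areas case is an identity.
#'
#' @param cells Per-cell tibble with `area` (and usually `condition`).
#' @param low_pct,high_pct Percentile bounds, `0 <= low < high <= 100`.
#'
#' @return The trimmed cell tibble.
#' @export
area_trim <- function(cells, low_pct = 5, high_pct = 95) {
  check_cell_table_cols(cells, "area")
  if (!(low_pct >= 0 && high_pct <= 100 && low_pct < high_pct)) {
    abort("need 0 <= low_pct < high_pct <= 100.")
  }
  bounds <- quantile(cells$area, c(low_pct, high_pct) / 100,
    names = FALSE, type = 7
  )
  cells[cells$area >= bounds[1] & cells$area <= bounds[2], , drop = FALSE]
}

#' Linear size-expression relationship per condition
#'
#' Ordinary least squares of a gene's per-cell count on cell area, fit in
#' each condition separately. The Pearson correlation `r`, `R^2 = r^2`,
#' slope and the regression slope p-value quantify how much expression still
#' tracks cell size — the residual extrinsic-noise signal the iterative
#' filter drives down.
#'
#' @param cells Per-cell tibble with `condition`, `area` and the gene's
#'   count column.
#' @param gene Gene id (matched to column `count_<gene>`) or column name.
#'
#' @return A tibble with one row per condition: `condition`, `n`, `r`,
#'   `r_squared`, `slope`, `p_value`.
#' @export
size_expression_correlation <- function(cells, gene) {
  check_cell_table_cols(cells)
  col <- resolve_gene_column(cells, gene)
  cells |>
    dplyr::group_by(.data$condition) |>
    dplyr::group_modify(function(df, key) {
      n <- nrow(df)
      if (n < 3 || var(df$area) == 0 || var(df[[col]]) == 0) {
        return(tibble(
          n = n, r = 0, r_squared = 0, slope = 0, p_value = 1
        ))
      }
      fit <- lm(df[[col]] ~ df$area)
      sm <- summary(fit)
      r <- cor(df$area, df[[col]])
      tibble(
        n = n, r = r, r_squared = r^2,
        slope = coef(fit)[[2]],
        p_value = sm$coefficients[2, 4]
      )
    }) |>
    dplyr::ungroup()
}

#' Iterative cell-size extrinsic-noise filter
#'
#' Restricts an smFISH cell table to cells of similar size so that
#' extrinsic (cell-size / cell-cycle) variability does not masquerade as
#' transcriptional noise. The procedure: (1) trim cells outside the
#' `init_trim` (default 5th/95th) area percentiles of the pooled
#' control+treated population; (2) while the control and treated area
#' distributions remain distinguishable (permutation test p <= `alpha`) or
#' expression still correlates with area (|r| >= `r_max` in either
#' condition), repeat a pooled `iter_trim` (default 2nd/98th) percentile
#' trim. Stops with `converged = FALSE` (plus diagnostics) if `max_iter` is
#' reached or a condition drops below `min_cells`; errors if a condition is
#' exhausted. Fewer than `min_cells` cells per condition triggers a warning,
#' reflecting the >= 50 cells/condition rule for reliable noise estimates.
#'
#' @param cells Per-cell tibble (both conditions present) with `condition`,
#'   `area` and the gene's count column.
#' @param gene Gene id or count column name.
#' @param alpha Significance level of the permutation stopping rule (strict:
#'   convergence requires p > alpha).
#' @param n_perm Permutations per test.
#' @param init_trim,iter_trim Length-2 percentile bounds for the initial and
#'   the iterated trims.
#' @param r_max Maximum allowed |Pearson r| between count and area, per
#'   condition.
#' @param min_cells Minimum cells per condition.
#' @param max_iter Maximum number of iterative trims.
#' @param seed Optional seed for the permutation tests.
#' @param perm_mode Resampling mode passed to [permutation_test()].
#'
#' @return An object of class `"extrinsic_filter"`: a list with `cells`
#'   (retained rows), `retained_ids`, `n_iterations`, `p_value`,
#'   `correlations` (per-condition tibble from
#'   [size_expression_correlation()]), `n_per_condition`, `converged`, and
#'   `trace` (one row per iteration). `tidy()` returns the per-condition
#'   correlations; `glance()` the one-row convergence summary.
#' @export
iterative_extrinsic_filter <- function(cells, gene, alpha = 0.01,
                                       n_perm = 10000,
                                       init_trim = c(5, 95),
                                       iter_trim = c(2, 98),
                                       r_max = 0.45, min_cells = 50,
                                       max_iter = 25, seed = NULL,
                                       perm_mode = "bootstrap") {
  check_cell_table_cols(cells)
  col <- resolve_gene_column(cells, gene)
  conds <- unique(cells$condition)
  if (length(conds) < 2) {
    abort("both conditions must be present for extrinsic filtering.")
  }
  current <- area_trim(cells, init_trim[1], init_trim[2])
  trace <- list()
  converged <- FALSE
  iter <- 0
  repeat {
    n_cond <- table(current$condition)
    if (length(n_cond) < length(conds) || any(n_cond == 0)) {
      abort(paste0(
        "a condition was exhausted at iteration ", iter, "; trace: ",
        paste(vapply(trace, function(t) {
          sprintf("[iter %d n=%d p=%.3g]", t$iteration, t$n_total, t$p_value)
        }, character(1)), collapse = " ")
      ))
    }
    areas <- split(current$area, current$condition)
    perm <- permutation_test(areas[[1]], areas[[2]],
      n_perm = n_perm, mode = perm_mode,
      seed = if (is.null(seed)) NULL else seed + iter
    )
    cors <- size_expression_correlation(current, col)
    max_abs_r <- max(abs(cors$r))
    trace[[iter + 1]] <- tibble(
      iteration = iter, n_total = nrow(current),
      n_control = as.integer(n_cond[[1]]), n_treated = as.integer(n_cond[[2]]),
      p_value = perm$p_value, max_abs_r = max_abs_r
    )
    if (perm$p_value > alpha && max_abs_r < r_max) {
      converged <- TRUE
      break
    }
    if (any(n_cond < min_cells)) {
      warn(sprintf(
        "condition below min_cells (%d) at iteration %d; stopping unconverged.",
        min_cells, iter
      ))
      break
    }
    if (iter >= max_iter) break
    current <- area_trim(current, iter_trim[1], iter_trim[2])
    iter <- iter + 1
  }
  n_cond <- table(current$condition)
  if (any(n_cond < min_cells)) {
    warn(sprintf(
      "fewer than %d cells/condition retained (%s); noise estimates unreliable.",
      min_cells, paste(names(n_cond), n_cond, sep = "=", collapse = ", ")
    ))
  }
  last <- trace[[length(trace)]]
  structure(
    list(
      cells = current,
      retained_ids = if ("cell_id" %in% names(current)) current$cell_id else NULL,
      gene = sub("^count_", "", col),
      n_iterations = iter,
      p_value = last$p_value,
      correlations = size_expression_correlation(current, col),
      n_per_condition = setNames(as.integer(n_cond), names(n_cond)),
      converged = converged,
      trace = dplyr::bind_rows(trace)
    ),
    class = "extrinsic_filter"
  )
}

#' @export
print.extrinsic_filter <- function(x, ...) {
  cat(sprintf(
    paste0(
      "<extrinsic_filter> gene %s: %s after %d iteration(s)\n",
      "  area permutation p = %.4g | max |r| = %.3g | cells: %s\n"
    ),
    x$gene, if (x$converged) "converged" else "NOT converged",
    x$n_iterations, x$p_value, max(abs(x$correlations$r)),
    paste(names(x$n_per_condition), x$n_per_condition,
      sep = "=", collapse = ", "
    )
  ))
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.extrinsic_filter <- function(x, ...) x$correlations

#' @exportS3Method generics::glance
glance.extrinsic_filter <- function(x, ...) {
  tibble(
    gene = x$gene, converged = x$converged, n_iterations = x$n_iterations,
    p_value = x$p_value, max_abs_r = max(abs(x$correlations$r)),
    n_retained = nrow(x$cells)
  )
}

#' Cell-size-corrected noise metrics
#'
#' Regresses a gene's per-cell count on cell area (OLS, per condition) and
#' recomputes the noise metrics from the residual variance: corrected
#' variance = variance of the residuals, corrected mean = raw mean,
#' corrected CV-squared and Fano from those. Because OLS residual variance
#' never exceeds total variance, the correction can only reduce the
#' metrics; if counts are independent of size the correction is a no-op (up
#' to sampling error).
#'
#' @inheritParams size_expression_correlation
#'
#' @return A tibble per condition: `condition`, `n_cells`, `mean`, `var`,
#'   `cv2`, `fano` (corrected values).
#' @export
size_corrected_noise <- function(cells, gene) {
  check_cell_table_cols(cells)
  col <- resolve_gene_column(cells, gene)
  cells |>
    dplyr::group_by(.data$condition) |>
    dplyr::group_modify(function(df, key) {
      n <- nrow(df)
      if (n < 3) abort("need at least 3 cells per condition.")
      res <- if (var(df$area) == 0) {
        df[[col]] - mean(df[[col]])
      } else {
        residuals(lm(df[[col]] ~ df$area))
      }
      mu <- mean(df[[col]])
      v <- sum(res^2) / (n - 1)
      tibble(
        n_cells = n, mean = mu, var = v,
        cv2 = ifelse(mu > 0, v / mu^2, NA_real_),
        fano = ifelse(mu > 0, v / mu, NA_real_)
      )
    }) |>
    dplyr::ungroup()
}
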