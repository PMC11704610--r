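#' Negative binomial maximum-likelihood burst fit
#'
#' Fits a negative binomial to a vector of per-cell mRNA counts and reads
#' off the transcriptional bursting parameters: with NB size `r` and success
#' probability `p`, the burst frequency is `f = r` (bursts per mRNA
#' lifetime) and the burst size `b = (1 - p) / p = mean / r`, so the implied
#' mean is `b * f` and the implied Fano factor `1 + b`. The fit profiles the
#' likelihood over `r` with the mean profiled out at the sample mean (the
#' exact MLE for any fixed `r`), using a bracketed 1-D search on `log r` —
#' derivative-free and robust. When the sample variance does not exceed the
#' mean there is no interior optimum; a flagged Poisson-boundary fit
#' (`b = 0`, `f = mean`) is returned instead of an unstable huge-`r`
#' estimate.
#'
#' @param counts Non-negative integer vector, length >= 2 (at least ~25
#'   cells are needed for a usable fit; fewer triggers a warning), not all
#'   zero.
#'
#' @return An object of class `"nb_burst_fit"`: list with `size`, `prob`,
#'   `burst_size`, `burst_frequency`, `mean`, `fano`, `loglik`, `n_cells`,
#'   `converged`, `boundary`. `tidy()` gives the parameter tibble;
#'   `glance()` the fit summary.
#' @export
#' @examples
#' set.seed(1)
#' fit <- fit_negative_binomial(rnbinom(500, size = 4, mu = 20))
#' tidy(fit)
fit_negative_binomial <- function(counts) {
  if (length(counts) < 2) abort("need at least 2 counts.")
  if (any(!is.finite(counts)) || any(counts < 0)) {
    abort("counts must be finite and non-negative.")
  }
  if (any(abs(counts - round(counts)) > 1e-8)) {
    abort("counts must be integers (mRNA copy numbers).")
  }
  counts <- as.integer(round(counts))
  if (all(counts == 0)) abort("all counts are zero; nothing to fit.")
  n <- length(counts)
  if (n < 25) {
    warn(sprintf("only %d cells; NB fits below ~25 cells are unreliable.", n))
  }
  m <- mean(counts)
  v <- var(counts)
  if (v <= m) {
    # Poisson boundary: no overdispersion to attribute to bursting
    return(new_nb_burst_fit(
      size = Inf, prob = 1, burst_size = 0, burst_frequency = m,
      mean = m, loglik = sum(dpois(counts, m, log = TRUE)),
      n_cells = n, converged = TRUE, boundary = TRUE
    ))
  }
  r0 <- m^2 / (v - m) # method-of-moments start
  nll <- function(logr) {
    -sum(dnbinom(counts, size = exp(logr), mu = m, log = TRUE))
  }
  lower <- log(r0) - 12
  upper <- log(r0) + 12
  opt <- optimize(nll, interval = c(lower, upper), tol = 1e-10)
  r_hat <- exp(opt$minimum)
  converged <- opt$minimum > lower + 1e-6 && opt$minimum < upper - 1e-6
  new_nb_burst_fit(
    size = r_hat, prob = r_hat / (r_hat + m), burst_size = m / r_hat,
    burst_frequency = r_hat, mean = m, loglik = -opt$objective,
    n_cells = n, converged = converged, boundary = FALSE
  )
}

new_nb_burst_fit <- function(size, prob, burst_size, burst_frequency, mean,
                             loglik, n_cells, converged, boundary) {
  structure(
    list(
      size = size, prob = prob, burst_size = burst_size,
      burst_frequency = burst_frequency, mean = mean,
      fano = 1 + burst_size, loglik = loglik, n_cells = n_cells,
      converged = converged, boundary = boundary
    ),
    class = "nb_burst_fit"
  )
}

#' @export
print.nb_burst_fit <- function(x, ...) {
  cat(sprintf(
    paste0(
      "<nb_burst_fit>%s burst size b = %.4g, burst frequency f = %.4g\n",
      "  implied mean = %.4g, implied Fano = %.4g | logLik %.4g (n = %d)\n"
    ),
    if (x$boundary) " [Poisson boundary]" else "",
    x$burst_size, x$burst_frequency, x$burst_size * x$burst_frequency,
    x$fano, x$loglik, x$n_cells
  ))
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.nb_burst_fit <- function(x, ...) {
  tibble(
    term = c("burst_size", "burst_frequency", "nb_size", "nb_prob"),
    estimate = c(x$burst_size, x$burst_frequency, x$size, x$prob)
  )
}

#' @exportS3Method generics::glance
glance.nb_burst_fit <- function(x, ...) {
  tibble(
    burst_size = x$burst_size, burst_frequency = x$burst_frequency,
    mean = x$burst_size * x$burst_frequency, fano = x$fano,
    loglik = x$loglik, n_cells = x$n_cells,
    converged = x$converged, boundary = x$boundary
  )
}

#' Fit burst parameters for every gene, condition and replicate
#'
#' Maps [fit_negative_binomial()] over an smFISH-style cell table: one fit
#' per gene x condition x replicate, plus (optionally) a pooled fit per gene
#' x condition with all replicates' cells combined (`replicate = "pooled"`).
#'
#' @param cells Per-cell tibble with `condition`, `replicate` and
#'   `count_<gene>` columns.
#' @param genes Gene ids to fit (default: all count columns).
#' @param pooled Also fit pooled-replicate distributions (default TRUE).
#'
#' @return A tibble: `gene_id`, `condition`, `replicate` (character;
#'   `"pooled"` for pooled fits), `burst_size`, `burst_frequency`, `mean`,
#'   `fano`, `loglik`, `n_cells`, `converged`, `boundary`.
#' @export
fit_bursts <- function(cells, genes = NULL, pooled = TRUE) {
  check_cell_table_cols(cells, c("condition", "replicate"))
  count_cols <- grep("^count_", names(cells), value = TRUE)
  genes <- genes %||% sub("^count_", "", count_cols)
  grid <- expand.grid(
    gene_id = genes,
    condition = unique(cells$condition),
    replicate = as.character(unique(cells$replicate)),
    stringsAsFactors = FALSE
  )
  if (pooled) {
    grid <- rbind(grid, expand.grid(
      gene_id = genes, condition = unique(cells$condition),
      replicate = "pooled", stringsAsFactors = FALSE
    ))
  }
  purrr::pmap_dfr(grid, function(gene_id, condition, replicate) {
    col <- resolve_gene_column(cells, gene_id)
    sel <- cells$condition == condition &
      (replicate == "pooled" | as.character(cells$replicate) == replicate)
    fit <- fit_negative_binomial(cells[[col]][sel])
    dplyr::bind_cols(
      tibble(gene_id = gene_id, condition = condition, replicate = replicate),
      glance(fit)
    )
  })
}

#' Fold changes in burst size and burst frequency
#'
#' Pairs treated and control NB fits by gene and replicate and reports the
#' treated/control ratios `d_burst_size`, `d_burst_frequency` and their
#' log2. For homeostatic amplification by a factor `c` the ground-truth
#' values are `d_burst_size = c`, `d_burst_frequency = 1/c`, i.e.
#' `log2 d_burst_size + log2 d_burst_frequency = 0`.
#'
#' @param fits_treated,fits_control Fit tibbles from [fit_bursts()] (or one
#'   combined tibble split by its `condition` column may be passed as
#'   `fits_treated` with `fits_control = NULL`).
#'
#' @return A tibble per gene x replicate: `gene_id`, `replicate`,
#'   `d_burst_size`, `d_burst_frequency`, `log2_d_burst_size`,
#'   `log2_d_burst_frequency`.
#' @export
burst_fold_changes <- function(fits_treated, fits_control = NULL) {
  if (is.null(fits_control)) {
    stopifnot("condition" %in% names(fits_treated))
    fits_control <- dplyr::filter(fits_treated, .data$condition == "control")
    fits_treated <- dplyr::filter(fits_treated, .data$condition == "treated")
  }
  joined <- dplyr::inner_join(
    fits_treated, fits_control,
    by = c("gene_id", "replicate"), suffix = c("_t", "_c")
  )
  if (nrow(joined) == 0) abort("no gene x replicate pairs in common.")
  boundary <- joined$boundary_t | joined$boundary_c
  if (any(boundary)) {
    warn(sprintf(
      "%d gene x replicate pair(s) had Poisson-boundary fits; their burst fold changes are NA.",
      sum(boundary)
    ))
  }
  tibble(
    gene_id = joined$gene_id,
    replicate = joined$replicate,
    d_burst_size = ifelse(boundary, NA_real_,
      joined$burst_size_t / joined$burst_size_c
    ),
    d_burst_frequency = ifelse(boundary, NA_real_,
      joined$burst_frequency_t / joined$burst_frequency_c
    ),
    log2_d_burst_size = log2(.data$d_burst_size),
    log2_d_burst_frequency = log2(.data$d_burst_frequency)
  )
}

#' Replicate mean and SEM of burst fold changes
#'
#' Averages per-replicate log2 fold changes in burst size and frequency per
#' gene and reports the standard error of the mean across replicates
#' (pooled-fit rows are excluded from the averaging and carried through as
#' their own columns when present).
#'
#' @param fc Tibble from [burst_fold_changes()].
#'
#' @return A tibble per gene: `n_replicates`, `log2_d_burst_size`,
#'   `sem_log2_d_burst_size`, `log2_d_burst_frequency`,
#'   `sem_log2_d_burst_frequency`, plus `pooled_log2_d_burst_size` /
#'   `pooled_log2_d_burst_frequency` if pooled fits were present.
#' @export
summarize_burst_fold_changes <- function(fc) {
  reps <- dplyr::filter(fc, .data$replicate != "pooled")
  out <- reps |>
    dplyr::group_by(.data$gene_id) |>
    dplyr::summarise(
      n_replicates = dplyr::n(),
      sem_log2_d_burst_size = stats::sd(.data$log2_d_burst_size) /
        sqrt(dplyr::n()),
      sem_log2_d_burst_frequency = stats::sd(.data$log2_d_burst_frequency) /
        sqrt(dplyr::n()),
      log2_d_burst_size = mean(.data$log2_d_burst_size),
      log2_d_burst_frequency = mean(.data$log2_d_burst_frequency),
      .groups = "drop"
    )
  pooled <- dplyr::filter(fc, .data$replicate == "pooled")
  if (nrow(pooled) > 0) {
    out <- dplyr::left_join(
      out,
      dplyr::select(pooled,
        "gene_id",
        pooled_log2_d_burst_size = "log2_d_burst_size",
        pooled_log2_d_burst_frequency = "log2_d_burst_frequency"
      ),
      by = "gene_id"
    )
  }
  out
}

#' Reciprocity regression of burst-parameter fold changes
#'
#' Regresses `log2` fold change in burst size on `log2` fold change in burst
#' frequency across genes/replicates. Under homeostatic noise amplification
#' the points fall on the anti-diagonal: slope -1, intercept 0.
#'
#' @param fc Tibble with columns `log2_d_burst_frequency` and
#'   `log2_d_burst_size` (e.g. from [burst_fold_changes()]), or a two-column
#'   numeric data frame in that order.
#'
#' @return An object of class `"reciprocity_fit"` wrapping the `lm`:
#'   `slope`, `intercept`, `se_slope`, `se_intercept`, `n`. `tidy()` and
#'   `glance()` methods provided.
#' @export
reciprocity_regression <- function(fc) {
  if (all(c("log2_d_burst_frequency", "log2_d_burst_size") %in% names(fc))) {
    x <- fc$log2_d_burst_frequency
    y <- fc$log2_d_burst_size
  } else {
    x <- fc[[1]]
    y <- fc[[2]]
  }
  keep <- is.finite(x) & is.finite(y)
  x <- x[keep]
  y <- y[keep]
  if (length(x) < 3) abort("need at least 3 finite points.")
  if (var(x) == 0) {
    abort("degenerate design: no spread in log2 burst-frequency fold changes.")
  }
  fit <- lm(y ~ x)
  sm <- summary(fit)$coefficients
  structure(
    list(
      slope = sm[2, 1], intercept = sm[1, 1],
      se_slope = sm[2, 2], se_intercept = sm[1, 2],
      n = length(x), fit = fit
    ),
    class = "reciprocity_fit"
  )
}

#' @export
print.reciprocity_fit <- function(x, ...) {
  cat(sprintf(
    "<reciprocity_fit> slope %.3f (SE %.3f), intercept %.3f (SE %.3f), n = %d\n",
    x$slope, x$se_slope, x$intercept, x$se_intercept, x$n
  ))
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.reciprocity_fit <- function(x, ...) {
  tibble(
    term = c("intercept", "slope"),
    estimate = c(x$intercept, x$slope),
    std_error = c(x$se_intercept, x$se_slope)
  )
}

#' @exportS3Method generics::glance
glance.reciprocity_fit <- function(x, ...) {
  tibble(
    slope = x$slope, intercept = x$intercept,
    se_slope = x$se_slope, se_intercept = x$se_intercept, n = x$n
  )
}

#' Homeostasis report: classification and population tests
#'
#' Classifies each gene's response and tests the population-level signature
#' of homeostatic noise amplification. Per gene (replicate-averaged): a gene
#' is `mean_shifted` when `|log2 d_mean| > log2(mean_shift_max)`; otherwise
#' `homeostatic` when burst size and frequency moved in opposite directions,
#' else `non_reciprocal`. Across replicates, paired signed-rank tests
#' compare each fold change against 1: two-sided for the mean, one-sided
#' greater for CV-squared, Fano and burst size, one-sided less for burst
#' frequency.
#'
#' @param burst_fc Tibble from [burst_fold_changes()] (per-replicate rows).
#' @param noise_fc Fold-change tibble from [fold_change_table()] with a
#'   `replicate` column aligned with `burst_fc`.
#' @param mean_shift_max Fold-change threshold separating homeostatic from
#'   mean-shifted responses (default 1.5).
#'
#' @return A list: `genes` (per-gene tibble with classification and the
#'   averaged fold changes) and `tests` (tibble of signed-rank results per
#'   metric, computed on per-gene replicate-averaged fold changes).
#' @export
homeostasis_report <- function(burst_fc, noise_fc, mean_shift_max = 1.5) {
  reps <- dplyr::filter(burst_fc, .data$replicate != "pooled")
  merged <- dplyr::inner_join(
    reps, noise_fc,
    by = c("gene_id", "replicate")
  )
  if (nrow(merged) == 0) abort("no overlap between burst and noise fold changes.")
  per_gene <- merged |>
    dplyr::group_by(.data$gene_id) |>
    dplyr::summarise(
      dplyr::across(
        c(
          "d_mean", "d_cv2", "d_fano", "log2_d_burst_size",
          "log2_d_burst_frequency"
        ),
        ~ mean(.x, na.rm = TRUE)
      ),
      .groups = "drop"
    ) |>
    dplyr::mutate(
      class = dplyr::case_when(
        abs(log2(.data$d_mean)) > log2(mean_shift_max) ~ "mean_shifted",
        .data$log2_d_burst_size * .data$log2_d_burst_frequency < 0 ~
          "homeostatic",
        TRUE ~ "non_reciprocal"
      )
    )
  test_spec <- tibble(
    metric = c(
      "d_mean", "d_cv2", "d_fano", "log2_d_burst_size",
      "log2_d_burst_frequency"
    ),
    alternative = c("two_sided", "greater", "greater", "greater", "less"),
    null_value = c(1, 1, 1, 0, 0)
  )
  tests <- purrr::pmap_dfr(
    test_spec,
    function(metric, alternative, null_value) {
      vals <- per_gene[[metric]]
      vals <- vals[is.finite(vals)]
      res <- compare_populations(vals, rep(null_value, length(vals)),
        test = "signed_rank", alternative = alternative
      )
      dplyr::mutate(res, metric = metric, .before = 1)
    }
  )
  list(genes = per_gene, tests = tests)
}
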