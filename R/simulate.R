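#' Per-gene bursting parameters
#'
#' Builds the per-gene parameter table used by the simulators. Under the
#' two-state (telegraph) model in its negative binomial limit, a gene is
#' characterised by a burst size `b` (mean mRNAs made per transcriptional
#' burst) and a burst frequency `f` (bursts per mRNA lifetime; lifetimes are
#' normalised to 1). The stationary mRNA count is then Gamma-Poisson
#' (negative binomial) with mean `b * f` and Fano factor `1 + b`.
#'
#' @param gene_id Character vector of unique gene identifiers.
#' @param burst_size Non-negative numeric vector `b`. `b = 0` selects the
#'   Poisson limit, where counts are drawn as `Poisson(f)`.
#' @param burst_frequency Positive numeric vector `f`.
#'
#' @return A tibble with columns `gene_id`, `burst_size`, `burst_frequency`,
#'   `intrinsic_mean` and `intrinsic_fano`.
#' @export
#' @examples
#' gene_params(c("g1", "g2"), burst_size = c(5, 0), burst_frequency = c(4, 7))
gene_params <- function(gene_id, burst_size, burst_frequency) {
  if (anyDuplicated(gene_id)) {
    abort("`gene_id` contains duplicates.")
  }
  check_param(burst_size, "burst_size", min = 0)
  check_param(burst_frequency, "burst_frequency", min = 0, strict = TRUE)
  tibble(
    gene_id = as.character(gene_id),
    burst_size = as.numeric(burst_size),
    burst_frequency = as.numeric(burst_frequency),
    intrinsic_mean = ifelse(burst_size == 0, burst_frequency,
      burst_size * burst_frequency
    ),
    intrinsic_fano = 1 + burst_size
  )
}

check_param <- function(x, name, min = NULL, max = NULL, strict = FALSE) {
  if (!is.numeric(x) || any(!is.finite(x))) {
    abort(sprintf("`%s` must be finite numeric.", name))
  }
  if (!is.null(min) && (any(x < min) || (strict && any(x == min)))) {
    abort(sprintf(
      "`%s` must be %s %s.", name, if (strict) ">" else ">=", format(min)
    ))
  }
  if (!is.null(max) && any(x > max)) {
    abort(sprintf("`%s` must be <= %s.", name, format(max)))
  }
  invisible(x)
}

#' Simulation configuration
#'
#' Bundles and validates every knob of the synthetic-data generators. The
#' defaults describe the study conditions the package is tested under:
#' paired treated/control populations of 200 cells per condition in each of
#' 3 biological replicates, lognormal cell areas with ~25% coefficient of
#' variation, extrinsic size coupling `eta = 1`, a mean capture probability
#' of 0.1 for the sequencing layer, and a homeostatic noise amplification
#' `c = 2` (treated burst size `c * b`, burst frequency `f / c`, so the mean
#' `b * f` is unchanged while the Fano factor rises from `1 + b` to
#' `1 + c * b`).
#'
#' @param genes A tibble from [gene_params()].
#' @param n_cells Cells per condition per replicate.
#' @param n_replicates Number of biological replicates.
#' @param extrinsic_coupling Power coupling `eta >= 0` of the Poisson rate to
#'   relative cell size: rate is multiplied by `(A / Abar)^eta`, `Abar` the
#'   mean area of the replicate's pooled (both-condition) population.
#' @param area_log_mean,area_log_sd Meanlog and sdlog of the lognormal cell
#'   area distribution (arbitrary area units; only relative areas matter).
#' @param capture_mean Mean per-cell capture probability in (0, 1].
#' @param capture_sd Spread of capture probabilities on the logit scale;
#'   `0` gives every cell exactly `capture_mean` (the analytic uniform-beta
#'   mode).
#' @param amplification Homeostatic amplification factor `c >= 1`.
#' @param area_shift_treated Multiplicative area offset (>= 0) applied to
#'   treated cells, used to exercise the extrinsic-noise filter; `1` leaves
#'   areas exchangeable between conditions.
#' @param seed Integer seed; identical `(config, seed)` pairs produce
#'   bit-identical output.
#'
#' @return A list of class `"sim_config"`.
#' @export
#' @examples
#' cfg <- sim_config(gene_params("g1", 5, 4), n_cells = 50, seed = 1)
sim_config <- function(genes,
                       n_cells = 200,
                       n_replicates = 3,
                       extrinsic_coupling = 1,
                       area_log_mean = log(200),
                       area_log_sd = 0.25,
                       capture_mean = 0.1,
                       capture_sd = 0,
                       amplification = 2,
                       area_shift_treated = 1,
                       seed = 1L) {
  if (!is.data.frame(genes) || !all(c("gene_id", "burst_size", "burst_frequency")
  %in% names(genes))) {
    abort("`genes` must be a gene_params() tibble.")
  }
  check_param(genes$burst_size, "burst_size", min = 0)
  check_param(genes$burst_frequency, "burst_frequency", min = 0, strict = TRUE)
  check_param(n_cells, "n_cells", min = 1)
  check_param(n_replicates, "n_replicates", min = 1)
  check_param(extrinsic_coupling, "extrinsic_coupling", min = 0)
  check_param(area_log_mean, "area_log_mean")
  check_param(area_log_sd, "area_log_sd", min = 0)
  check_param(capture_mean, "capture_mean", min = 0, max = 1, strict = TRUE)
  check_param(capture_sd, "capture_sd", min = 0)
  check_param(amplification, "amplification", min = 1)
  check_param(area_shift_treated, "area_shift_treated", min = 0)
  check_param(seed, "seed")
  structure(
    list(
      genes = as_tibble(genes[, c("gene_id", "burst_size", "burst_frequency")]),
      n_cells = as.integer(n_cells),
      n_replicates = as.integer(n_replicates),
      extrinsic_coupling = extrinsic_coupling,
      area_log_mean = area_log_mean,
      area_log_sd = area_log_sd,
      capture_mean = capture_mean,
      capture_sd = capture_sd,
      amplification = amplification,
      area_shift_treated = area_shift_treated,
      seed = as.integer(seed)
    ),
    class = "sim_config"
  )
}

#' @export
print.sim_config <- function(x, ...) {
  cat(sprintf(
    paste0(
      "<sim_config> %d genes | %d cells/condition x %d replicates\n",
      "  eta = %g, amplification c = %g, capture = %g (sd %g, logit)\n",
      "  area ~ lognormal(%.3g, %.3g), treated area x%g, seed %d\n"
    ),
    nrow(x$genes), x$n_cells, x$n_replicates, x$extrinsic_coupling,
    x$amplification, x$capture_mean, x$capture_sd, x$area_log_mean,
    x$area_log_sd, x$area_shift_treated, x$seed
  ))
  invisible(x)
}

# parameters actually used in a condition
condition_params <- function(config, condition) {
  g <- config$genes
  if (condition == "treated") {
    g$burst_size <- g$burst_size * config$amplification
    g$burst_frequency <- g$burst_frequency / config$amplification
  }
  g$intrinsic_mean <- ifelse(g$burst_size == 0, g$burst_frequency,
    g$burst_size * g$burst_frequency
  )
  g$intrinsic_fano <- 1 + g$burst_size
  g$condition <- condition
  g
}

# Gamma-Poisson counts for one gene across cells, with multiplicative
# extrinsic size factor on the Poisson rate. b = 0 is the Poisson limit.
draw_counts <- function(n, b, f, size_factor) {
  if (b == 0) {
    rpois(n, f * size_factor)
  } else {
    lambda <- rgamma(n, shape = f, scale = b)
    rpois(n, lambda * size_factor)
  }
}

sim_cells_one_replicate <- function(config, replicate) {
  n <- config$n_cells
  area <- list(
    control = rlnorm(n, config$area_log_mean, config$area_log_sd),
    treated = rlnorm(n, config$area_log_mean, config$area_log_sd) *
      config$area_shift_treated
  )
  area_bar <- mean(c(area$control, area$treated))
  out <- lapply(c("control", "treated"), function(cond) {
    sf <- (area[[cond]] / area_bar)^config$extrinsic_coupling
    pars <- condition_params(config, cond)
    counts <- vapply(
      seq_len(nrow(pars)),
      function(i) draw_counts(n, pars$burst_size[i], pars$burst_frequency[i], sf),
      integer(n)
    )
    colnames(counts) <- paste0("count_", pars$gene_id)
    dplyr::bind_cols(
      tibble(
        cell_id = sprintf("%s_r%d_c%04d", cond, replicate, seq_len(n)),
        condition = cond,
        replicate = as.integer(replicate),
        area = area[[cond]]
      ),
      as_tibble(counts)
    )
  })
  dplyr::bind_rows(out)
}

#' Simulate smFISH-style per-cell mRNA spot counts
#'
#' Draws per-cell mRNA counts from the Gamma-Poisson (negative binomial)
#' bursting model: for each cell, a gene's rate is `Gamma(shape = f,
#' scale = b)` and the observed count is `Poisson(rate * (A / Abar)^eta)`,
#' where `A` is the cell's area. With `eta = 0` the marginal count of a gene
#' is exactly negative binomial with mean `b * f` and Fano factor `1 + b`;
#' the treated condition uses `(c * b, f / c)` so its mean is unchanged and
#' its Fano factor is `1 + c * b` (homeostatic noise amplification).
#'
#' @param config A [sim_config()].
#'
#' @return A list with class `"smfish_sim"`:
#' * `treated`, `control`: per-cell tibbles (`cell_id`, `condition`,
#'   `replicate`, `area`, one `count_<gene_id>` column per gene);
#' * `truth`: ground-truth list (`params`: per gene x condition burst
#'   parameters and intrinsic moments; `cells`: per-cell area). Ground truth
#'   is for tests and benchmarking only; no analysis stage consumes it.
#' @seealso [simulate_umi_matrix()] for the sequencing-layer counterpart.
#' @export
#' @examples
#' sim <- simulate_smfish(sim_config(gene_params("g1", 5, 4),
#'   n_cells = 100, n_replicates = 1, extrinsic_coupling = 0, seed = 7
#' ))
#' head(sim$control)
simulate_smfish <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  cells <- dplyr::bind_rows(
    lapply(seq_len(config$n_replicates), function(r) {
      sim_cells_one_replicate(config, r)
    })
  )
  truth <- list(
    params = dplyr::bind_rows(
      condition_params(config, "control"),
      condition_params(config, "treated")
    ),
    cells = cells[, c("cell_id", "condition", "replicate", "area")]
  )
  structure(
    list(
      treated = cells[cells$condition == "treated", , drop = FALSE],
      control = cells[cells$condition == "control", , drop = FALSE],
      truth = truth
    ),
    class = "smfish_sim"
  )
}

#' Simulate a scRNA-seq-style UMI count matrix
#'
#' Layers the sequencing measurement process on top of [simulate_smfish()]:
#' each cell receives a capture probability `beta` (logit-normal around
#' `capture_mean`; constant when `capture_sd = 0`) and every true mRNA is
#' observed independently with probability `beta` (binomial thinning).
#' Thinning a negative binomial with uniform `beta` leaves the burst
#' frequency `f` unchanged and scales the burst size to `beta * b`, so the
#' observed Fano factor is `1 + beta * b` — the mechanism by which
#' sequencing compresses fold changes in noise relative to direct smFISH
#' counting.
#'
#' @inheritParams simulate_smfish
#'
#' @return A list with class `"umi_sim"`: `treated` and `control`
#'   [count_matrix()] objects and `truth` (as in [simulate_smfish()], plus
#'   per-cell `capture`).
#' @export
#' @examples
#' sim <- simulate_umi_matrix(sim_config(gene_params("g1", 5, 4),
#'   n_cells = 50, n_replicates = 1, extrinsic_coupling = 0, seed = 7
#' ))
#' sim$control
simulate_umi_matrix <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  fish <- simulate_smfish(config)
  cells <- dplyr::bind_rows(fish$control, fish$treated)
  n <- nrow(cells)
  beta <- if (config$capture_sd == 0) {
    rep(config$capture_mean, n)
  } else {
    pmin(pmax(
      plogis(rnorm(n, qlogis(config$capture_mean), config$capture_sd)),
      1e-6
    ), 1)
  }
  count_cols <- grep("^count_", names(cells), value = TRUE)
  gene_ids <- sub("^count_", "", count_cols)
  true_counts <- t(as.matrix(cells[, count_cols]))
  obs <- matrix(
    rbinom(length(true_counts), as.vector(true_counts),
      prob = rep(beta, each = length(gene_ids))
    ),
    nrow = length(gene_ids),
    dimnames = list(gene_ids, cells$cell_id)
  )
  truth <- fish$truth
  truth$cells$capture <- beta
  make_cm <- function(cond) {
    keep <- cells$condition == cond
    count_matrix(
      obs[, keep, drop = FALSE],
      cell_meta = cells[keep, c("cell_id", "condition", "replicate", "area")]
    )
  }
  structure(
    list(
      treated = make_cm("treated"),
      control = make_cm("control"),
      truth = truth
    ),
    class = "umi_sim"
  )
}

#' Manufacture a synthetic method fold-change table
#'
#' Produces the output a (synthetic) normalization method would report, by
#' shrinking a reference fold-change table toward 1 on the log scale and
#' adding multiplicative jitter: `log(D') = (1 - s) * log(D) + noise`. Used
#' to test the method-scoring machinery: `s = 0, jitter_sd = 0` reproduces
#' the reference exactly; `s = 1` collapses every fold change to 1; larger
#' `s` yields larger deviation scores against the reference.
#'
#' @param reference Fold-change tibble with `gene_id` and `d_*` columns
#'   (positive values), as produced by [fold_change_table()].
#' @param shrink Shrinkage factor `s` in \[0, 1\].
#' @param jitter_sd Standard deviation of lognormal multiplicative noise.
#' @param seed Optional integer seed.
#' @param method Method name recorded in the `method` column.
#'
#' @return A tibble like `reference` with shrunk/jittered `d_*` columns.
#' @export
#' @examples
#' ref <- tibble::tibble(gene_id = "g1", d_mean = 1, d_cv2 = 2, d_fano = 2)
#' simulate_method_tables(ref, shrink = 0.5, method = "shrunk")
simulate_method_tables <- function(reference, shrink, jitter_sd = 0,
                                   seed = NULL, method = "synthetic") {
  check_param(shrink, "shrink", min = 0, max = 1)
  check_param(jitter_sd, "jitter_sd", min = 0)
  d_cols <- grep("^d_", names(reference), value = TRUE)
  if (length(d_cols) == 0) {
    abort("`reference` has no `d_*` fold-change columns.")
  }
  vals <- as.matrix(reference[, d_cols])
  if (any(!is.finite(vals)) || any(vals <= 0)) {
    abort("`reference` fold changes must be positive and finite.")
  }
  if (!is.null(seed)) set.seed(seed)
  out <- reference
  for (col in d_cols) {
    lg <- log(reference[[col]]) * (1 - shrink)
    if (jitter_sd > 0) lg <- lg + rnorm(length(lg), 0, jitter_sd)
    out[[col]] <- exp(lg)
  }
  out$method <- method
  as_tibble(out)
}
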