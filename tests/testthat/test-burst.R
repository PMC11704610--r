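test_that("Poisson data lands on the boundary with Fano near 1", {
  set.seed(40)
  fit <- fit_negative_binomial(rpois(1e4, 10))
  expect_lt(fit$burst_size, 0.05)
  expect_lt(fit$fano, 1.05)
})

test_that("degenerate constant counts take the flagged boundary path", {
  fit <- suppressWarnings(fit_negative_binomial(rep(5L, 10)))
  expect_true(fit$boundary)
  expect_equal(fit$burst_size, 0)
  expect_equal(fit$burst_frequency, 5)
})

test_that("input validation: all-zero and non-integer counts are rejected", {
  expect_error(fit_negative_binomial(rep(0L, 30)), "zero")
  expect_error(fit_negative_binomial(c(1.5, 2, 3)), "integer")
  expect_warning(fit_negative_binomial(c(0L, 3L, 5L, 9L)), "25")
})

test_that("NB parameter recovery: median relative error < 10% at n = 1000", {
  errs <- t(vapply(1:20, function(seed) {
    set.seed(seed)
    counts <- rnbinom(1000, size = 5, mu = 50) # b = 10, f = 5
    fit <- fit_negative_binomial(counts)
    c(
      abs(fit$burst_size / 10 - 1),
      abs(fit$burst_frequency / 5 - 1)
    )
  }, numeric(2)))
  expect_lt(median(errs[, 1]), 0.1)
  expect_lt(median(errs[, 2]), 0.1)
})

test_that("MLE agrees with an independent NB fit and its own likelihood surface", {
  set.seed(41)
  counts <- rnbinom(2000, size = 3, mu = 12)
  fit <- fit_negative_binomial(counts)
  ref <- suppressWarnings(MASS::fitdistr(counts, "negative binomial"))
  expect_equal(fit$burst_frequency, unname(ref$estimate["size"]), tolerance = 1e-3)
  expect_equal(fit$burst_size * fit$burst_frequency, unname(ref$estimate["mu"]),
    tolerance = 1e-4
  )
  # reported log-likelihood equals the direct summation of the NB log-pmf
  direct <- sum(dnbinom(counts, size = fit$size, mu = fit$mean, log = TRUE))
  expect_equal(fit$loglik, direct, tolerance = 1e-8)
  expect_gte(fit$loglik, as.numeric(ref$loglik) - 1e-6)
})

test_that("implied identities Fano = 1 + b and mean = b * f hold exactly", {
  set.seed(42)
  for (i in 1:5) {
    counts <- rnbinom(300, size = runif(1, 0.5, 8), mu = runif(1, 2, 40))
    fit <- fit_negative_binomial(counts)
    expect_identical(fit$fano, 1 + fit$burst_size)
    expect_equal(fit$burst_size * fit$burst_frequency, mean(counts))
  }
})

test_that("MLE error shrinks with sample size", {
  med_err <- vapply(c(100, 1000, 10000), function(n) {
    errs <- vapply(1:10, function(seed) {
      set.seed(seed * 100 + n)
      fit <- fit_negative_binomial(rnbinom(n, size = 5, mu = 50))
      abs(fit$burst_size / 10 - 1)
    }, numeric(1))
    median(errs)
  }, numeric(1))
  expect_true(all(diff(med_err) < 0))
})

test_that("thinning leaves burst frequency invariant and scales burst size", {
  cfg <- quick_config(b = 5, f = 4, n = 5e4, seed = 43, capture_mean = 0.1, c = 1)
  umi <- simulate_umi_matrix(cfg)
  thinned <- fit_negative_binomial(as.integer(umi$control$counts["g1", ]))
  fish <- simulate_smfish(cfg)
  full <- fit_negative_binomial(fish$control$count_g1)
  expect_lt(abs(thinned$burst_frequency / full$burst_frequency - 1), 0.1)
  expect_lt(abs(thinned$burst_size / (0.1 * full$burst_size) - 1), 0.15)
})

test_that("fit_bursts maps over gene x condition x replicate plus pooled", {
  sim <- simulate_smfish(quick_config(
    b = 5, f = 4, n = 200, c = 2, seed = 44, n_replicates = 2
  ))
  cells <- dplyr::bind_rows(sim$control, sim$treated)
  fits <- fit_bursts(cells)
  expect_equal(nrow(fits), 2 * 3) # 1 gene x 2 conditions x (2 reps + pooled)
  expect_setequal(unique(fits$replicate), c("1", "2", "pooled"))

  fc <- burst_fold_changes(fits)
  expect_equal(nrow(fc), 3)
  # identical fits give unit fold changes
  same <- burst_fold_changes(fits[fits$condition == "control", ] |>
    dplyr::mutate(condition = "treated"), fits[fits$condition == "control", ])
  expect_true(all(same$d_burst_size == 1 & same$d_burst_frequency == 1))
  expect_true(all(same$log2_d_burst_size == 0))
})

test_that("c = 2 pairs recover the reciprocal log2 fold changes within 0.2", {
  sim <- simulate_smfish(quick_config(
    b = 5, f = 4, n = 1000, c = 2, seed = 45, n_replicates = 3
  ))
  cells <- dplyr::bind_rows(sim$control, sim$treated)
  fc <- burst_fold_changes(fit_bursts(cells, pooled = FALSE))
  summary <- summarize_burst_fold_changes(fc)
  expect_lt(abs(summary$log2_d_burst_size - 1), 0.2)
  expect_lt(abs(summary$log2_d_burst_frequency + 1), 0.2)
  # parameter-level ground truth is exactly reciprocal
  truth <- simulate_smfish(quick_config(b = 5, f = 4, c = 2, seed = 1))$truth$params
  expect_equal(
    truth$burst_size[truth$condition == "treated"] /
      truth$burst_size[truth$condition == "control"], 2
  )
  expect_equal(
    truth$burst_frequency[truth$condition == "treated"] /
      truth$burst_frequency[truth$condition == "control"], 0.5
  )
})

test_that("reciprocity regression: collinear points give slope -1 with zero SE", {
  pts <- tibble::tibble(
    log2_d_burst_frequency = c(-1, -2, 1),
    log2_d_burst_size = c(1, 2, -1)
  )
  fit <- suppressWarnings(reciprocity_regression(pts)) # lm perfect-fit notice
  expect_equal(fit$slope, -1)
  expect_equal(fit$intercept, 0)
  expect_equal(fit$se_slope, 0)
  expect_equal(tidy(fit)$estimate, c(0, -1))
  degenerate <- tibble::tibble(
    log2_d_burst_frequency = rep(1, 4), log2_d_burst_size = rep(-1, 4)
  )
  expect_error(reciprocity_regression(degenerate), "degenerate")
  expect_error(reciprocity_regression(pts[1:2, ]), "at least 3")
})

test_that("homeostasis_report classifies constructed response patterns", {
  burst_fc <- tibble::tibble(
    gene_id = rep(c("homeo", "shifted", "outlier"), each = 2),
    replicate = rep(c("1", "2"), 3),
    d_burst_size = rep(c(2, sqrt(2), 1.2), each = 2),
    d_burst_frequency = rep(c(0.5, sqrt(2), 1.2), each = 2),
    log2_d_burst_size = log2(d_burst_size),
    log2_d_burst_frequency = log2(d_burst_frequency)
  )
  noise_fc <- tibble::tibble(
    gene_id = rep(c("homeo", "shifted", "outlier"), each = 2),
    replicate = rep(c("1", "2"), 3),
    d_mean = rep(c(1, 2, 1.44), each = 2),
    d_cv2 = rep(c(1.8, 1.1, 1.4), each = 2),
    d_fano = rep(c(1.8, 1.1, 1.4), each = 2)
  )
  rep_out <- homeostasis_report(burst_fc, noise_fc)
  classes <- setNames(rep_out$genes$class, rep_out$genes$gene_id)
  expect_equal(classes[["homeo"]], "homeostatic")
  expect_equal(classes[["shifted"]], "mean_shifted")
  expect_equal(classes[["outlier"]], "non_reciprocal")
  expect_setequal(
    rep_out$tests$metric,
    c("d_mean", "d_cv2", "d_fano", "log2_d_burst_size", "log2_d_burst_frequency")
  )
})
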