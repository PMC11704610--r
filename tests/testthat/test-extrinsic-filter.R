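test_that("permutation test: identical groups give p = 1, same seed same p", {
  a <- c(1, 2, 3, 4)
  expect_equal(permutation_test(a, a, n_perm = 200, seed = 1)$p_value, 1)
  set.seed(1)
  x <- rnorm(10)
  y <- rnorm(10) + 0.5
  expect_identical(
    permutation_test(x, y, n_perm = 500, seed = 7)$p_value,
    permutation_test(x, y, n_perm = 500, seed = 7)$p_value
  )
  expect_error(permutation_test(numeric(0), 1:3), "non-empty")
})

test_that("sampled permutation p matches exhaustive enumeration within MC error", {
  set.seed(30)
  for (i in 1:5) {
    a <- rnorm(6)
    b <- rnorm(6) + runif(1, 0, 1.5)
    exact <- permutation_test(a, b, mode = "exhaustive")$p_value
    sampled <- permutation_test(a, b,
      n_perm = 4000, mode = "permutation", seed = i
    )$p_value
    mc_sd <- sqrt(exact * (1 - exact) / 4000)
    expect_lt(abs(sampled - exact), 3 * mc_sd + 2 / 4000)
  }
})

test_that("area_trim uses pooled interpolated percentiles, bounds inclusive", {
  cells <- tibble::tibble(
    cell_id = as.character(1:100), condition = "control", area = 1:100
  )
  expect_equal(nrow(area_trim(cells, 5, 95)), 90)
  expect_equal(nrow(area_trim(cells, 0, 100)), 100)
  equal_areas <- tibble::tibble(cell_id = as.character(1:10), area = rep(2, 10))
  expect_equal(nrow(area_trim(equal_areas, 2, 98)), 10)
  expect_error(area_trim(cells, 95, 5), "low_pct")
})

test_that("size_expression_correlation recovers exact linear relations", {
  cells <- tibble::tibble(
    condition = "control", area = c(1, 2, 3), count_g = c(2, 4, 6)
  )
  res <- suppressWarnings(size_expression_correlation(cells, "g")) # perfect fit
  expect_equal(res$slope, 2)
  expect_equal(res$r, 1)
  expect_equal(res$r_squared, 1)

  null_sim <- simulate_smfish(quick_config(b = 5, f = 4, n = 1000, eta = 0, seed = 14))
  res0 <- size_expression_correlation(
    dplyr::bind_rows(null_sim$control, null_sim$treated), "g1"
  )
  expect_true(all(abs(res0$r) < 0.1))
})

test_that("already-matched populations converge at iteration zero", {
  sim <- simulate_smfish(quick_config(b = 5, f = 4, n = 200, eta = 0, seed = 15))
  cells <- dplyr::bind_rows(sim$control, sim$treated)
  res <- iterative_extrinsic_filter(cells, "g1", n_perm = 2000, seed = 1)
  expect_true(res$converged)
  expect_equal(res$n_iterations, 0)
  expect_equal(nrow(res$cells), nrow(area_trim(cells, 5, 95)))
})

test_that("the shifted-area construction converges to matched, decorrelated populations", {
  cfg <- quick_config(
    b = 5, f = 4, n = 300, eta = 1, seed = 16,
    area_shift_treated = 1.3
  )
  cells <- with(simulate_smfish(cfg), dplyr::bind_rows(control, treated))
  res <- iterative_extrinsic_filter(cells, "g1", n_perm = 2000, seed = 2)
  expect_true(res$converged)
  expect_gt(res$p_value, 0.01)
  expect_true(all(abs(res$correlations$r) < 0.45))
  expect_gt(res$n_iterations, 0)
  # monotone shrinkage, iteration count bounded
  expect_true(all(diff(res$trace$n_total) <= 0))
  expect_lte(res$n_iterations, 25)
  # glance/tidy expose the summary
  expect_identical(glance(res)$converged, TRUE)
  expect_identical(nrow(tidy(res)), 2L)
})

test_that("max_iter = 0 forces a diagnosed non-convergence", {
  cfg <- quick_config(
    b = 5, f = 4, n = 300, eta = 1, seed = 17,
    area_shift_treated = 1.3
  )
  cells <- with(simulate_smfish(cfg), dplyr::bind_rows(control, treated))
  res <- suppressWarnings(iterative_extrinsic_filter(
    cells, "g1",
    n_perm = 500, max_iter = 0, seed = 3
  ))
  expect_false(res$converged)
  expect_gte(nrow(res$trace), 1)
})

test_that("an exhausted condition raises an error carrying the trace", {
  cells <- tibble::tibble(
    cell_id = as.character(1:104),
    condition = rep(c("control", "treated"), c(4, 100)),
    area = c(rnorm(4, 1, 0.01), rnorm(100, 100, 1)),
    count_g = rpois(104, 5)
  )
  expect_error(
    suppressWarnings(iterative_extrinsic_filter(
      cells, "g",
      n_perm = 200, min_cells = 0, max_iter = 200, seed = 4
    )),
    "exhausted"
  )
})

test_that("size correction removes the linear area component, never adds variance", {
  # perfect linearity: corrected variance 0
  exact <- tibble::tibble(
    condition = "control", area = as.numeric(1:50), count_g = 2 * (1:50)
  )
  expect_equal(size_corrected_noise(exact, "g")$var, 0)

  # independence: correction is a near no-op
  null_sim <- simulate_smfish(quick_config(b = 5, f = 4, n = 1000, eta = 0, seed = 18))
  cells0 <- dplyr::bind_rows(null_sim$control, null_sim$treated)
  raw <- noise_summary(cells0, by = "condition")
  corr <- size_corrected_noise(cells0, "g1")
  expect_equal(corr$cv2, raw$cv2, tolerance = 0.02)

  # coupling: correction strictly reduces cv2; never increases variance
  coupled <- simulate_smfish(quick_config(b = 5, f = 4, n = 1000, eta = 1, seed = 18))
  cells1 <- dplyr::bind_rows(coupled$control, coupled$treated)
  raw1 <- noise_summary(cells1, by = "condition")
  corr1 <- size_corrected_noise(cells1, "g1")
  expect_true(all(corr1$cv2 < raw1$cv2))
  expect_true(all(corr1$var <= raw1$var))
})
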