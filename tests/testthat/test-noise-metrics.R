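test_that("noise_summary matches the hand-computed oracle", {
  s <- noise_summary(c(2, 4, 6, 8))
  expect_equal(s$mean, 5)
  expect_equal(s$var, 20 / 3)
  expect_equal(s$fano, 4 / 3)
  expect_equal(s$cv2, 4 / 15)
  constant <- noise_summary(c(5, 5, 5))
  expect_equal(constant$var, 0)
  expect_equal(constant$cv2, 0)
  expect_equal(constant$fano, 0)
  expect_error(noise_summary(3), "at least 2")
})

test_that("a large Poisson sample has Fano factor 1", {
  set.seed(2)
  s <- noise_summary(rpois(1e5, 10))
  expect_gt(s$fano, 0.97)
  expect_lt(s$fano, 1.03)
})

test_that("fano = cv2 * mean to machine precision, zero-mean genes flagged", {
  set.seed(3)
  counts <- matrix(rpois(600, 3), nrow = 6)
  counts[2, ] <- 0
  dimnames(counts) <- list(paste0("g", 1:6), paste0("c", 1:100))
  s <- noise_summary(count_matrix(counts))
  ok <- !s$undefined
  expect_equal(s$fano[ok], s$cv2[ok] * s$mean[ok])
  expect_identical(s$undefined, s$gene_id == "g2")
  expect_true(all(is.na(s$fano[!ok])))
})

test_that("qc_filter_cells applies threshold semantics and reports removals", {
  counts <- matrix(0, nrow = 6, ncol = 3,
    dimnames = list(c(paste0("g", 1:5), "mt-nd1"), paste0("c", 1:3))
  )
  counts[1:5, 1] <- c(3, 2, 1, 4, 5) # 5 detected genes
  counts[1:2, 2] <- c(8, 1) # 2 detected genes
  counts[1:4, 3] <- c(2, 2, 2, 3) # 4 detected genes
  m <- count_matrix(counts)
  kept <- qc_filter_cells(m, min_genes = 4, min_umi = 0, max_mito_frac = NULL)
  expect_identical(kept$cell_ids, c("c1", "c3"))
  report <- attr(kept, "qc_report")
  expect_equal(report$n_removed[report$criterion == "min_genes"], 1L)

  # mito fraction exactly at the bound is removed (strict <)
  counts2 <- matrix(c(9, 1, 9, 0), nrow = 2,
    dimnames = list(c("g1", "mt-nd1"), c("c1", "c2"))
  )
  m2 <- count_matrix(counts2)
  kept2 <- qc_filter_cells(m2, min_genes = 0, min_umi = 0, max_mito_frac = 0.1)
  expect_identical(kept2$cell_ids, "c2")

  # disabled thresholds are the identity
  expect_identical(
    qc_filter_cells(m, min_genes = NULL, min_umi = NULL, max_mito_frac = NULL)$cell_ids,
    m$cell_ids
  )
  expect_error(
    qc_filter_cells(m, min_genes = 100, min_umi = 0, max_mito_frac = NULL),
    "every cell"
  )
})

test_that("gene_coverage_filter enforces both thresholds per condition", {
  counts <- matrix(0, nrow = 2, ncol = 100,
    dimnames = list(c("g1", "g2"), paste0("c", 1:100))
  )
  counts[1, 1] <- 50 # detected in 1% of cells but mean 0.5
  counts[2, ] <- rep(1, 100)
  m <- count_matrix(counts)
  kept <- gene_coverage_filter(m, min_mean_count = 0.1, min_detect_frac = 0.1)
  expect_identical(kept$gene_ids, "g2")
  expect_identical(
    gene_coverage_filter(m, min_mean_count = 0, min_detect_frac = 0)$gene_ids,
    m$gene_ids
  )
  # intersection rule: a gene passing in only one condition is dropped
  cond <- rep(c("control", "treated"), each = 50)
  counts3 <- rbind(
    g1 = c(rep(2, 50), rep(0, 50)),
    g2 = rep(2, 100)
  )
  colnames(counts3) <- paste0("c", 1:100)
  m3 <- count_matrix(counts3, tibble::tibble(
    cell_id = colnames(counts3), condition = cond
  ))
  expect_identical(
    gene_coverage_filter(m3, min_mean_count = 0.1, min_detect_frac = 0.05)$gene_ids,
    "g2"
  )
})

test_that("raw_normalize rescales each cell to the target total", {
  m <- toy_count_matrix(matrix(c(1, 3), nrow = 2,
    dimnames = list(c("g1", "g2"), "c1")
  ))
  norm <- raw_normalize(m)
  expect_equal(as.numeric(norm$counts[, 1]), c(2500, 7500))

  set.seed(4)
  counts <- matrix(rpois(500, 5) + 1, nrow = 5,
    dimnames = list(paste0("g", 1:5), paste0("c", 1:100))
  )
  norm2 <- raw_normalize(count_matrix(counts), scale = 1e4)
  expect_lt(max(abs(Matrix::colSums(norm2$counts) / 1e4 - 1)), 1e-9)
  # within-cell proportions conserved
  ratio_raw <- counts[1, ] / counts[2, ]
  ratio_norm <- as.numeric(norm2$counts[1, ] / norm2$counts[2, ])
  expect_equal(ratio_norm, unname(ratio_raw))

  zero <- matrix(c(1, 0), nrow = 1, dimnames = list("g1", c("c1", "c2")))
  expect_error(raw_normalize(count_matrix(zero)), "c2")
})

test_that("single-gene matrices normalize to the scale everywhere", {
  m <- count_matrix(matrix(c(3, 7, 1), nrow = 1,
    dimnames = list("g1", paste0("c", 1:3))
  ))
  expect_true(all(as.numeric(raw_normalize(m)$counts) == 1e4))
})

test_that("fold_change_table divides treated by control and records exclusions", {
  treated <- noise_summary(count_matrix(matrix(c(2, 4, 6, 8, 5, 5, 5, 5),
    nrow = 2, byrow = TRUE, dimnames = list(c("g1", "g2"), paste0("c", 1:4))
  )))
  identical_fc <- fold_change_table(treated, treated)
  expect_true(all(identical_fc$d_mean == 1 & identical_fc$d_cv2 == 1 &
    identical_fc$d_fano == 1))
  # constant-count gene g2 has zero control metrics -> excluded with reason
  expect_identical(identical_fc$gene_id, "g1")
  expect_match(attr(identical_fc, "excluded")$reason[1], "zero")

  a <- tibble::tibble(
    gene_id = "g", n_cells = 10, mean = 2, var = 22, cv2 = 5.5, fano = 11,
    undefined = FALSE
  )
  b <- dplyr::mutate(a, var = 12, cv2 = 3, fano = 6)
  expect_equal(fold_change_table(a, b)$d_fano, 11 / 6)
})

test_that("replicate_average requires genes in all replicates", {
  x <- tibble::tibble(
    gene_id = c("g1", "g1", "g2"),
    replicate = c(1, 2, 1),
    fano = c(2, 4, 10)
  )
  avg <- replicate_average(x)
  expect_equal(avg$gene_id, "g1")
  expect_equal(avg$fano, 3)
  single <- tibble::tibble(gene_id = "g1", fano = 2)
  expect_identical(replicate_average(single), single)
})

test_that("negative_control_split is disjoint, balanced and seeded", {
  set.seed(10)
  counts <- matrix(rpois(3000, 5), nrow = 30,
    dimnames = list(paste0("g", 1:30), paste0("c", 1:100))
  )
  m <- count_matrix(counts)
  sp <- negative_control_split(m, seed = 3)
  expect_equal(length(sp$half_a$cell_ids), 50)
  expect_equal(length(sp$half_b$cell_ids), 50)
  expect_length(intersect(sp$half_a$cell_ids, sp$half_b$cell_ids), 0)
  sp2 <- negative_control_split(m, seed = 3)
  expect_identical(sp$half_a$cell_ids, sp2$half_a$cell_ids)
  expect_true(all(c("cv2", "fano") %in% sp$report$metric))
})

test_that("null splits keep near-nominal type-I error for noise metrics", {
  set.seed(11)
  counts <- matrix(rpois(30 * 120, 8), nrow = 30,
    dimnames = list(paste0("g", 1:30), paste0("c", 1:120))
  )
  m <- count_matrix(counts)
  ps <- vapply(1:100, function(seed) {
    min(negative_control_split(m, seed = seed)$report$p_value)
  }, numeric(1))
  # two correlated tests per split; allow binomial slack around ~5-10%
  expect_lt(mean(ps < 0.05), 0.2)
  expect_gt(median(ps), 0.2)
})

test_that("amplified_fraction counts strict exceedances", {
  fc <- tibble::tibble(gene_id = letters[1:3], d_fano = c(0.5, 1.5, 2.0))
  expect_equal(amplified_fraction(fc), 2 / 3)
  expect_equal(amplified_fraction(fc, threshold = 1.5), 1 / 3)
  expect_equal(
    amplified_fraction(tibble::tibble(d_fano = rep(1, 4)), "d_fano"), 0
  )
})

test_that("amplified_fraction is invariant under depth normalization at equal totals", {
  set.seed(12)
  counts <- matrix(rpois(20 * 60, 4), nrow = 20,
    dimnames = list(paste0("g", 1:20), paste0("c", 1:60))
  )
  # force equal totals by padding a dummy gene
  totals <- colSums(counts)
  counts <- rbind(counts, pad = max(totals) - totals + 1)
  cond <- rep(c("control", "treated"), 30)
  m <- count_matrix(counts, tibble::tibble(
    cell_id = colnames(counts), condition = cond
  ))
  fc_of <- function(mm) {
    s <- noise_summary(mm, by = "condition")
    fold_change_table(
      s[s$condition == "treated", ], s[s$condition == "control", ]
    )
  }
  raw_frac <- amplified_fraction(fc_of(m))
  norm_frac <- amplified_fraction(fc_of(raw_normalize(m)))
  expect_equal(raw_frac, norm_frac)
})
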