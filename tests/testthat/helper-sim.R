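# Shared fixtures: all synthetic, built in code.

# one-gene homeostatic pair at configurable size
quick_config <- function(b = 5, f = 4, n = 1000, c = 2, eta = 0, seed = 1,
                         n_replicates = 1, ...) {
  sim_config(
    gene_params("g1", b, f),
    n_cells = n, n_replicates = n_replicates,
    extrinsic_coupling = eta, amplification = c, seed = seed, ...
  )
}

# tiny count matrix with known structure; genes x cells
toy_count_matrix <- function(counts = NULL, conditions = NULL) {
  if (is.null(counts)) {
    counts <- matrix(
      c(
        5, 0, 3,
        2, 1, 0,
        0, 0, 4,
        1, 1, 1,
        3, 0, 2
      ),
      nrow = 5, byrow = TRUE,
      dimnames = list(paste0("g", 1:5), paste0("c", 1:3))
    )
  }
  meta <- tibble::tibble(cell_id = colnames(counts))
  if (!is.null(conditions)) meta$condition <- conditions
  count_matrix(counts, meta)
}

# independent oracle for the signed-rank / rank-sum tests: base R's exact
# distributions (valid when there are no ties), kept separate from the
# package's own enumeration.
oracle_wilcox_p <- function(x, y, test, alternative) {
  alt <- c(two_sided = "two.sided", greater = "greater", less = "less")[[alternative]]
  suppressWarnings(stats::wilcox.test(
    x, y,
    paired = (test == "signed_rank"), alternative = alt,
    exact = TRUE, correct = TRUE
  )$p.value)
}
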