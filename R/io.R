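#' Read and write count matrices
#'
#' Count matrices are stored in the 10x-style layout: a Matrix Market
#' coordinate file `matrix.mtx` plus `genes.tsv` and `barcodes.tsv` sidecars
#' (one id per line, no header) and a `cells.csv` metadata table. A dense
#' CSV fallback (genes in rows, first column `gene_id`, one column per cell,
#' metadata in `<stem>_cells.csv`) is used when `path` ends in `.csv`.
#' Round-trips are lossless.
#'
#' @param path Directory (MTX layout) or `.csv` file (dense layout).
#' @param m A [count_matrix()].
#'
#' @return `read_count_matrix()` returns a [count_matrix()];
#'   `write_count_matrix()` returns `path` invisibly.
#' @export
read_count_matrix <- function(path) {
  if (grepl("\\.csv$", path)) {
    dense <- utils::read.csv(path, check.names = FALSE)
    if (nrow(dense) == 0 || ncol(dense) < 2) {
      abort(sprintf("empty count matrix in '%s'.", path))
    }
    counts <- as.matrix(dense[, -1, drop = FALSE])
    rownames(counts) <- dense[[1]]
    meta_path <- sub("\\.csv$", "_cells.csv", path)
    meta <- if (file.exists(meta_path)) {
      as_tibble(utils::read.csv(meta_path))
    } else {
      NULL
    }
    return(count_matrix(counts, meta))
  }
  mtx <- file.path(path, "matrix.mtx")
  if (!file.exists(mtx)) abort(sprintf("no matrix.mtx under '%s'.", path))
  header <- readLines(mtx, n = 1)
  if (!grepl("^%%MatrixMarket", header)) {
    abort(sprintf(
      "malformed Matrix Market header at %s line 1: '%s'.", mtx, header
    ))
  }
  counts <- methods::as(Matrix::readMM(mtx), "CsparseMatrix")
  genes <- readLines(file.path(path, "genes.tsv"))
  barcodes <- readLines(file.path(path, "barcodes.tsv"))
  if (nrow(counts) == 0 || ncol(counts) == 0) {
    abort(sprintf("empty count matrix (%d x %d) in '%s'.", nrow(counts), ncol(counts), path))
  }
  if (length(genes) != nrow(counts) || length(barcodes) != ncol(counts)) {
    abort("genes.tsv/barcodes.tsv lengths do not match the matrix.")
  }
  dimnames(counts) <- list(genes, barcodes)
  meta_path <- file.path(path, "cells.csv")
  meta <- if (file.exists(meta_path)) {
    as_tibble(utils::read.csv(meta_path))
  } else {
    NULL
  }
  count_matrix(counts, meta)
}

#' @rdname read_count_matrix
#' @export
write_count_matrix <- function(m, path) {
  stopifnot(inherits(m, "count_matrix"))
  meta_cols <- setdiff(
    names(m$cell_meta), c("total_umi", "detected_genes", "mito_frac")
  )
  if (grepl("\\.csv$", path)) {
    dense <- data.frame(
      gene_id = m$gene_ids, as.matrix(m$counts), check.names = FALSE
    )
    utils::write.csv(dense, path, row.names = FALSE)
    utils::write.csv(m$cell_meta[, meta_cols, drop = FALSE],
      sub("\\.csv$", "_cells.csv", path),
      row.names = FALSE
    )
    return(invisible(path))
  }
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  Matrix::writeMM(m$counts, file.path(path, "matrix.mtx"))
  writeLines(m$gene_ids, file.path(path, "genes.tsv"))
  writeLines(m$cell_ids, file.path(path, "barcodes.tsv"))
  utils::write.csv(m$cell_meta[, meta_cols, drop = FALSE],
    file.path(path, "cells.csv"),
    row.names = FALSE
  )
  invisible(path)
}

#' Read and write smFISH-style cell tables
#'
#' Cell tables are CSV files with columns `cell_id`, `condition`,
#' `replicate`, `area` and one `count_<gene_id>` column per probed gene.
#' Reading validates the schema: the required columns must be present,
#' `cell_id` must be unique, areas positive and counts non-negative
#' integers.
#'
#' @param path CSV file path.
#' @param cells A per-cell tibble with the schema above.
#'
#' @return `read_cell_table()` returns a tibble; `write_cell_table()`
#'   returns `path` invisibly.
#' @export
read_cell_table <- function(path) {
  cells <- as_tibble(utils::read.csv(path))
  required <- c("cell_id", "condition", "replicate", "area")
  missing <- setdiff(required, names(cells))
  if (length(missing)) {
    abort(sprintf(
      "cell table '%s' lacks column(s): %s.", path,
      paste(missing, collapse = ", ")
    ))
  }
  dups <- unique(cells$cell_id[duplicated(cells$cell_id)])
  if (length(dups)) {
    abort(sprintf(
      "duplicate cell_id(s) in '%s': %s.", path,
      paste(head(dups, 5), collapse = ", ")
    ))
  }
  count_cols <- grep("^count_", names(cells), value = TRUE)
  if (length(count_cols) == 0) {
    abort(sprintf("cell table '%s' has no count_<gene> columns.", path))
  }
  counts <- as.matrix(cells[, count_cols])
  if (any(counts < 0) || any(abs(counts - round(counts)) > 1e-8)) {
    abort(sprintf("counts in '%s' must be non-negative integers.", path))
  }
  check_cell_table_cols(cells)
  cells
}

#' @rdname read_cell_table
#' @export
write_cell_table <- function(cells, path) {
  utils::write.csv(cells, path, row.names = FALSE)
  invisible(path)
}

#' Write an analysis table as TSV
#'
#' Writes noise summaries, fold-change tables, burst fits or score tables
#' with stable column names; floats are serialized with 9 significant
#' digits.
#'
#' @param x A data frame.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_table_tsv <- function(x, path) {
  out <- as.data.frame(x)
  num <- vapply(out, is.numeric, logical(1))
  out[num] <- lapply(out[num], function(v) {
    ifelse(v == round(v) & abs(v) < 1e15, format(v, scientific = FALSE),
      signif(v, 9)
    )
  })
  utils::write.table(out, path,
    sep = "\t", quote = FALSE, row.names = FALSE
  )
  invisible(path)
}

#' @rdname write_table_tsv
#' @export
read_table_tsv <- function(path) {
  as_tibble(utils::read.delim(path))
}

#' Run configuration
#'
#' Assembles (and validates against defaults) the full configuration of an
#' end-to-end run: simulation parameters, QC and coverage-filter thresholds,
#' normalization scale, extrinsic-filter settings, burst-fit options and the
#' output directory. Configurations are plain lists, fully serializable to
#' JSON or YAML; a run's config and seed determine all outputs.
#'
#' @param ... Named overrides of the defaults (nested lists are merged
#'   shallowly per section).
#'
#' @return A list of class `"run_config"`.
#' @export
#' @examples
#' cfg <- run_config(seed = 42, sim = list(n_cells = 100))
run_config <- function(...) {
  defaults <- list(
    seed = 1L,
    out_dir = tempfile("noisebench_run_"),
    sim = list(
      n_genes = 8, burst_size_range = c(2, 15),
      burst_frequency_range = c(0.5, 5), n_cells = 200, n_replicates = 3,
      extrinsic_coupling = 1, capture_mean = 0.1, capture_sd = 0,
      amplification = 2, area_shift_treated = 1
    ),
    qc = list(
      min_genes = 1, min_umi = 1, max_mito_frac = 0.1, mito_prefix = "mt-"
    ),
    coverage = list(min_mean_count = 0.1, min_detect_frac = 0.05),
    normalize = list(scale = 1e4),
    filter = list(
      alpha = 0.01, n_perm = 10000, init_trim = c(5, 95),
      iter_trim = c(2, 98), r_max = 0.45, min_cells = 50, max_iter = 25
    ),
    burst = list(pooled = TRUE)
  )
  overrides <- list(...)
  unknown <- setdiff(names(overrides), names(defaults))
  if (length(unknown)) {
    abort(paste0("unknown config section(s): ", paste(unknown, collapse = ", ")))
  }
  for (key in names(overrides)) {
    if (is.list(defaults[[key]]) && is.list(overrides[[key]])) {
      bad <- setdiff(names(overrides[[key]]), names(defaults[[key]]))
      if (length(bad)) {
        abort(sprintf(
          "unknown option(s) in `%s`: %s.", key, paste(bad, collapse = ", ")
        ))
      }
      defaults[[key]][names(overrides[[key]])] <- overrides[[key]]
    } else {
      defaults[[key]] <- overrides[[key]]
    }
  }
  structure(defaults, class = "run_config")
}

#' @rdname run_config
#' @param path JSON (`.json`) or YAML (`.yaml`/`.yml`) file.
#' @export
read_run_config <- function(path) {
  raw <- if (grepl("\\.json$", path)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  do.call(run_config, raw)
}

#' @rdname run_config
#' @param config A `run_config`.
#' @export
write_run_config <- function(config, path) {
  if (grepl("\\.json$", path)) {
    jsonlite::write_json(unclass(config), path,
      auto_unbox = TRUE, digits = NA, pretty = TRUE
    )
  } else {
    yaml::write_yaml(unclass(config), path)
  }
  invisible(path)
}

# Per-stage seed substream: a fixed affine derivation from the global seed,
# so inserting a stage never shifts another stage's randomness.
stage_seed <- function(seed, stage) {
  offsets <- c(
    simulate = 1L, split = 2L, filter = 3L, burst = 4L, score = 5L
  )
  if (!stage %in% names(offsets)) abort(sprintf("unknown stage '%s'.", stage))
  (as.integer(seed) + 7919L * offsets[[stage]]) %% 2147483647L
}

file_hash <- function(path) {
  rlang::hash(readBin(path, "raw", n = file.size(path)))
}

#' Run the full two-arm analysis pipeline
#'
#' Chains every stage end to end on simulated data with shared ground truth:
#' an smFISH-like arm (cell tables -> extrinsic-noise filter -> noise
#' summaries -> fold changes -> NB burst fits -> reciprocity) and a
#' scRNA-seq-like arm (UMI matrices -> QC -> gene coverage filter -> depth
#' normalization -> noise summaries -> replicate-averaged fold changes),
#' then scores the sequencing arm against the smFISH reference. All tables
#' are written under `config$out_dir` together with a JSON manifest
#' recording the package version, config hash, per-stage seeds, output file
#' hashes and warnings.
#'
#' @param config A [run_config()].
#'
#' @return The manifest, invisibly, as a list; its `results` element holds
#'   the in-memory tables (`fish_fc`, `umi_fc`, `scores`, `burst_summary`,
#'   `reciprocity`, `filters`).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  warnings_seen <- character()
  note <- function(w) {
    warnings_seen <<- c(warnings_seen, conditionMessage(w))
    invokeRestart("muffleWarning")
  }
  sim_seed <- stage_seed(config$seed, "simulate")
  set.seed(sim_seed)
  sc <- config$sim
  genes <- gene_params(
    gene_id = sprintf("gene%02d", seq_len(sc$n_genes)),
    burst_size = stats::runif(sc$n_genes, sc$burst_size_range[1], sc$burst_size_range[2]),
    burst_frequency = stats::runif(
      sc$n_genes, sc$burst_frequency_range[1], sc$burst_frequency_range[2]
    )
  )
  scfg <- sim_config(
    genes,
    n_cells = sc$n_cells, n_replicates = sc$n_replicates,
    extrinsic_coupling = sc$extrinsic_coupling,
    capture_mean = sc$capture_mean, capture_sd = sc$capture_sd,
    amplification = sc$amplification,
    area_shift_treated = sc$area_shift_treated, seed = sim_seed
  )
  fish <- simulate_smfish(scfg)
  umi <- simulate_umi_matrix(scfg)
  cells <- dplyr::bind_rows(fish$control, fish$treated)
  write_cell_table(cells, file.path(config$out_dir, "smfish_cells.csv"))
  write_count_matrix(umi$control, file.path(config$out_dir, "umi_control"))
  write_count_matrix(umi$treated, file.path(config$out_dir, "umi_treated"))

  # smFISH arm: extrinsic filter per gene, then noise + bursts on survivors
  fl <- config$filter
  filters <- withCallingHandlers(
    purrr::map(genes$gene_id, function(g) {
      iterative_extrinsic_filter(cells, g,
        alpha = fl$alpha, n_perm = fl$n_perm, init_trim = fl$init_trim,
        iter_trim = fl$iter_trim, r_max = fl$r_max,
        min_cells = fl$min_cells, max_iter = fl$max_iter,
        seed = stage_seed(config$seed, "filter")
      )
    }),
    warning = note
  )
  names(filters) <- genes$gene_id
  fish_fc <- purrr::map_dfr(genes$gene_id, function(g) {
    kept <- filters[[g]]$cells
    summ <- noise_summary(kept, by = c("condition", "replicate"))
    summ <- summ[summ$gene_id == g, , drop = FALSE]
    fold_change_table(
      summ[summ$condition == "treated", ],
      summ[summ$condition == "control", ],
      method = "smfish"
    )
  })
  fish_fc_avg <- replicate_average(fish_fc)
  fish_fc_avg$method <- "smfish"
  write_table_tsv(fish_fc_avg, file.path(config$out_dir, "smfish_fold_changes.tsv"))

  burst_fits <- withCallingHandlers(
    purrr::map_dfr(genes$gene_id, function(g) {
      fit_bursts(filters[[g]]$cells,
        genes = g, pooled = config$burst$pooled
      )
    }),
    warning = note
  )
  burst_fc <- withCallingHandlers(
    burst_fold_changes(burst_fits),
    warning = note
  )
  burst_summary <- summarize_burst_fold_changes(burst_fc)
  write_table_tsv(burst_fits, file.path(config$out_dir, "burst_fits.tsv"))
  write_table_tsv(burst_summary, file.path(config$out_dir, "burst_fold_changes.tsv"))
  reciprocity <- glance(reciprocity_regression(
    dplyr::filter(burst_fc, .data$replicate != "pooled")
  ))

  # sequencing arm: QC -> coverage -> depth normalization -> fold changes
  qc <- config$qc
  umi_arm <- purrr::map(list(control = umi$control, treated = umi$treated), function(m) {
    qc_filter_cells(m,
      min_genes = qc$min_genes, min_umi = qc$min_umi,
      max_mito_frac = qc$max_mito_frac, mito_prefix = qc$mito_prefix
    )
  })
  cov <- config$coverage
  shared_genes <- NULL
  umi_arm <- purrr::map(umi_arm, function(m) {
    gene_coverage_filter(m,
      min_mean_count = cov$min_mean_count,
      min_detect_frac = cov$min_detect_frac
    )
  })
  shared_genes <- intersect(umi_arm$control$gene_ids, umi_arm$treated$gene_ids)
  umi_arm <- purrr::map(umi_arm, function(m) {
    subset_genes(m, match(shared_genes, m$gene_ids))
  })
  umi_norm <- purrr::map(umi_arm, raw_normalize, scale = config$normalize$scale)
  umi_summ <- purrr::map(umi_norm, noise_summary, by = "replicate")
  umi_fc <- fold_change_table(umi_summ$treated, umi_summ$control, method = "raw")
  umi_fc_avg <- replicate_average(umi_fc)
  umi_fc_avg$method <- "raw"
  write_table_tsv(umi_fc_avg, file.path(config$out_dir, "umi_fold_changes.tsv"))

  scores <- rank_methods(list(raw = umi_fc_avg), fish_fc_avg)
  write_table_tsv(scores, file.path(config$out_dir, "method_scores.tsv"))

  out_files <- list.files(config$out_dir, recursive = TRUE, full.names = TRUE)
  out_files <- out_files[!grepl("manifest\\.json$", out_files)]
  manifest <- list(
    package = "noisebench",
    version = as.character(utils::packageVersion("noisebench")),
    seed = config$seed,
    stage_seeds = list(
      simulate = stage_seed(config$seed, "simulate"),
      filter = stage_seed(config$seed, "filter")
    ),
    config_hash = rlang::hash(unclass(config)),
    outputs = lapply(
      setNames(out_files, basename(out_files)), file_hash
    ),
    warnings = warnings_seen,
    results = list(
      fish_fc = fish_fc_avg, umi_fc = umi_fc_avg, scores = scores,
      burst_summary = burst_summary, reciprocity = reciprocity,
      filters = purrr::map_dfr(filters, glance)
    )
  )
  jsonlite::write_json(
    manifest[setdiff(names(manifest), "results")],
    file.path(config$out_dir, "manifest.json"),
    auto_unbox = TRUE, digits = NA, pretty = TRUE
  )
  invisible(manifest)
}
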