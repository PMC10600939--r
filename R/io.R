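#' Write a cohort bundle to plain-text files
#'
#' Lays a cohort out in the on-disk layout the file-based pipeline
#' consumes: one TSV per subject (rows = time points, columns = ROIs)
#' under `timeseries/`, an atlas TSV (`roi_id`, `x`, `y`, `z`,
#' `network`), a clinical CSV, a covariates CSV, and — for synthetic
#' cohorts — a ground-truth JSON.
#'
#' @param cohort A `cohort_bundle`.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the paths written (named list).
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "cohort_bundle"))
  ts_dir <- file.path(dir, "timeseries")
  dir.create(ts_dir, recursive = TRUE, showWarnings = FALSE)
  for (s in names(cohort$timeseries)) {
    m <- tibble::as_tibble(cohort$timeseries[[s]], .name_repair = ~ paste0("roi_", seq_along(.x)))
    readr::write_tsv(m, file.path(ts_dir, paste0(s, ".tsv")))
  }
  paths <- list(
    timeseries_dir = ts_dir,
    atlas = file.path(dir, "atlas.tsv"),
    clinical = file.path(dir, "clinical.csv"),
    covariates = file.path(dir, "covariates.csv"),
    truth = file.path(dir, "ground_truth.json"))
  readr::write_tsv(cohort$atlas, paths$atlas)
  readr::write_csv(cohort$clinical, paths$clinical)
  readr::write_csv(cohort$covariates, paths$covariates)
  if (!is.null(cohort$truth)) {
    tr <- cohort$truth
    jsonlite::write_json(
      list(latent_scores = unclass(tr$latent_scores),
           coupled_edges = tr$coupled_edges,
           shared_edges = tr$shared_edges,
           coupling = tr$coupling,
           mediation_params = as.list(tr$mediation_params)),
      paths$truth, auto_unbox = TRUE, digits = NA)
  }
  invisible(paths)
}

#' Read a cohort from the on-disk layout of [write_cohort()]
#'
#' @param dir Directory containing `timeseries/`, `atlas.tsv`,
#'   `clinical.csv`, `covariates.csv`.
#' @param tr_s Repetition time in seconds (not stored in the TSVs).
#' @return A `cohort_bundle` (without ground truth).
#' @export
read_cohort <- function(dir, tr_s = 2) {
  ts_files <- sort(list.files(file.path(dir, "timeseries"),
                              pattern = "\\.tsv$", full.names = TRUE))
  if (!length(ts_files)) abort(paste0("no time-series TSVs under ", dir))
  ts <- lapply(ts_files, function(f) {
    as.matrix(readr::read_tsv(f, show_col_types = FALSE))
  })
  names(ts) <- sub("\\.tsv$", "", basename(ts_files))
  atlas <- readr::read_tsv(file.path(dir, "atlas.tsv"), show_col_types = FALSE)
  structure(list(
    timeseries = ts,
    clinical = readr::read_csv(file.path(dir, "clinical.csv"),
                               show_col_types = FALSE),
    covariates = readr::read_csv(file.path(dir, "covariates.csv"),
                                 show_col_types = FALSE),
    truth = NULL,
    atlas = atlas,
    edge_index = edge_index(atlas),
    tr_s = tr_s), class = "cohort_bundle")
}

#' Write an analysis results bundle to disk
#'
#' Writes, per clinical block, the permutation table, bootstrap pair
#' statistics, stable features, structure loadings and network-block
#' loading sums as CSV, plus a `results.json` summary (canonical
#' correlations, p/q values, mediation estimates) and a `provenance.json`
#' carrying the configuration, its hash and the package version. Every
#' CSV gets a `# config_hash:` comment header.
#'
#' @param results A `dfc_cca_results` object from [run_all()].
#' @param dir Output directory.
#' @return Invisibly, `dir`.
#' @export
write_results <- function(results, dir) {
  stopifnot(inherits(results, "dfc_cca_results"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  hash <- results$provenance$config_hash
  stamp_csv <- function(df, path) {
    writeLines(paste0("# config_hash: ", hash), path)
    readr::write_csv(df, path, append = TRUE, col_names = TRUE)
  }
  if (!is.null(results$dfc)) {
    stamp_csv(dplyr::bind_cols(tibble::tibble(subject = rownames(results$dfc)),
                               tibble::as_tibble(results$dfc)),
              file.path(dir, "dfc_matrix.csv"))
  }
  for (blk in names(results$models)) {
    m <- results$models[[blk]]
    stamp_csv(m$permutation, file.path(dir, paste0(blk, "_permutation.csv")))
    stamp_csv(m$bootstrap$pair_stats, file.path(dir, paste0(blk, "_bootstrap.csv")))
    stamp_csv(m$bootstrap$feature_stats,
              file.path(dir, paste0(blk, "_features.csv")))
    stamp_csv(m$network_loadings, file.path(dir, paste0(blk, "_network_loadings.csv")))
    stamp_csv(m$loadings, file.path(dir, paste0(blk, "_loadings.csv")))
    stamp_csv(tidy(m$model), file.path(dir, paste0(blk, "_weights.csv")))
    jsonlite::write_json(
      list(config_hash = hash,
           sparsity = as.list(m$sparsity),
           standardization = m$model$standardization,
           pairs = lapply(m$model$pairs, function(p) {
             list(r = p$r, u = p$u, v = p$v, converged = p$converged)
           })),
      file.path(dir, paste0(blk, "_model.json")), auto_unbox = TRUE,
      digits = NA)
  }
  if (!is.null(results$mediation)) {
    writeLines(
      unlist(lapply(names(results$mediation), function(nm) {
        c(paste0("== ", nm, " links =="),
          utils::capture.output(print(results$mediation[[nm]])))
      })),
      file.path(dir, "mediation_summary.txt"))
  }
  summary <- list(
    pairs = results$pair_table,
    dimension_correlations = results$dimension_correlations,
    mediation = lapply(results$mediation, function(mf) {
      if (is.null(mf)) NULL else mf$estimates
    }))
  jsonlite::write_json(summary, file.path(dir, "results.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  jsonlite::write_json(results$provenance, file.path(dir, "provenance.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
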