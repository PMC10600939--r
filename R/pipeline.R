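#' Assemble (or load) a pipeline run configuration
#'
#' Collects every knob of the end-to-end analysis in one validated list:
#' window specification, dFC method, feature-selection mode and fraction,
#' sparsity handling, permutation/bootstrap sizes and the seed all other
#' stage seeds derive from. `run_config()` builds it from arguments;
#' `read_run_config()` loads the same fields from a YAML file.
#'
#' @param width_tr,step_tr Sliding-window width and step in TRs.
#' @param dfc_method `"sliding_window"` or `"fls"`.
#' @param fls_mu FLS smoothness penalty.
#' @param fisher_z Take the SD on Fisher-z transformed correlations.
#' @param discard_initial_volumes Leading volumes dropped at validation
#'   (default 0; scanner equilibration frames).
#' @param selection_mode `"regression"` (RReliefF against the first
#'   principal component of the clinical block) or `"classification"`
#'   (ReliefF against the diagnosis label).
#' @param selection_fraction Top fraction of dFC features kept.
#' @param k_neighbors Relief neighbourhood size (clamped to the number
#'   of subjects minus one at run time; default 100, i.e. most of a
#'   cohort of ~122 subjects serves as the neighbourhood).
#' @param tune Logical: tune the sparsity budgets by cross-validation? If
#'   `FALSE`, `c_x`/`c_y` are used as given.
#' @param c_x,c_y Sparsity budgets (used when `tune = FALSE`).
#' @param c_x_grid,c_y_grid Tuning grids.
#' @param reselect_in_permutation If `TRUE`, each permutation iteration
#'   re-runs Relief selection on the permuted clinical block, so the
#'   null distribution reflects the full selection + fit procedure.
#'   Default `FALSE` (selection held fixed; faster, and anticonservative
#'   under the null when selection is supervised — see the vignette).
#' @param n_pairs Canonical pairs to extract per block (default: number
#'   of clinical items, capped at 10 — resolved at run time).
#' @param n_perm,n_boot Permutation and bootstrap sizes.
#' @param stability_threshold Bootstrap same-sign selection frequency for
#'   a feature to count stable.
#' @param q_threshold FDR threshold for significant pairs.
#' @param seed Root seed.
#' @return List of class `run_config`.
#' @export
run_config <- function(width_tr = 22, step_tr = 1,
                       dfc_method = c("sliding_window", "fls"),
                       fls_mu = 100, fisher_z = FALSE,
                       discard_initial_volumes = 0,
                       selection_mode = c("regression", "classification"),
                       selection_fraction = 0.01, k_neighbors = 100,
                       tune = FALSE, c_x = 0.7, c_y = 0.8,
                       c_x_grid = seq(0.1, 1, by = 0.1),
                       c_y_grid = seq(0.1, 1, by = 0.1),
                       reselect_in_permutation = FALSE,
                       n_pairs = NULL, n_perm = 1000, n_boot = 1000,
                       stability_threshold = 0.9, q_threshold = 0.05,
                       seed = 1) {
  cfg <- list(width_tr = width_tr, step_tr = step_tr,
              dfc_method = match.arg(dfc_method), fls_mu = fls_mu,
              fisher_z = fisher_z,
              discard_initial_volumes = discard_initial_volumes,
              selection_mode = match.arg(selection_mode),
              selection_fraction = selection_fraction,
              k_neighbors = k_neighbors, tune = tune,
              c_x = c_x, c_y = c_y,
              c_x_grid = c_x_grid, c_y_grid = c_y_grid,
              reselect_in_permutation = reselect_in_permutation,
              n_pairs = n_pairs, n_perm = n_perm, n_boot = n_boot,
              stability_threshold = stability_threshold,
              q_threshold = q_threshold, seed = seed)
  class(cfg) <- "run_config"
  cfg
}

#' @rdname run_config
#' @param path Path to a YAML file whose keys match the `run_config()`
#'   arguments.
#' @export
read_run_config <- function(path) {
  vals <- yaml::read_yaml(path)
  unknown <- setdiff(names(vals), names(formals(run_config)))
  if (length(unknown)) {
    abort(paste0("unknown config field(s): ", paste(unknown, collapse = ", ")))
  }
  do.call(run_config, vals)
}

#' Validate a cohort against a run configuration
#'
#' Checks the structural contract the pipeline assumes before any
#' computation: matched subject sets and ordering across time series,
#' clinical table and covariates; no missing values; every series long
#' enough for the configured window after discarding the configured
#' number of initial volumes. The discard is applied here (e.g. a
#' 205-volume session with 5 discarded enters the analysis with 200
#' volumes). Problems are reported as one itemized error.
#'
#' @param cohort A `cohort_bundle` (in-memory or from [read_cohort()]).
#' @param config A `run_config`.
#' @return The validated (possibly trimmed) `cohort_bundle`, with
#'   attribute `validation` summarizing retained volume/ROI counts.
#' @export
validate_cohort_files <- function(cohort, config = run_config()) {
  stopifnot(inherits(cohort, "cohort_bundle"))
  problems <- character(0)
  subj_ts <- names(cohort$timeseries)
  subj_cl <- cohort$clinical$subject
  subj_cov <- cohort$covariates$subject
  for (nm in setdiff(subj_ts, subj_cl)) {
    problems <- c(problems, paste0("subject ", nm, " missing from clinical table"))
  }
  for (nm in setdiff(subj_ts, subj_cov)) {
    problems <- c(problems, paste0("subject ", nm, " missing from covariates"))
  }
  for (nm in setdiff(union(subj_cl, subj_cov), subj_ts)) {
    problems <- c(problems, paste0("subject ", nm, " has no time series"))
  }
  drop0 <- config$discard_initial_volumes
  trimmed <- lapply(subj_ts, function(nm) {
    ts <- cohort$timeseries[[nm]]
    if (anyNA(ts)) {
      problems <<- c(problems, paste0("subject ", nm, " has NaN cells"))
    }
    if (nrow(ts) <= drop0) {
      problems <<- c(problems, paste0("subject ", nm, " shorter than discard count"))
      return(ts)
    }
    if (drop0 > 0) ts <- ts[-seq_len(drop0), , drop = FALSE]
    if (nrow(ts) < config$width_tr) {
      problems <<- c(problems,
                     sprintf("subject %s: %d volumes < window width %d",
                             nm, nrow(ts), config$width_tr))
    }
    if (ncol(ts) != nrow(cohort$atlas)) {
      problems <<- c(problems,
                     sprintf("subject %s: %d ROIs but atlas has %d",
                             nm, ncol(ts), nrow(cohort$atlas)))
    }
    ts
  })
  if (length(problems)) {
    abort(paste0("cohort validation failed:\n  - ",
                 paste(problems, collapse = "\n  - ")))
  }
  names(trimmed) <- subj_ts
  if (any(vapply(trimmed, nrow, 1L) == config$width_tr)) {
    warn("some series have exactly one analysis window")
  }
  cohort$timeseries <- trimmed
  # align clinical/covariates to the time-series subject order
  cohort$clinical <- cohort$clinical[match(subj_ts, subj_cl), , drop = FALSE]
  cohort$covariates <- cohort$covariates[match(subj_ts, subj_cov), , drop = FALSE]
  attr(cohort, "validation") <- list(
    n_subjects = length(trimmed),
    retained_volumes = nrow(trimmed[[1]]),
    n_roi = ncol(trimmed[[1]]),
    discarded_volumes = drop0)
  cohort
}

# one clinical block (behavior or cognition) through selection, sparse
# CCA, permutation and bootstrap
run_dimension_model <- function(X_resid, Y_block, covariates, config, seed,
                                diagnosis = NULL) {
  Y_resid <- residualize(Y_block, covariates, c("age", "sex"))
  if (config$selection_mode == "classification") {
    if (is.null(diagnosis)) abort("classification selection needs a diagnosis column")
    target <- diagnosis
  } else {
    target <- pca_reduce(Y_resid, variance_kept = 1e-12)$scores[, 1]
  }
  k_eff <- min(config$k_neighbors, nrow(X_resid) - 1)
  select_features <- function(X, Y) {
    tgt <- if (config$selection_mode == "classification") target
           else pca_reduce(Y, variance_kept = 1e-12)$scores[, 1]
    select_top_fraction(
      relief_weights(X, tgt, k_neighbors = k_eff,
                     mode = config$selection_mode),
      config$selection_fraction)
  }
  w <- relief_weights(X_resid, target, k_neighbors = k_eff,
                      mode = config$selection_mode)
  sel <- select_top_fraction(w, config$selection_fraction)
  Xs <- X_resid[, sel, drop = FALSE]
  if (isTRUE(config$tune)) {
    tuned <- tune_sparsity(Xs, Y_resid, config$c_x_grid, config$c_y_grid,
                           seed = seed)
    c_x <- tuned$c_x; c_y <- tuned$c_y
  } else {
    c_x <- config$c_x; c_y <- config$c_y; tuned <- NULL
  }
  n_pairs <- config$n_pairs %||% min(ncol(Xs), ncol(Y_resid), 10)
  model <- fit_scca(Xs, Y_resid, n_pairs = n_pairs, c_x = c_x, c_y = c_y)
  perm <- permutation_test(
    Xs, Y_resid, n_pairs, c_x, c_y,
    n_perm = config$n_perm, seed = seed + 1, model = model,
    X_full = if (isTRUE(config$reselect_in_permutation)) X_resid,
    select_fun = if (isTRUE(config$reselect_in_permutation)) select_features)
  boot <- bootstrap_stability(Xs, Y_resid, n_pairs, c_x, c_y,
                              n_boot = config$n_boot,
                              stability_threshold = config$stability_threshold,
                              seed = seed + 2, model = model)
  loadings <- structure_loadings(Xs, Y_resid, model)
  scores <- scca_scores(model, X = Xs, Y = Y_resid)
  list(model = model, permutation = perm, bootstrap = boot,
       loadings = loadings, scores = scores, selected = sel,
       relief_weights = w, tuning = tuned,
       sparsity = c(c_x = c_x, c_y = c_y))
}

#' Run the full dFC-dimension analysis end to end
#'
#' Orchestrates the whole pipeline on a (validated) cohort: dFC
#' variability per subject, confound residualization (age, sex, mean
#' framewise displacement out of dFC; age and sex out of the clinical
#' blocks), Relief selection of the top dFC features, separate sparse CCA
#' models for the behavior block and the cognition block (sharing the dFC
#' matrix), permutation significance with FDR applied jointly across the
#' pairs of both models, bootstrap stability, structure loadings and
#' their network-block sums, behavior-by-cognition dimension-score
#' correlations, and — when significant dimensions share stable dFC
#' features — overlap composites and mediation of dFC on behavior
#' through cognition (covariates age and sex). Identical configuration
#' and seed reproduce identical outputs.
#'
#' @param cohort A `cohort_bundle`; clinical columns must carry the
#'   `behav_`/`cog_` prefixes.
#' @param config A `run_config`.
#' @param out_dir Optional directory; when given, results are written
#'   there via [write_results()].
#' @return List of class `dfc_cca_results` with `models` (per block:
#'   model, permutation, bootstrap, loadings, network_loadings, scores),
#'   `pair_table` (joint FDR across blocks), `dimension_correlations`,
#'   `overlap`, `mediation`, `validation`, `provenance`.
#' @export
run_all <- function(cohort, config = run_config(), out_dir = NULL) {
  cohort <- validate_cohort_files(cohort, config)
  seed <- config$seed
  dfc <- compute_dfc(cohort$timeseries, method = config$dfc_method,
                     width_tr = config$width_tr, step_tr = config$step_tr,
                     fisher_z = config$fisher_z, mu = config$fls_mu)
  covs <- cohort$covariates
  X_resid <- residualize(dfc, covs, c("age", "sex", "mean_fd"))
  cl <- as.data.frame(cohort$clinical)
  blocks <- list(
    behavior = as.matrix(cl[, grep("^behav_", names(cl)), drop = FALSE]),
    cognition = as.matrix(cl[, grep("^cog_", names(cl)), drop = FALSE]))
  if (any(vapply(blocks, ncol, 1L) == 0)) {
    abort("clinical table must contain behav_* and cog_* columns")
  }
  models <- list(
    behavior = run_dimension_model(X_resid, blocks$behavior, covs, config,
                                   seed = seed + 100, diagnosis = covs$diagnosis),
    cognition = run_dimension_model(X_resid, blocks$cognition, covs, config,
                                    seed = seed + 200, diagnosis = covs$diagnosis))
  # joint FDR across the extracted pairs of both blocks
  pair_table <- dplyr::bind_rows(
    dplyr::mutate(models$behavior$permutation, block = "behavior"),
    dplyr::mutate(models$cognition$permutation, block = "cognition"))
  pair_table$q <- fdr_adjust(pair_table$p)
  pair_table$significant <- pair_table$q < config$q_threshold
  # network-block loading sums per pair (edge features only)
  for (blk in names(models)) {
    xl <- dplyr::filter(models[[blk]]$loadings, .data$side == "x")
    xl$edge_id <- as.integer(sub("^edge_", "", xl$variable))
    models[[blk]]$network_loadings <-
      network_block_loadings(dplyr::select(xl, "pair", "edge_id", "loading"),
                             cohort$edge_index)
  }
  sig <- function(blk) {
    pt <- pair_table[pair_table$block == blk & pair_table$significant, ]
    if (nrow(pt)) pt$pair else integer(0)
  }
  sig_b <- sig("behavior"); sig_c <- sig("cognition")
  dim_cor <- NULL; overlap <- NULL; mediation <- NULL
  if (length(sig_b) && length(sig_c)) {
    bs <- models$behavior$scores$y_scores[, sig_b, drop = FALSE]
    cs <- models$cognition$scores$y_scores[, sig_c, drop = FALSE]
    colnames(bs) <- paste0("behavior_pair", sig_b)
    colnames(cs) <- paste0("cognition_pair", sig_c)
    dim_cor <- dimension_score_correlations(bs, cs)
    # mediate through the most strongly correlated dimension pairing
    top <- dim_cor[which.max(abs(dim_cor$r)), ]
    kb <- as.integer(sub("behavior_pair", "", top$behavior_dim))
    kc <- as.integer(sub("cognition_pair", "", top$cognition_dim))
    cl_cog <- models$cognition$loadings
    cl_cog <- cl_cog[cl_cog$side == "x" & cl_cog$pair == kc, ]
    cog_load <- stats::setNames(cl_cog$loading, cl_cog$variable)
    overlap <- select_overlap_composites(
      models$behavior$bootstrap$stable_features[[kb]],
      models$cognition$bootstrap$stable_features[[kc]],
      cog_load, X_resid)
    if (!overlap$empty) {
      # standardized composite and dimension scores -> standardized paths
      med_data <- dplyr::bind_cols(
        dplyr::mutate(overlap$composites,
                      dplyr::across(dplyr::everything(),
                                    ~ as.numeric(scale(.x)))),
        tibble::tibble(M = as.numeric(scale(models$cognition$scores$y_scores[, kc])),
                       Y = as.numeric(scale(models$behavior$scores$y_scores[, kb])),
                       age = covs$age, sex = covs$sex))
      mediation <- lapply(intersect(c("positive", "negative"),
                                    names(overlap$composites)),
                          function(link) {
        fit_mediation(med_data, x = link, m = "M", y = "Y",
                      covariates = c("age", "sex"),
                      n_boot = max(500, config$n_boot), seed = seed + 300)
      })
      names(mediation) <- intersect(c("positive", "negative"),
                                    names(overlap$composites))
    }
  }
  provenance <- list(
    config = unclass(config),
    config_hash = rlang::hash(unclass(config)),
    package_version = as.character(utils::packageVersion("dfclink")),
    r_version = R.version.string,
    n_subjects = attr(cohort, "validation")$n_subjects,
    retained_volumes = attr(cohort, "validation")$retained_volumes)
  out <- structure(list(models = models, pair_table = pair_table,
                        dimension_correlations = dim_cor,
                        overlap = overlap, mediation = mediation,
                        dfc = dfc,
                        validation = attr(cohort, "validation"),
                        provenance = provenance),
                   class = "dfc_cca_results")
  if (!is.null(out_dir)) write_results(out, out_dir)
  out
}

#' @export
print.dfc_cca_results <- function(x, ...) {
  cat("dFC-dimension analysis results\n")
  cat(sprintf("  %d subjects, %d retained volumes, %d edges\n",
              x$validation$n_subjects, x$validation$retained_volumes,
              ncol(x$dfc)))
  pt <- x$pair_table
  cat(sprintf("  significant pairs (q < %.2f): %d of %d\n",
              x$provenance$config$q_threshold, sum(pt$significant), nrow(pt)))
  if (!is.null(x$mediation)) {
    cat("  mediation fitted for link set(s):",
        paste(names(x$mediation), collapse = ", "), "\n")
  }
  invisible(x)
}
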