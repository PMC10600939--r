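#' Permutation test for canonical correlations
#'
#' Builds a null distribution for each canonical pair by permuting the
#' subject rows of the clinical block `Y` uniformly at random, refitting
#' the full sparse CCA model (same sparsity budgets, same number of
#' pairs) on each permuted dataset, and comparing observed to permuted
#' correlations with the add-one estimator
#' `p_k = (1 + #\{r_perm >= r_obs\}) / (1 + n_perm)`, so p is never
#' exactly 0 and is bounded below by `1/(n_perm + 1)`. Benjamini-Hochberg
#' adjusted q-values across the extracted pairs are included.
#'
#' @param X,Y Subjects-by-features matrices (original scale).
#' @param n_pairs,c_x,c_y Model specification passed to [fit_scca()].
#' @param n_perm Number of permutations (default 1000).
#' @param seed Integer seed for the permutations.
#' @param model Optional pre-fitted `scca` model on `(X, Y)` (saves one
#'   fit; must match the specification).
#' @param perms Optional list of explicit permutations (integer vectors),
#'   overriding random generation — mainly for testing.
#' @param X_full,select_fun Optional supervised-selection refresh: when
#'   both are given, `X` must equal `X_full[, select_fun(X_full, Y)]` up
#'   to selection, and every permutation re-runs the selection on the
#'   permuted clinical block (`select_fun(X_full, Y_perm)`) before
#'   refitting. This removes the optimism that fixed supervised feature
#'   selection injects into the null distribution, at the cost of one
#'   selection pass per permutation.
#' @return A tibble of class `scca_perm` with columns `pair`, `r`, `p`,
#'   `q`, `n_perm`, and attribute `perm_r` (the n_perm x n_pairs matrix
#'   of permuted correlations).
#' @export
permutation_test <- function(X, Y, n_pairs = min(ncol(Y), 10),
                             c_x = 1, c_y = 1, n_perm = 1000, seed = 1,
                             model = NULL, perms = NULL,
                             X_full = NULL, select_fun = NULL) {
  X <- as.matrix(X); Y <- as.matrix(Y)
  n <- nrow(X)
  reselect <- !is.null(X_full) && !is.null(select_fun)
  if (is.null(model)) model <- fit_scca(X, Y, n_pairs, c_x, c_y)
  r_obs <- vapply(model$pairs, `[[`, numeric(1), "r")
  if (is.null(perms)) {
    perms <- with_seed_if(seed, replicate(n_perm, sample.int(n), simplify = FALSE))
  }
  n_perm <- length(perms)
  if (n_perm < 1) abort("need at least one permutation")
  perm_r <- matrix(NA_real_, n_perm, n_pairs)
  for (b in seq_len(n_perm)) {
    Yb <- Y[perms[[b]], , drop = FALSE]
    Xb <- if (reselect) {
      X_full[, select_fun(X_full, Yb), drop = FALSE]
    } else X
    mb <- fit_scca(Xb, Yb, n_pairs, c_x, c_y)
    perm_r[b, ] <- vapply(mb$pairs, `[[`, numeric(1), "r")
  }
  p <- vapply(seq_len(n_pairs), function(k) {
    (1 + sum(perm_r[, k] >= r_obs[k])) / (1 + n_perm)
  }, numeric(1))
  out <- tibble::tibble(pair = seq_len(n_pairs), r = r_obs, p = p,
                        q = fdr_adjust(p), n_perm = n_perm)
  attr(out, "perm_r") <- perm_r
  class(out) <- c("scca_perm", class(out))
  out
}

#' Benjamini-Hochberg false discovery rate adjustment
#'
#' Step-up adjusted p-values (q-values), clipped at 1. Thin wrapper over
#' the standard BH procedure so the adjustment used across the package is
#' named and testable in one place.
#'
#' @param p_values Numeric vector of p-values in (0, 1].
#' @return Numeric vector of q-values, same length and order.
#' @export
#' @examples
#' fdr_adjust(c(0.01, 0.02, 0.04, 0.8))
fdr_adjust <- function(p_values) {
  stopifnot(is.numeric(p_values), all(p_values > 0 & p_values <= 1))
  stats::p.adjust(p_values, method = "BH")
}

#' Bootstrap stability of a sparse CCA model
#'
#' Refits the model on subject resamples drawn with replacement, aligns
#' each resampled pair's sign to the original fit (flip when the dot
#' product of the resampled and original `u` is negative), and records
#' per-pair canonical correlation mean/SE plus, for every X-side feature,
#' the frequency with which it is selected (nonzero) with the same sign
#' as in the original fit, and a percentile interval for its weight.
#' Features whose same-sign selection frequency reaches
#' `stability_threshold` form the stable set of "reliable" features.
#'
#' @param X,Y Subjects-by-features matrices (original scale).
#' @param n_pairs,c_x,c_y Model specification passed to [fit_scca()].
#' @param n_boot Number of bootstrap resamples (default 1000).
#' @param stability_threshold Same-sign selection frequency required for a
#'   feature to count as stable (default 0.9).
#' @param seed Integer seed.
#' @param model Optional pre-fitted `scca` model on `(X, Y)`.
#' @param conf Confidence level of the weight percentile intervals.
#' @return List of class `scca_boot` with `pair_stats` (tibble: pair,
#'   r_mean, r_se), `feature_stats` (tibble: pair, feature, original
#'   weight, selection frequency, weight CI, stable flag),
#'   `stable_features` (per-pair list of stable feature names),
#'   `n_boot`, and `n_redrawn` (degenerate resamples replaced).
#' @export
bootstrap_stability <- function(X, Y, n_pairs = min(ncol(Y), 10),
                                c_x = 1, c_y = 1, n_boot = 1000,
                                stability_threshold = 0.9, seed = 1,
                                model = NULL, conf = 0.95) {
  X <- as.matrix(X); Y <- as.matrix(Y)
  n <- nrow(X)
  if (n_boot < 2) abort("n_boot must be at least 2")
  if (is.null(model)) model <- fit_scca(X, Y, n_pairs, c_x, c_y)
  p <- ncol(X)
  u0 <- matrix(unlist(lapply(model$pairs, `[[`, "u")), nrow = p)
  r_b <- matrix(NA_real_, n_boot, n_pairs)
  u_b <- array(NA_real_, c(n_boot, p, n_pairs))
  n_redrawn <- 0
  with_seed_if(seed, {
    for (b in seq_len(n_boot)) {
      for (attempt in 1:50) {
        idx <- sample.int(n, replace = TRUE)
        ok <- all(col_sds(X[idx, , drop = FALSE]) > 0) &&
          all(col_sds(Y[idx, , drop = FALSE]) > 0)
        if (ok) break
        n_redrawn <- n_redrawn + 1
      }
      if (!ok) abort("could not draw a non-degenerate bootstrap resample")
      mb <- fit_scca(X[idx, , drop = FALSE], Y[idx, , drop = FALSE],
                     n_pairs, c_x, c_y)
      for (k in seq_len(n_pairs)) {
        uk <- mb$pairs[[k]]$u
        vk <- mb$pairs[[k]]$v
        if (sum(uk * u0[, k]) < 0) { uk <- -uk; vk <- -vk }
        u_b[b, , k] <- uk
        r_b[b, k] <- mb$pairs[[k]]$r
      }
    }
  })
  alpha <- (1 - conf) / 2
  feature_stats <- purrr::map_dfr(seq_len(n_pairs), function(k) {
    s0 <- sign(u0[, k])
    ub_k <- matrix(u_b[, , k], nrow = n_boot)
    freq <- colMeans(sign(ub_k) == matrix(s0, n_boot, p, byrow = TRUE) &
                       ub_k != 0)
    ci <- apply(ub_k, 2, stats::quantile, probs = c(alpha, 1 - alpha))
    tibble::tibble(pair = k, feature = model$x_names,
                   weight = u0[, k], selection_freq = freq,
                   ci_lo = ci[1, ], ci_hi = ci[2, ],
                   stable = freq >= stability_threshold)
  })
  pair_stats <- tibble::tibble(
    pair = seq_len(n_pairs),
    r_mean = colMeans(r_b),
    r_se = apply(r_b, 2, stats::sd))
  structure(list(
    pair_stats = pair_stats,
    feature_stats = feature_stats,
    stable_features = lapply(seq_len(n_pairs), function(k) {
      feature_stats$feature[feature_stats$pair == k & feature_stats$stable]
    }),
    n_boot = n_boot,
    stability_threshold = stability_threshold,
    n_redrawn = n_redrawn), class = "scca_boot")
}

#' Structure loadings of original variables on the canonical variates
#'
#' For each canonical pair, the Pearson correlation between every original
#' variable and its own side's canonical variate (X variables against
#' `X u`, Y variables against `Y v`). These structure loadings — not the
#' sparse weights — are what gets aggregated to the network level.
#' Zero-variance variables get loading 0 with a warning.
#'
#' @param X_orig,Y_orig Subjects-by-variables matrices on the original
#'   scale (typically the pre-selection feature matrix and the clinical
#'   items).
#' @param model Fitted `scca` object whose variates are computable from
#'   the columns of `X_orig`/`Y_orig` used at fit time; variates are
#'   recomputed from the model's own standardization.
#' @param X_fit,Y_fit Matrices the model was fitted on, defaulting to
#'   `X_orig`/`Y_orig`; pass the selected-feature matrix here when
#'   `X_orig` is a wider matrix whose loadings you want.
#' @return Tibble with `side` ("x"/"y"), `pair`, `variable`, `loading`.
#' @export
structure_loadings <- function(X_orig, Y_orig, model,
                               X_fit = X_orig, Y_fit = Y_orig) {
  stopifnot(inherits(model, "scca"))
  sc <- scca_scores(model, X = X_fit, Y = Y_fit)
  load_side <- function(M, scores, side) {
    M <- as.matrix(M)
    sds <- col_sds(M)
    if (any(sds == 0)) warn("zero-variance variable(s): loading set to 0")
    purrr::map_dfr(seq_len(ncol(scores)), function(k) {
      l <- rep(0, ncol(M))
      ok <- sds > 0 & stats::sd(scores[, k]) > 0
      if (any(ok)) l[ok] <- drop(stats::cor(M[, ok, drop = FALSE], scores[, k]))
      tibble::tibble(side = side, pair = k,
                     variable = colnames(M) %||% paste0(side, seq_len(ncol(M))),
                     loading = l)
    })
  }
  dplyr::bind_rows(load_side(X_orig, sc$x_scores, "x"),
                   load_side(Y_orig, sc$y_scores, "y"))
}

#' Aggregate edge loadings to network blocks
#'
#' Sums the absolute values of per-edge loadings within each network
#' block (within-network and between-network pairs; 55 blocks for a
#' 10-network atlas). Edges not present in `loadings` contribute 0, and
#' every block appears in the output even when its sum is 0 — the shape
#' expected by block heatmaps.
#'
#' @param loadings Data frame with columns `edge_id` and `loading` (one
#'   canonical pair at a time), or additionally `pair` to aggregate
#'   several pairs in one call.
#' @param edge_index Edge table from [edge_index()].
#' @return Tibble with `pair` (if supplied), `block`, `within`,
#'   `sum_abs_loading`.
#' @export
network_block_loadings <- function(loadings, edge_index) {
  stopifnot(all(c("edge_id", "loading") %in% names(loadings)))
  bad <- setdiff(loadings$edge_id, edge_index$edge_id)
  if (length(bad)) {
    abort(paste0("unknown edge id(s): ", paste(head(bad, 5), collapse = ", ")))
  }
  blocks <- dplyr::distinct(edge_index, .data$block, .data$within)
  by_pair <- "pair" %in% names(loadings)
  df <- dplyr::left_join(loadings,
                         dplyr::select(edge_index, "edge_id", "block"),
                         by = "edge_id")
  grp <- if (by_pair) c("pair", "block") else "block"
  sums <- dplyr::summarise(dplyr::group_by(df, dplyr::across(dplyr::all_of(grp))),
                           sum_abs_loading = sum(abs(.data$loading)),
                           .groups = "drop")
  if (by_pair) {
    full <- tidyr::expand_grid(pair = sort(unique(loadings$pair)),
                               block = blocks$block)
    out <- dplyr::left_join(full, sums, by = c("pair", "block"))
  } else {
    out <- dplyr::left_join(dplyr::select(blocks, "block"), sums, by = "block")
  }
  out$sum_abs_loading[is.na(out$sum_abs_loading)] <- 0
  out <- dplyr::left_join(out, blocks, by = "block")
  dplyr::arrange(out, dplyr::across(dplyr::any_of(c("pair", "block"))))
}
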