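#' Fit one sparse canonical pair by penalized matrix decomposition
#'
#' Finds sparse weight vectors `u` (length p) and `v` (length q) that
#' maximize `cor(X u, Y v)` subject to unit L2 norms and L1 budgets
#' `||u||_1 <= c_x * sqrt(p)` and `||v||_1 <= c_y * sqrt(q)` — the
#' rank-one penalized matrix decomposition of the cross-product matrix
#' `X'Y`, i.e. diagonal-penalized sparse CCA. The solver alternates
#' soft-thresholded updates
#' `u <- normalize(S(X'Y v, lambda_u))`, `v <- normalize(S(Y'X u, lambda_v))`,
#' with each threshold found by bisection so the L1 budget holds, starting
#' from the leading right singular vector of `X'Y` (deterministic).
#' The sign convention flips `v` (and hence the pair) so the canonical
#' correlation is non-negative.
#'
#' @param X,Y Column-standardized numeric matrices (subjects by p, q);
#'   [fit_scca()] standardizes for you.
#' @param c_x,c_y Sparsity budget scales in (0, 1]; 1 is effectively
#'   unpenalized when `sqrt(p) >= ||u||_1` at the unit L2 norm.
#' @param max_iter Maximum alternating iterations (default 200).
#' @param tol Convergence threshold on the max absolute change of the
#'   weight vectors (default 1e-6).
#' @return List with `u`, `v`, `r` (canonical correlation, >= 0),
#'   `iterations`, `converged`.
#' @export
fit_pmd_pair <- function(X, Y, c_x = 1, c_y = 1, max_iter = 200, tol = 1e-6) {
  X <- as.matrix(X); Y <- as.matrix(Y)
  n <- nrow(X)
  if (n != nrow(Y)) abort("X and Y disagree on subject count")
  if (n < 3) abort("need at least 3 subjects")
  if (!(c_x > 0 && c_x <= 1 && c_y > 0 && c_y <= 1)) {
    abort("sparsity budgets must lie in (0, 1]")
  }
  if (any(col_sds(X) == 0) || any(col_sds(Y) == 0)) {
    abort("zero-variance column in X or Y")
  }
  fit <- pmd_core(X, Y, c_x, c_y, max_iter, tol)
  if (!fit$converged) {
    warn(sprintf("PMD did not converge in %d iterations", max_iter))
  }
  fit
}

# the PMD solver proper; unlike fit_pmd_pair() it tolerates all-zero
# columns, which arise legitimately in deflated matrices (a sparse u
# annihilates its own columns exactly)
pmd_core <- function(X, Y, c_x, c_y, max_iter = 200, tol = 1e-6) {
  p <- ncol(X); q <- ncol(Y)
  # L1 budget: a unit-L2 vector always has L1 >= 1, and sqrt(dim) is the
  # unpenalized maximum, so the feasible budget range is [1, sqrt(dim)]
  bud_u <- min(max(c_x * sqrt(p), 1), sqrt(p))
  bud_v <- min(max(c_y * sqrt(q), 1), sqrt(q))
  Z <- crossprod(X, Y)
  if (all(Z == 0)) {
    # fully deflated block: no structure left to extract
    return(list(u = numeric(p), v = numeric(q), r = 0,
                iterations = 0L, converged = TRUE))
  }
  sv <- svd(Z, nu = 1, nv = 1)
  v <- drop(sv$v)
  # deterministic sign for the initializer
  if (v[which.max(abs(v))] < 0) v <- -v
  u <- numeric(p)
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    u_new <- l1_projected_unit(drop(Z %*% v), bud_u)
    v_new <- l1_projected_unit(drop(crossprod(Z, u_new)), bud_v)
    delta <- max(max(abs(u_new - u)), max(abs(v_new - v)))
    u <- u_new; v <- v_new
    if (delta < tol) { converged <- TRUE; break }
  }
  xs <- drop(X %*% u); ys <- drop(Y %*% v)
  r <- if (stats::sd(xs) == 0 || stats::sd(ys) == 0) 0 else stats::cor(xs, ys)
  if (r < 0) { v <- -v; r <- -r }
  list(u = u, v = v, r = r, iterations = it, converged = converged)
}

# soft-threshold `a`, L2-normalize, with the threshold chosen by bisection
# so the L1 norm of the normalized vector is within the budget; the
# search runs on |a| only (the norms do not depend on the signs)
l1_projected_unit <- function(a, budget) {
  aa <- abs(a)
  m <- max(aa)
  if (m == 0) return(a)
  if (sum(aa) / sqrt(sum(aa * aa)) <= budget) return(a / sqrt(sum(aa * aa)))
  lo <- 0; hi <- m
  tol <- 1e-9 * max(1, m)
  for (iter in 1:30) {
    lam <- (lo + hi) / 2
    t <- aa - lam
    t[t < 0] <- 0
    l1 <- sum(t)
    # as lam -> max|a| the ratio tends to 1, always within the budget
    ratio <- if (l1 == 0) 1 else l1 / sqrt(sum(t * t))
    if (ratio > budget) lo <- lam else hi <- lam
    if (hi - lo < tol) break
  }
  t <- aa - hi
  t[t < 0] <- 0
  x <- sign(a) * t
  x / sqrt(sum(x * x))
}

#' Rank-one deflation for successive canonical pairs
#'
#' Removes a fitted canonical pair from the data so the next pair can be
#' extracted: `X' = X - (X u) u'`, `Y' = Y - (Y v) v'`. The deflated
#' matrices are not re-standardized.
#'
#' @param X,Y Matrices as passed to [fit_pmd_pair()].
#' @param u,v Unit-norm weight vectors of the fitted pair.
#' @return List with deflated `X` and `Y`.
#' @export
deflate <- function(X, Y, u, v) {
  X <- as.matrix(X); Y <- as.matrix(Y)
  list(X = X - tcrossprod(drop(X %*% u), u),
       Y = Y - tcrossprod(drop(Y %*% v), v))
}

#' Fit a multi-pair sparse CCA model
#'
#' Standardizes both blocks, then repeatedly fits a sparse canonical pair
#' with [fit_pmd_pair()] and deflates, recording each pair in extraction
#' order. The returned object carries the standardization constants so
#' canonical variates can be reproduced on the original data, and supports
#' [generics::tidy()] / [generics::glance()] and `autoplot()`.
#'
#' @param X Subjects-by-features matrix (e.g. selected dFC features).
#' @param Y Subjects-by-items matrix (behavioral or cognitive block).
#' @param n_pairs Number of canonical pairs to extract; default
#'   `min(ncol(Y), 10)`.
#' @param c_x,c_y Sparsity budget scales in (0, 1] (see [fit_pmd_pair()]).
#' @param max_iter,tol Solver controls.
#' @return An object of class `scca` with elements `pairs` (list of
#'   u/v/r), `chosen_sparsity`, `standardization`, `n_pairs`, and the
#'   dimnames of both blocks.
#' @export
fit_scca <- function(X, Y, n_pairs = min(ncol(Y), 10), c_x = 1, c_y = 1,
                     max_iter = 200, tol = 1e-6) {
  stopifnot(is_count(n_pairs))
  sx <- standardize_cols(X)
  sy <- standardize_cols(Y)
  Xd <- sx$Z; Yd <- sy$Z
  if (!(c_x > 0 && c_x <= 1 && c_y > 0 && c_y <= 1)) {
    abort("sparsity budgets must lie in (0, 1]")
  }
  pairs <- vector("list", n_pairs)
  for (k in seq_len(n_pairs)) {
    fit <- pmd_core(Xd, Yd, c_x, c_y, max_iter, tol)
    pairs[[k]] <- fit
    if (k < n_pairs) {
      dd <- deflate(Xd, Yd, fit$u, fit$v)
      Xd <- dd$X; Yd <- dd$Y
    }
  }
  structure(
    list(pairs = pairs,
         chosen_sparsity = c(c_x = c_x, c_y = c_y),
         standardization = list(x = sx[c("mean", "sd")], y = sy[c("mean", "sd")]),
         n_pairs = n_pairs,
         x_names = colnames(X) %||% paste0("x", seq_len(ncol(X))),
         y_names = colnames(Y) %||% paste0("y", seq_len(ncol(Y)))),
    class = "scca")
}

#' Canonical variate scores of an scca model on (new) data
#'
#' @param model An `scca` object.
#' @param X,Y Data on the original (unstandardized) scale; either may be
#'   `NULL` to skip that side.
#' @return List with `x_scores` and/or `y_scores`, subjects by pairs.
#' @export
scca_scores <- function(model, X = NULL, Y = NULL) {
  stopifnot(inherits(model, "scca"))
  out <- list()
  if (!is.null(X)) {
    Z <- apply_standardization(X, model$standardization$x)
    out$x_scores <- sapply(model$pairs, function(p) drop(Z %*% p$u))
    colnames(out$x_scores) <- paste0("pair", seq_len(model$n_pairs))
  }
  if (!is.null(Y)) {
    Z <- apply_standardization(Y, model$standardization$y)
    out$y_scores <- sapply(model$pairs, function(p) drop(Z %*% p$v))
    colnames(out$y_scores) <- paste0("pair", seq_len(model$n_pairs))
  }
  out
}

#' @export
print.scca <- function(x, ...) {
  cat("Sparse CCA model (penalized matrix decomposition)\n")
  cat(sprintf("  features: %d (X) x %d (Y); pairs: %d; sparsity c_x=%.2f c_y=%.2f\n",
              length(x$pairs[[1]]$u), length(x$pairs[[1]]$v),
              x$n_pairs, x$chosen_sparsity["c_x"], x$chosen_sparsity["c_y"]))
  r <- vapply(x$pairs, `[[`, numeric(1), "r")
  cat("  canonical correlations:", paste(sprintf("%.3f", r), collapse = ", "), "\n")
  invisible(x)
}

#' Tune the sparsity budgets by cross-validated canonical correlation
#'
#' Grid search over candidate `(c_x, c_y)` budget pairs, scoring each cell
#' by the first-pair canonical correlation estimated out of sample with
#' k-fold cross-validation on subjects (fit on the training folds,
#' correlate the held-out canonical scores, average over folds). Ties are
#' broken toward the sparser cell (smaller `c_x + c_y`, then smaller
#' `c_x`).
#'
#' @param X,Y Subjects-by-features matrices (original scale).
#' @param c_x_grid,c_y_grid Candidate budget scales in (0, 1].
#' @param n_folds Cross-validation folds (default 5; reduced with a
#'   warning when there are fewer than `2 * n_folds` subjects).
#' @param seed Integer seed for the fold split.
#' @return List with `c_x`, `c_y`, and the full `grid` tibble of
#'   cross-validated correlations.
#' @export
tune_sparsity <- function(X, Y, c_x_grid = seq(0.1, 1, by = 0.1),
                          c_y_grid = seq(0.1, 1, by = 0.1),
                          n_folds = 5, seed = 1) {
  X <- as.matrix(X); Y <- as.matrix(Y)
  n <- nrow(X)
  if (n < 2 * n_folds) {
    n_folds <- max(2, floor(n / 2))
    warn(sprintf("too few subjects for requested folds; using %d folds", n_folds))
  }
  folds <- with_seed_if(seed, sample(rep_len(seq_len(n_folds), n)))
  grid <- tidyr::expand_grid(c_x = c_x_grid, c_y = c_y_grid)
  cv_r <- purrr::pmap_dbl(grid, function(c_x, c_y) {
    rs <- vapply(seq_len(n_folds), function(f) {
      tr <- folds != f
      sx <- standardize_cols(X[tr, , drop = FALSE])
      sy <- standardize_cols(Y[tr, , drop = FALSE])
      fit <- fit_pmd_pair(sx$Z, sy$Z, c_x, c_y)
      xs <- drop(apply_standardization(X[!tr, , drop = FALSE], sx) %*% fit$u)
      ys <- drop(apply_standardization(Y[!tr, , drop = FALSE], sy) %*% fit$v)
      if (stats::sd(xs) == 0 || stats::sd(ys) == 0) 0 else stats::cor(xs, ys)
    }, numeric(1))
    mean(rs)
  })
  grid$cv_r <- cv_r
  ord <- order(-grid$cv_r, grid$c_x + grid$c_y, grid$c_x)
  best <- grid[ord[1], ]
  list(c_x = best$c_x, c_y = best$c_y, grid = grid)
}
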