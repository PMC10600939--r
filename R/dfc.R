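#' Sliding-window functional connectivity
#'
#' Slides a rectangular window of `width_tr` samples with step `step_tr`
#' along a parcellated time series and computes the Pearson correlation of
#' every ROI pair within each window. Windows are ordered by start time;
#' the window count is `floor((n_tr - width_tr) / step_tr) + 1`.
#'
#' @param ts Numeric matrix, time points (rows, TR units) by ROIs (columns).
#' @param width_tr Window width in TRs (default 22, i.e. 44 s at TR = 2 s).
#' @param step_tr Step between window starts in TRs (default 1).
#' @param subject_id Optional label used in error messages.
#' @return Matrix of windowed correlations, windows by edges; edges in
#'   row-major upper-triangle order (see [edge_index()]).
#' @export
windowed_connectivity <- function(ts, width_tr = 22, step_tr = 1,
                                  subject_id = NULL) {
  ts <- as.matrix(ts)
  n_tr <- nrow(ts); n_roi <- ncol(ts)
  stopifnot(is_count(width_tr), is_count(step_tr))
  if (anyNA(ts)) abort("time series contains missing values")
  if (width_tr > n_tr) {
    abort(sprintf("window width (%d TR) exceeds series length (%d TR)",
                  width_tr, n_tr))
  }
  n_win <- floor((n_tr - width_tr) / step_tr) + 1
  # row-major upper triangle of a symmetric matrix = column-major lower
  # triangle, which is the native order of `[lower.tri(.)]`
  lt <- lower.tri(diag(n_roi))
  out <- matrix(NA_real_, n_win, sum(lt))
  for (w in seq_len(n_win)) {
    rows <- ((w - 1) * step_tr + 1):((w - 1) * step_tr + width_tr)
    seg <- ts[rows, , drop = FALSE]
    sds <- col_sds(seg)
    if (any(sds == 0)) {
      abort(sprintf(
        "zero-variance ROI %d in window %d%s",
        which(sds == 0)[1], w,
        if (is.null(subject_id)) "" else paste0(" (subject ", subject_id, ")")))
    }
    cm <- stats::cor(seg)
    out[w, ] <- cm[lt]
  }
  out
}

#' Edgewise variability of windowed connectivity
#'
#' Summarizes a windows-by-edges matrix of windowed correlations as the
#' per-edge sample standard deviation (denominator n - 1) across windows —
#' the dynamic functional connectivity (dFC) variability measure. Higher
#' values mean more temporal fluctuation of that edge's connectivity.
#'
#' @param windows Windows-by-edges matrix from [windowed_connectivity()].
#' @param fisher_z If `TRUE`, apply the Fisher z transform (atanh) to the
#'   windowed correlations before taking the SD. Default `FALSE`: the SD is
#'   taken on the raw correlation scale.
#' @return Numeric vector of per-edge SDs (length = number of edges).
#' @export
dfc_sd <- function(windows, fisher_z = FALSE) {
  windows <- as.matrix(windows)
  if (nrow(windows) < 2) abort("need at least 2 windows to compute dFC variability")
  if (isTRUE(fisher_z)) {
    windows <- atanh(pmin(pmax(windows, -1 + 1e-12), 1 - 1e-12))
  }
  col_sds(windows)
}

#' Sliding-window dFC variability of one subject
#'
#' Convenience wrapper chaining [windowed_connectivity()] and [dfc_sd()].
#'
#' @inheritParams windowed_connectivity
#' @inheritParams dfc_sd
#' @return Numeric vector of per-edge dFC variability values with
#'   attributes `method` (`"sliding_window"`) and `n_windows`.
#' @export
dfc_sliding <- function(ts, width_tr = 22, step_tr = 1, fisher_z = FALSE,
                        subject_id = NULL) {
  w <- windowed_connectivity(ts, width_tr, step_tr, subject_id)
  out <- dfc_sd(w, fisher_z = fisher_z)
  attr(out, "method") <- "sliding_window"
  attr(out, "n_windows") <- nrow(w)
  out
}

#' Flexible least squares dFC variability
#'
#' For every edge (i < j) the coupling between the two standardized ROI
#' series is modeled as a time-varying regression coefficient
#' \eqn{\beta_t}: \eqn{y_t = \beta_t x_t + e_t}, estimated by flexible
#' least squares, i.e. minimizing
#' \eqn{\sum_t (y_t - \beta_t x_t)^2 + \mu \sum_t (\beta_{t+1}-\beta_t)^2}.
#' The normal equations are tridiagonal and solved exactly (Thomas
#' algorithm, vectorized across edges). The dFC value of an edge is the
#' sample SD of its coefficient path over time. With large \eqn{\mu} the
#' path collapses to the static OLS slope (SD tends to 0); with
#' \eqn{\mu = 0} the fit is pointwise \eqn{\beta_t = y_t / x_t}.
#'
#' @param ts Numeric matrix, time points by ROIs.
#' @param mu Smoothness penalty on squared coefficient increments
#'   (unitless, >= 0; default 100).
#' @return Numeric vector of per-edge SDs of the coefficient paths, with
#'   attributes `method` (`"fls"`) and `mu`.
#' @export
fls_dfc <- function(ts, mu = 100) {
  ts <- as.matrix(ts)
  stopifnot(is.numeric(mu), length(mu) == 1, mu >= 0)
  n_tr <- nrow(ts); n_roi <- ncol(ts)
  if (n_tr < 2) abort("need at least 2 time points")
  sds <- col_sds(ts)
  if (any(sds == 0)) {
    abort(sprintf("zero-variance ROI %d: singular FLS system", which(sds == 0)[1]))
  }
  Z <- scale(ts)  # both sides standardized
  i <- rep(seq_len(n_roi - 1), times = (n_roi - 1):1)
  j <- unlist(lapply(seq_len(n_roi - 1), function(k) (k + 1):n_roi),
              use.names = FALSE)
  X <- t(Z[, i, drop = FALSE])  # edges x time, regressor
  Y <- t(Z[, j, drop = FALSE])  # edges x time, response
  B <- fls_paths(X, Y, mu)
  out <- apply(B, 1, stats::sd)
  attr(out, "method") <- "fls"
  attr(out, "mu") <- mu
  out
}

# exact FLS coefficient paths for many edges at once.
# X, Y: edges x time. Solves (diag(x_t^2) + mu * L) beta = x * y per edge,
# L the second-difference (random-walk) penalty matrix, via a Thomas sweep
# vectorized over edges.
fls_paths <- function(X, Y, mu) {
  T_ <- ncol(X)
  if (mu == 0) {
    B <- ifelse(X != 0, Y / X, 0)
    return(matrix(B, nrow = nrow(X)))
  }
  d <- c(1, rep(2, T_ - 2), 1)            # diag of L
  A <- X^2 + matrix(mu * d, nrow(X), T_, byrow = TRUE)  # main diagonal
  off <- -mu                               # constant sub/super diagonal
  R <- X * Y                               # right-hand side
  # forward elimination
  cp <- matrix(0, nrow(X), T_ - 1)         # modified superdiagonal
  dp <- matrix(0, nrow(X), T_)             # modified rhs
  denom <- A[, 1]
  cp[, 1] <- off / denom
  dp[, 1] <- R[, 1] / denom
  for (t in 2:T_) {
    denom <- A[, t] - off * cp[, t - 1]
    if (t < T_) cp[, t] <- off / denom
    dp[, t] <- (R[, t] - off * dp[, t - 1]) / denom
  }
  # back substitution
  B <- matrix(0, nrow(X), T_)
  B[, T_] <- dp[, T_]
  for (t in (T_ - 1):1) {
    B[, t] <- dp[, t] - cp[, t] * B[, t + 1]
  }
  B
}

#' Stack per-subject dFC vectors into a subjects-by-edges matrix
#'
#' Applies the chosen dFC estimator to every subject of a cohort and
#' returns the stacked feature matrix that enters confound residualization
#' and sparse CCA.
#'
#' @param timeseries Named list of per-subject time-series matrices
#'   (time points by ROIs), as in a [simulate_cohort()] bundle.
#' @param method `"sliding_window"` (default) or `"fls"`.
#' @param width_tr,step_tr,fisher_z Sliding-window parameters, see
#'   [dfc_sliding()].
#' @param mu FLS smoothness penalty, see [fls_dfc()].
#' @return Numeric matrix subjects x edges; rownames are subject ids.
#' @export
compute_dfc <- function(timeseries, method = c("sliding_window", "fls"),
                        width_tr = 22, step_tr = 1, fisher_z = FALSE,
                        mu = 100) {
  method <- match.arg(method)
  stopifnot(is.list(timeseries), length(timeseries) >= 1)
  rows <- lapply(seq_along(timeseries), function(s) {
    ts <- timeseries[[s]]
    if (method == "sliding_window") {
      dfc_sliding(ts, width_tr, step_tr, fisher_z,
                  subject_id = names(timeseries)[s])
    } else {
      fls_dfc(ts, mu = mu)
    }
  })
  out <- do.call(rbind, rows)
  rownames(out) <- names(timeseries)
  colnames(out) <- paste0("edge_", seq_len(ncol(out)))
  out
}
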