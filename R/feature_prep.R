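#' Residualize a feature matrix on confound covariates
#'
#' Replaces each feature column by its residual from an ordinary least
#' squares fit on an intercept plus the named covariates. Residual columns
#' are exactly uncorrelated with every covariate used. Typical use:
#' regress age, sex and mean framewise displacement out of the dFC
#' features, and age and sex out of the clinical features, before sparse
#' CCA.
#'
#' @param X Numeric matrix or data frame, subjects by features.
#' @param covariates Data frame of per-subject covariates (same row order
#'   as `X`); sex should be coded 0/1.
#' @param which Character vector naming the covariate columns to remove.
#' @return Numeric matrix of residuals, same dimnames as `X`, with
#'   attribute `residualized_on` recording the covariates used.
#' @export
residualize <- function(X, covariates, which) {
  X <- as.matrix(X)
  stopifnot(is.data.frame(covariates) || is.matrix(covariates))
  missing_cov <- setdiff(which, colnames(covariates))
  if (length(missing_cov)) {
    abort(paste0("covariate(s) not found: ", paste(missing_cov, collapse = ", ")))
  }
  C <- as.matrix(as.data.frame(covariates)[, which, drop = FALSE])
  storage.mode(C) <- "double"
  if (anyNA(C)) abort("covariates contain missing values")
  if (nrow(C) != nrow(X)) abort("covariates and X disagree on subject count")
  M <- cbind(`(Intercept)` = 1, C)
  qr_m <- qr(M)
  if (qr_m$rank < ncol(M)) abort("rank-deficient covariate matrix")
  R <- qr.resid(qr_m, X)
  dimnames(R) <- dimnames(X)
  attr(R, "residualized_on") <- which
  R
}

#' Relief feature weights (ReliefF / RReliefF)
#'
#' Estimates the relevance of each feature for a target by the Relief
#' family of nearest-neighbour algorithms. Features are first rescaled to
#' the unit interval; neighbours are found by Manhattan distance in that
#' rescaled space and every subject serves as an instance.
#'
#' * `mode = "classification"`: ReliefF. For each instance, the `k`
#'   nearest hits (same class) decrease a feature's weight by its mean
#'   value difference and the `k` nearest misses of each other class
#'   increase it, miss classes weighted by their prior probability.
#' * `mode = "regression"`: RReliefF. Hit/miss is replaced by the
#'   probabilistic formulation that accumulates, over the `k` nearest
#'   neighbours with rank-decayed influence, the probabilities of the
#'   target differing, of each feature differing, and of both, and
#'   combines them into `W(f) = P(df|dt)P(dt)/P(dt) - ...` (the standard
#'   RReliefF update).
#'
#' A constant feature always has weight exactly 0.
#'
#' @param X Numeric matrix or data frame, subjects by features.
#' @param target Per-subject class labels (classification) or numeric
#'   scores (regression).
#' @param k_neighbors Number of neighbours (default 10).
#' @param mode `"regression"` (default) or `"classification"`.
#' @param sigma Rank-decay scale of the neighbour influence weights in
#'   regression mode; neighbour at rank r gets weight
#'   `exp(-(r / sigma)^2)`, normalized per instance. Default
#'   `k_neighbors` (mild decay).
#' @return Named numeric vector of feature weights.
#' @export
relief_weights <- function(X, target, k_neighbors = 10,
                           mode = c("regression", "classification"),
                           sigma = k_neighbors) {
  mode <- match.arg(mode)
  X <- as.matrix(X)
  n <- nrow(X); p <- ncol(X)
  stopifnot(length(target) == n, is_count(k_neighbors))
  if (anyNA(X) || anyNA(target)) abort("missing values in X or target")
  rng <- apply(X, 2, function(v) diff(range(v)))
  keep <- rng > 0
  Z <- X
  Z[, keep] <- sweep(sweep(X[, keep, drop = FALSE], 2,
                           apply(X[, keep, drop = FALSE], 2, min), "-"),
                     2, rng[keep], "/")
  Z[, !keep] <- 0
  D <- as.matrix(stats::dist(Z, method = "manhattan"))
  diag(D) <- Inf
  w <- numeric(p)

  if (mode == "classification") {
    cls <- as.factor(target)
    tab <- table(cls)
    if (k_neighbors >= min(tab)) {
      abort(sprintf("k_neighbors (%d) must be smaller than the smallest class (%d)",
                    k_neighbors, min(tab)))
    }
    prior <- as.numeric(tab) / n
    names(prior) <- names(tab)
    for (i in seq_len(n)) {
      ci <- as.character(cls[i])
      hits <- which(cls == cls[i])
      hits <- hits[order(D[i, hits])][seq_len(k_neighbors)]
      dh <- colMeans(abs(Z[hits, , drop = FALSE] -
                           matrix(Z[i, ], k_neighbors, p, byrow = TRUE)))
      w <- w - dh / n
      for (cm in setdiff(levels(cls), ci)) {
        miss <- which(cls == cm)
        miss <- miss[order(D[i, miss])][seq_len(k_neighbors)]
        dm <- colMeans(abs(Z[miss, , drop = FALSE] -
                             matrix(Z[i, ], k_neighbors, p, byrow = TRUE)))
        w <- w + (prior[cm] / (1 - prior[ci])) * dm / n
      }
    }
  } else {
    tau <- as.numeric(target)
    tr <- diff(range(tau))
    if (tr == 0) return(stats::setNames(numeric(p), colnames(X)))
    dt_all <- abs(outer(tau, tau, "-")) / tr
    k <- min(k_neighbors, n - 1)
    infl <- exp(-(seq_len(k) / sigma)^2)
    infl <- infl / sum(infl)
    n_dc <- 0
    n_da <- numeric(p)
    n_dcda <- numeric(p)
    for (i in seq_len(n)) {
      nb <- order(D[i, ])[seq_len(k)]
      da <- abs(Z[nb, , drop = FALSE] - matrix(Z[i, ], k, p, byrow = TRUE))
      dt <- dt_all[i, nb]
      n_dc <- n_dc + sum(infl * dt)
      n_da <- n_da + colSums(infl * da)
      n_dcda <- n_dcda + colSums((infl * dt) * da)
    }
    if (n_dc == 0 || n_dc == n) return(stats::setNames(numeric(p), colnames(X)))
    w <- n_dcda / n_dc - (n_da - n_dcda) / (n - n_dc)
  }
  w[!keep] <- 0
  stats::setNames(w, colnames(X))
}

#' Select the top fraction of features by weight
#'
#' Keeps the `ceiling(fraction * n_features)` features with the highest
#' weights (so the selection is never empty). Ties at the cutoff are
#' broken by ascending feature position, making the selection a
#' deterministic function of the weights.
#'
#' @param weights Numeric vector of feature weights (names optional).
#' @param fraction Proportion of features to keep, in (0, 1]. Default 0.01
#'   (the top 1 percent).
#' @return Integer vector of selected feature positions, in ascending
#'   order; names carried over when `weights` is named.
#' @export
select_top_fraction <- function(weights, fraction = 0.01) {
  stopifnot(is.numeric(weights), length(weights) >= 1)
  if (!(fraction > 0 && fraction <= 1)) abort("fraction must be in (0, 1]")
  m <- ceiling(fraction * length(weights))
  ord <- order(-weights, seq_along(weights))
  sel <- sort(ord[seq_len(m)])
  if (!is.null(names(weights))) names(sel) <- names(weights)[sel]
  sel
}

#' PCA reduction keeping a target explained-variance fraction
#'
#' Projects a feature matrix onto its leading principal components,
#' keeping the smallest number of components whose cumulative explained
#' variance reaches `variance_kept`.
#'
#' @param X Numeric matrix, subjects by features (centered internally).
#' @param variance_kept Proportion of total variance to retain, (0, 1].
#' @return List with `scores` (subjects x components), `loadings`
#'   (features x components), `explained` (per-component proportions) and
#'   `n_components`.
#' @export
pca_reduce <- function(X, variance_kept = 0.9) {
  if (!(variance_kept > 0 && variance_kept <= 1)) {
    abort("variance_kept must be in (0, 1]")
  }
  pc <- stats::prcomp(X, center = TRUE, scale. = FALSE)
  ev <- pc$sdev^2
  prop <- ev / sum(ev)
  k <- which(cumsum(prop) >= variance_kept - 1e-12)[1]
  if (is.na(k)) k <- length(prop)
  list(
    scores = pc$x[, seq_len(k), drop = FALSE],
    loadings = pc$rotation[, seq_len(k), drop = FALSE],
    explained = prop[seq_len(k)],
    n_components = k
  )
}
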