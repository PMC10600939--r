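#' Overlap composites of dFC features shared by two dimensions
#'
#' Given the stable dFC feature sets of a behavior-dimension model and a
#' cognition-dimension model, takes their intersection, splits it by the
#' sign of the cognition-side structure loading, and summarizes each
#' signed set as a per-subject composite: the mean dFC value over the
#' member edges ("positive links" and "negative links"). An empty overlap
#' yields an explicit empty result so downstream mediation can be
#' skipped.
#'
#' @param behavior_features Character vector of stable feature names for
#'   the behavior dimension.
#' @param cognition_features Character vector of stable feature names for
#'   the cognition dimension.
#' @param cognition_loadings Named numeric vector of loadings (names =
#'   feature names) used to sign the overlap edges.
#' @param dfc_matrix Subjects-by-edges dFC matrix whose column names
#'   contain the feature names.
#' @return List of class `overlap_composite`: `positive_links`,
#'   `negative_links` (feature names), `composites` (tibble with
#'   per-subject `positive` and `negative` means, columns absent when the
#'   corresponding set is empty), and `empty` flag.
#' @export
select_overlap_composites <- function(behavior_features, cognition_features,
                                      cognition_loadings, dfc_matrix) {
  overlap <- intersect(behavior_features, cognition_features)
  if (length(overlap) == 0) {
    inform("no overlapping stable dFC features; mediation will be skipped")
    return(structure(list(positive_links = character(0),
                          negative_links = character(0),
                          composites = tibble::tibble(.rows = nrow(dfc_matrix)),
                          empty = TRUE),
                     class = "overlap_composite"))
  }
  missing_l <- setdiff(overlap, names(cognition_loadings))
  if (length(missing_l)) abort("loadings missing for some overlap features")
  pos <- overlap[cognition_loadings[overlap] > 0]
  neg <- overlap[cognition_loadings[overlap] < 0]
  comp <- tibble::tibble(.rows = nrow(dfc_matrix))
  if (length(pos)) comp$positive <- rowMeans(dfc_matrix[, pos, drop = FALSE])
  if (length(neg)) comp$negative <- rowMeans(dfc_matrix[, neg, drop = FALSE])
  structure(list(positive_links = pos, negative_links = neg,
                 composites = comp, empty = FALSE),
            class = "overlap_composite")
}

#' Single-mediator linear mediation with percentile bootstrap CIs
#'
#' Estimates the classical three-regression mediation model with `X` the
#' exposure (a dFC composite), `M` the mediator (cognition dimension
#' score) and `Y` the outcome (behavior dimension score), optionally
#' adjusting for covariates entered as regressors in every model:
#' \itemize{
#'   \item \code{M ~ X + covariates} gives the path \code{a};
#'   \item \code{Y ~ X + M + covariates} gives the direct effect
#'     \code{c_prime} and the path \code{b};
#'   \item \code{Y ~ X + covariates} gives the total effect \code{TE}.
#' }
#' The indirect effect is \code{IE = a * b}; for this linear specification
#' on a common case set \code{TE = c_prime + IE} holds exactly. The proportion
#' mediated is \code{IE / TE} on the point estimates (reported as `NA`
#' when \code{|TE|} is numerically zero). Confidence intervals for all
#' quantities are percentile bootstrap over subjects.
#'
#' @param data Data frame with at least the columns named by `x`, `m`,
#'   `y` and `covariates`.
#' @param x,m,y Column names of exposure, mediator and outcome.
#' @param covariates Character vector of covariate column names (default
#'   `c("age", "sex")`; use `character(0)` for none).
#' @param n_boot Bootstrap resamples (default 5000).
#' @param seed Integer seed.
#' @param conf Confidence level (default 0.95).
#' @return Object of class `mediation_fit` with `estimates` (tibble:
#'   term, estimate, ci_lo, ci_hi, significant) for a, b, c_prime,
#'   indirect, total, prop_mediated, plus `n`, `n_boot`, `conf`,
#'   `covariates`.
#' @export
fit_mediation <- function(data, x = "X", m = "M", y = "Y",
                          covariates = c("age", "sex"),
                          n_boot = 5000, seed = 1, conf = 0.95) {
  stopifnot(is.data.frame(data))
  need <- c(x, m, y, covariates)
  missing_c <- setdiff(need, names(data))
  if (length(missing_c)) {
    abort(paste0("missing column(s): ", paste(missing_c, collapse = ", ")))
  }
  d <- data[stats::complete.cases(data[, need, drop = FALSE]), need, drop = FALSE]
  n <- nrow(d)
  if (n < 10) abort("need at least 10 complete cases")
  Xv <- as.matrix(d[, x]); Mv <- as.matrix(d[, m]); Yv <- as.matrix(d[, y])
  C <- if (length(covariates)) as.matrix(d[, covariates, drop = FALSE]) else NULL

  point <- mediation_paths(Xv, Mv, Yv, C)
  est <- with_seed_if(seed, {
    boot <- matrix(NA_real_, n_boot, 6,
                   dimnames = list(NULL, names(point)))
    for (b in seq_len(n_boot)) {
      idx <- sample.int(n, replace = TRUE)
      boot[b, ] <- mediation_paths(
        Xv[idx, , drop = FALSE], Mv[idx, , drop = FALSE],
        Yv[idx, , drop = FALSE],
        if (is.null(C)) NULL else C[idx, , drop = FALSE])
    }
    boot
  })
  alpha <- (1 - conf) / 2
  ci <- apply(est, 2, stats::quantile, probs = c(alpha, 1 - alpha), na.rm = TRUE)
  terms <- names(point)
  estimates <- tibble::tibble(
    term = terms,
    estimate = unname(point),
    ci_lo = ci[1, terms],
    ci_hi = ci[2, terms],
    significant = ci[1, terms] > 0 | ci[2, terms] < 0)
  # proportion mediated is a ratio of estimates; its CI can be unstable,
  # flag significance only for the effect terms
  estimates$significant[estimates$term == "prop_mediated"] <- NA
  structure(list(estimates = estimates, n = n, n_boot = n_boot,
                 conf = conf, covariates = covariates),
            class = "mediation_fit")
}

# point estimates of the mediation paths via three OLS fits (lm.fit for
# speed inside the bootstrap loop)
mediation_paths <- function(Xv, Mv, Yv, C) {
  ones <- rep(1, nrow(Xv))
  D1 <- cbind(ones, Xv, C)
  D2 <- cbind(ones, Xv, Mv, C)
  a <- stats::lm.fit(D1, drop(Mv))$coefficients[2]
  f2 <- stats::lm.fit(D2, drop(Yv))$coefficients
  c_prime <- f2[2]; b <- f2[3]
  te <- stats::lm.fit(D1, drop(Yv))$coefficients[2]
  ie <- a * b
  pm <- if (abs(te) < 1e-8) NA_real_ else ie / te
  c(a = unname(a), b = unname(b), c_prime = unname(c_prime),
    indirect = unname(ie), total = unname(te), prop_mediated = unname(pm))
}

#' @export
print.mediation_fit <- function(x, ...) {
  cat(sprintf("Mediation model (n = %d, %d bootstrap resamples, %.0f%% CIs)\n",
              x$n, x$n_boot, 100 * x$conf))
  e <- x$estimates
  for (i in seq_len(nrow(e))) {
    cat(sprintf("  %-14s %8.3f  [%6.3f, %6.3f]%s\n", e$term[i], e$estimate[i],
                e$ci_lo[i], e$ci_hi[i],
                ifelse(isTRUE(e$significant[i]), " *", "")))
  }
  invisible(x)
}

#' Correlations between behavior and cognition dimension scores
#'
#' Pearson correlation, with two-sided p-value, of every behavior
#' canonical-dimension score against every cognition dimension score —
#' the screen used to decide which dimension pairing enters mediation.
#'
#' @param behavior_scores Data frame or matrix of subject-level behavior
#'   dimension scores (columns = dimensions).
#' @param cognition_scores Same for cognition dimensions; same subjects
#'   in the same order.
#' @return Tibble with `behavior_dim`, `cognition_dim`, `r`, `p`.
#' @export
dimension_score_correlations <- function(behavior_scores, cognition_scores) {
  B <- as.matrix(behavior_scores); C <- as.matrix(cognition_scores)
  if (nrow(B) != nrow(C)) abort("score tables disagree on subject count")
  bn <- colnames(B) %||% paste0("behavior", seq_len(ncol(B)))
  cn <- colnames(C) %||% paste0("cognition", seq_len(ncol(C)))
  colnames(B) <- bn; colnames(C) <- cn
  tidyr::expand_grid(behavior_dim = bn, cognition_dim = cn) |>
    dplyr::mutate(purrr::map2_dfr(.data$behavior_dim, .data$cognition_dim,
      function(bd, cd) {
        ct <- stats::cor.test(B[, bd], C[, cd])
        tibble::tibble(r = unname(ct$estimate), p = ct$p.value)
      }))
}
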