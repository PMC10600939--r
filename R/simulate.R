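#' Default clinical item loading matrix
#'
#' Items-by-dimensions loading matrix used by [simulate_ground_truth()]:
#' ten parent-rated behavior items (prefix `behav_`) of which six load on
#' the behavior dimension, and eight cognitive test scores (prefix
#' `cog_`) of which seven load on the cognition dimension — timed/error
#' scores with negative sign (worse performance at higher cognitive
#' ability is impossible, so higher latent cognition lowers them), span
#' and fluency scores positive. The remaining items are pure noise.
#'
#' @return Numeric matrix, 18 items x 2 dimensions
#'   (`behavior`, `cognition`), with informative row names.
#' @export
default_clinical_loadings <- function() {
  behav_items <- c("hyperactivity_index", "attention_problems", "study_problems",
                   "psychosomatic", "somatic_complaints", "internalizing",
                   "anxiety", "conduct", "impulsivity", "social_problems")
  cog_items <- c("stroop_c_time", "stroop_cw_time", "wcst_errors",
                 "wcst_categories", "vft_total", "vm_score",
                 "digit_span", "reaction_time")
  L <- matrix(0, nrow = 18, ncol = 2,
              dimnames = list(c(paste0("behav_", behav_items),
                                paste0("cog_", cog_items)),
                              c("behavior", "cognition")))
  L[1:6, "behavior"] <- c(0.90, 0.85, 0.80, 0.70, 0.75, 0.60)
  L[11:17, "cognition"] <- c(-0.70, -0.80, -0.75, 0.65, 0.60, 0.55, 0.50)
  L
}

#' Plant the ground truth of a synthetic cohort
#'
#' Draws the latent dimension scores, the coupled edge sets with their
#' signs, and fixes the clinical loading structure — everything the
#' recovery tests need to score the pipeline against.
#'
#' Two latent dimensions are planted by default: a behavior-problem
#' dimension and a (negatively correlated) cognition dimension. Each
#' dimension couples to a sparse random set of edges; a configurable
#' fraction of those edges is shared between the two dimensions (with a
#' common sign), which is what makes dFC -> cognition -> behavior
#' mediation possible downstream.
#'
#' @param n_subj Number of subjects.
#' @param n_edges Number of edges in the connectivity upper triangle.
#' @param coupled_frac Fraction of edges coupled to each dimension
#'   (default 0.005: half as dense as the downstream top-1-percent
#'   feature selection, so the selected set can cover the planted set).
#' @param overlap_frac Fraction of each dimension's coupled edges shared
#'   with the other dimension (default 0.5).
#' @param coupling Slope linking a latent score to the coupled edges'
#'   connectivity-gap amplitude (unitless; default 0.4).
#' @param latent_cor Correlation planted between the behavior and
#'   cognition latent scores (default -0.4: worse cognition, more
#'   behavior problems).
#' @param clinical_loadings Items-by-dimensions loading matrix; default
#'   [default_clinical_loadings()].
#' @param age_slope Planted slope of standardized age on every
#'   cognition-loading item (default 0.3).
#' @param seed Integer seed.
#' @return List of class `ground_truth`: `latent_scores` (n_subj x 2
#'   matrix), `coupled_edges` (per-dimension integer vectors),
#'   `edge_signs` (per-dimension named sign vectors), `edge_weights`
#'   (per-dimension length-`n_edges` unit vectors: the planted canonical
#'   weight patterns), `shared_edges`, `coupling`, `clinical_loadings`,
#'   `covariate_slopes`, `mediation_params`.
#' @export
simulate_ground_truth <- function(n_subj, n_edges, coupled_frac = 0.005,
                                  overlap_frac = 0.5, coupling = 0.4,
                                  latent_cor = -0.4,
                                  clinical_loadings = default_clinical_loadings(),
                                  age_slope = 0.3, seed = 1) {
  stopifnot(is_count(n_subj), is_count(n_edges),
            coupled_frac > 0, coupled_frac <= 1,
            overlap_frac >= 0, overlap_frac <= 1,
            abs(latent_cor) < 1)
  dims <- colnames(clinical_loadings)
  if (is.null(dims) || any(colSums(clinical_loadings != 0) < 1)) {
    abort("clinical_loadings needs named columns with >= 1 nonzero entry each")
  }
  with_seed_if(seed, {
    n_c <- ceiling(coupled_frac * n_edges)
    n_sh <- round(overlap_frac * n_c)
    pool <- sample.int(n_edges, n_sh + length(dims) * (n_c - n_sh))
    shared <- sort(pool[seq_len(n_sh)])
    rest <- pool[-seq_len(n_sh)]
    coupled <- list(); signs <- list(); weights <- list()
    shared_sign <- sample(c(-1, 1), n_sh, replace = TRUE)
    for (d in seq_along(dims)) {
      own <- sort(rest[((d - 1) * (n_c - n_sh) + 1):(d * (n_c - n_sh))])
      edges <- sort(c(shared, own))
      sg <- stats::setNames(numeric(length(edges)), edges)
      # a shared edge loads on both dimensions coherently with their
      # correlation (e.g. positively on behavior problems and negatively
      # on cognition when the latents are anticorrelated), so its
      # amplitude tracks the strong latent contrast rather than the
      # attenuated latent sum
      sg[as.character(shared)] <-
        if (d == 1) shared_sign else sign(latent_cor) * shared_sign
      sg[as.character(own)] <- sample(c(-1, 1), length(own), replace = TRUE)
      w <- numeric(n_edges)
      w[edges] <- sg[as.character(edges)] / sqrt(length(edges))
      coupled[[dims[d]]] <- edges
      signs[[dims[d]]] <- sg
      weights[[dims[d]]] <- w
    }
    cog <- stats::rnorm(n_subj)
    beh <- latent_cor * cog + sqrt(1 - latent_cor^2) * stats::rnorm(n_subj)
    latent <- cbind(behavior = beh, cognition = cog)
    slopes <- stats::setNames(rep(0, nrow(clinical_loadings)),
                              rownames(clinical_loadings))
    slopes[clinical_loadings[, "cognition"] != 0] <- age_slope
    structure(list(
      latent_scores = latent,
      coupled_edges = coupled,
      edge_signs = signs,
      edge_weights = weights,
      shared_edges = shared,
      coupling = coupling,
      clinical_loadings = clinical_loadings,
      covariate_slopes = list(age = slopes),
      mediation_params = c(a = 0.5, b = 0.4, c_prime = 0.2)),
      class = "ground_truth")
  })
}

#' Simulate subject covariates
#'
#' Age uniform on 6-16 years, sex coded 0/1 with equal probability, mean
#' framewise displacement (head motion, mm) log-normal around 0.15 mm.
#' When `truth` is supplied, a diagnosis label marks the `n_patient`
#' subjects with the highest behavior-problem latent scores.
#'
#' @param n_subj Number of subjects.
#' @param truth Optional `ground_truth` for the diagnosis labels.
#' @param n_patient Number of patient-like subjects (default 63 when the
#'   cohort has the default 122 subjects, otherwise ~52 percent).
#' @param seed Integer seed.
#' @return Tibble with `subject`, `age`, `sex`, `mean_fd` and (when
#'   `truth` given) `diagnosis`.
#' @export
simulate_covariates <- function(n_subj, truth = NULL,
                                n_patient = round(n_subj * 63 / 122),
                                seed = 1) {
  with_seed_if(seed, {
    out <- tibble::tibble(
      subject = sprintf("sub%03d", seq_len(n_subj)),
      age = round(stats::runif(n_subj, 6, 16), 1),
      sex = stats::rbinom(n_subj, 1, 0.5),
      mean_fd = round(exp(stats::rnorm(n_subj, log(0.15), 0.4)), 4))
    if (!is.null(truth)) {
      beh <- truth$latent_scores[, "behavior"]
      out$diagnosis <- as.integer(rank(-beh, ties.method = "first") <= n_patient)
    }
    out
  })
}

#' Simulate band-limited time series with phenotype-coupled dynamics
#'
#' Generates one parcellated BOLD-like series per subject. Connectivity is
#' driven by a two-state regime-switching covariance process with
#' geometric dwell times (mean `dwell_tr` TRs). Edges coupled to a latent
#' dimension have a between-regime correlation gap of
#' `base_gap + coupling * sign * latent_score` (summed over the
#' dimensions that include the edge, plus small age/motion nuisance
#' terms when covariates are supplied), floored at a small positive value
#' — connectivity variability cannot be negative — and clipped so state
#' correlations stay inside (-1, 1). Uncoupled edges keep a time-constant
#' covariance (within-network `base_cor`, zero between networks). Signals
#' are band-limited to `band` Hz by frequency-domain masking of the
#' driving noise before covariance coloring.
#'
#' @param atlas Atlas tibble from [make_atlas()].
#' @param truth `ground_truth` object (provides latent scores, coupled
#'   edges, signs and the coupling slope).
#' @param n_tr Time points per subject (default 200).
#' @param tr_s Repetition time in seconds (default 2).
#' @param noise_sd Overall signal amplitude (arbitrary units, > 0).
#' @param base_cor Baseline within-network correlation (default 0.25).
#' @param base_gap Baseline between-regime correlation gap of coupled
#'   edges (default 0.9).
#' @param dwell_tr Mean regime dwell time in TRs (default 20).
#' @param band Passband in Hz (default `c(0.01, 0.08)`).
#' @param covariates Optional covariate tibble (for nuisance effects of
#'   age and motion on the gap amplitude).
#' @param nuisance_gap Slope of standardized age and motion on the
#'   coupled-edge gap (default 0.05 each).
#' @param shared_chain If `TRUE` (default) all subjects share one regime
#'   chain realization, so between-subject variability in edge dynamics
#'   reflects only the planted amplitude differences; if `FALSE` each
#'   subject gets an independent chain (adds state-occupancy noise).
#' @param seed Integer seed.
#' @return Named list of `n_tr` x `n_roi` matrices, one per subject, with
#'   attributes `tr_s` and `clip_warnings` (subjects where more than half
#'   the coupled edges needed clipping).
#' @export
simulate_timeseries <- function(atlas, truth, n_tr = 200, tr_s = 2,
                                noise_sd = 1, base_cor = 0.25,
                                base_gap = 0.9, dwell_tr = 20,
                                band = c(0.01, 0.08), covariates = NULL,
                                nuisance_gap = 0.05, shared_chain = TRUE,
                                seed = 1) {
  stopifnot(noise_sd > 0, is_count(n_tr), tr_s > 0)
  n_roi <- nrow(atlas)
  ei <- edge_index(atlas)
  n_edges <- nrow(ei)
  n_subj <- nrow(truth$latent_scores)
  if (n_tr < 2) abort("n_tr too small")
  # baseline correlation structure: block structure by network
  R0 <- diag(n_roi)
  R0[cbind(ei$roi_i, ei$roi_j)] <- ifelse(ei$within, base_cor, 0)
  R0[cbind(ei$roi_j, ei$roi_i)] <- R0[cbind(ei$roi_i, ei$roi_j)]
  dims <- names(truth$coupled_edges)
  z_age <- z_fd <- rep(0, n_subj)
  if (!is.null(covariates)) {
    z_age <- as.numeric(scale(covariates$age))
    z_fd <- as.numeric(scale(covariates$mean_fd))
  }
  clip_warn <- character(0)
  draw_chain <- function() {
    st <- integer(n_tr)
    st[1] <- sample(1:2, 1)
    flips <- stats::runif(n_tr - 1) < 1 / dwell_tr
    for (t in 2:n_tr) st[t] <- if (flips[t - 1]) 3L - st[t - 1] else st[t - 1]
    st
  }
  out <- with_seed_if(seed, {
    chain <- if (shared_chain) draw_chain() else NULL
    lapply(seq_len(n_subj), function(s) {
      gap <- numeric(n_edges)
      coupled_all <- sort(unique(unlist(truth$coupled_edges)))
      gap[coupled_all] <- base_gap +
        nuisance_gap * (z_age[s] + z_fd[s])
      for (d in dims) {
        e <- truth$coupled_edges[[d]]
        gap[e] <- gap[e] + truth$coupling * truth$edge_signs[[d]] *
          truth$latent_scores[s, d]
      }
      gap[coupled_all] <- pmax(gap[coupled_all], 0.02)
      r_e <- R0[cbind(ei$roi_i, ei$roi_j)]
      r_lo <- r_e; r_hi <- r_e
      r_lo[coupled_all] <- r_e[coupled_all] - gap[coupled_all] / 2
      r_hi[coupled_all] <- r_e[coupled_all] + gap[coupled_all] / 2
      clipped <- sum(r_lo[coupled_all] < -0.9 | r_hi[coupled_all] > 0.9)
      if (clipped > 0.5 * length(coupled_all)) {
        clip_warn <<- c(clip_warn, sprintf("sub%03d", s))
      }
      r_lo <- pmin(pmax(r_lo, -0.9), 0.9)
      r_hi <- pmin(pmax(r_hi, -0.9), 0.9)
      C_lo <- chol_repaired(edge_to_cor(r_lo, ei, n_roi))
      C_hi <- chol_repaired(edge_to_cor(r_hi, ei, n_roi))
      # regime chain with geometric dwell
      st <- chain %||% draw_chain()
      W <- bandlimit_noise(n_tr, n_roi, tr_s, band)
      Xs <- matrix(0, n_tr, n_roi)
      if (any(st == 1)) Xs[st == 1, ] <- W[st == 1, , drop = FALSE] %*% C_lo
      if (any(st == 2)) Xs[st == 2, ] <- W[st == 2, , drop = FALSE] %*% C_hi
      Xs * noise_sd
    })
  })
  names(out) <- sprintf("sub%03d", seq_len(n_subj))
  if (length(clip_warn)) {
    warn(paste0("correlation clipping affected >50% of coupled edges for: ",
                paste(clip_warn, collapse = ", ")))
  }
  attr(out, "tr_s") <- tr_s
  out
}

# rebuild a full correlation matrix from an edge vector
edge_to_cor <- function(r_edges, ei, n_roi) {
  R <- diag(n_roi)
  R[cbind(ei$roi_i, ei$roi_j)] <- r_edges
  R[cbind(ei$roi_j, ei$roi_i)] <- r_edges
  R
}

# upper Cholesky factor of a correlation matrix, repairing indefiniteness
# by eigenvalue flooring and rescaling the diagonal back to 1
chol_repaired <- function(R, floor_ev = 1e-4) {
  ev <- eigen(R, symmetric = TRUE)
  if (min(ev$values) < floor_ev) {
    vals <- pmax(ev$values, floor_ev)
    R <- ev$vectors %*% (vals * t(ev$vectors))
    d <- sqrt(diag(R))
    R <- R / tcrossprod(d)
  }
  chol(R)
}

# white Gaussian noise band-limited by frequency-domain masking, columns
# re-standardized to unit variance
bandlimit_noise <- function(n_tr, n_roi, tr_s, band) {
  W <- matrix(stats::rnorm(n_tr * n_roi), n_tr, n_roi)
  freqs <- (seq_len(n_tr) - 1) / (n_tr * tr_s)
  freqs <- pmin(freqs, 1 / tr_s - freqs)  # fold to [0, Nyquist]
  keep <- freqs >= band[1] & freqs <= band[2]
  if (!any(keep)) abort("passband contains no Fourier bins at this n_tr/tr_s")
  Fw <- stats::mvfft(W)
  Fw[!keep, ] <- 0
  W <- Re(stats::mvfft(Fw, inverse = TRUE)) / n_tr
  scale(W)[, , drop = TRUE]
}

#' Simulate the clinical table from planted loadings
#'
#' Each clinical item is `loadings . latent_scores` plus planted
#' covariate effects (standardized-age slopes on cognition items, a small
#' sex shift on behavior items) plus Gaussian item noise. Column names
#' carry the behavior/cognition set membership via their `behav_`/`cog_`
#' prefixes.
#'
#' @param truth `ground_truth` object.
#' @param covariates Covariate tibble from [simulate_covariates()].
#' @param item_noise_sd Item noise SD (>= 0, default 0.5).
#' @param sex_effect Additive shift on behavior-loading items for sex = 1
#'   (default 0.1).
#' @param seed Integer seed.
#' @return Tibble with `subject` plus one column per clinical item.
#' @export
simulate_clinical <- function(truth, covariates, item_noise_sd = 0.5,
                              sex_effect = 0.1, seed = 1) {
  stopifnot(item_noise_sd >= 0)
  L <- truth$clinical_loadings
  n_subj <- nrow(truth$latent_scores)
  stopifnot(nrow(covariates) == n_subj)
  with_seed_if(seed, {
    M <- truth$latent_scores[, colnames(L), drop = FALSE] %*% t(L)
    z_age <- as.numeric(scale(covariates$age))
    if (stats::sd(covariates$age) == 0) z_age <- rep(0, n_subj)
    age_sl <- truth$covariate_slopes$age[colnames(M)]
    M <- M + outer(z_age, age_sl)
    beh_items <- L[, "behavior"] != 0
    M[, beh_items] <- M[, beh_items] + sex_effect * covariates$sex
    M <- M + matrix(stats::rnorm(length(M), 0, item_noise_sd), nrow(M))
    dplyr::bind_cols(tibble::tibble(subject = covariates$subject),
                     tibble::as_tibble(M))
  })
}

#' Simulate a full synthetic cohort
#'
#' Assembles the pieces — atlas, ground truth, covariates, per-subject
#' band-limited time series with phenotype-coupled connectivity dynamics,
#' and the clinical table — into one bundle with consistent subject
#' ordering. The defaults mirror the emulated study conditions: 122
#' subjects (63 patient-like), 200 time points at TR = 2 s, a 227-ROI
#' 10-network atlas, and a latent coupling slope of 0.4.
#'
#' @param n_subj Number of subjects (default 122).
#' @param atlas Atlas tibble (default 227-ROI, 10-network).
#' @param n_tr,tr_s Series length and repetition time (defaults 200, 2 s).
#' @param coupling Latent-to-gap slope (default 0.4; 0 = null cohort).
#' @param coupled_frac,overlap_frac,latent_cor Ground-truth structure;
#'   see [simulate_ground_truth()].
#' @param item_noise_sd Clinical item noise (default 0.5).
#' @param noise_sd Time-series amplitude (default 1).
#' @param seed Integer seed; all component seeds derive from it.
#' @param ... Further arguments passed to [simulate_timeseries()].
#' @return List of class `cohort_bundle`: `timeseries`, `clinical`,
#'   `covariates`, `truth`, `atlas`, `edge_index`, `tr_s`.
#' @export
simulate_cohort <- function(n_subj = 122, atlas = make_atlas(227),
                            n_tr = 200, tr_s = 2, coupling = 0.4,
                            coupled_frac = 0.005, overlap_frac = 0.5,
                            latent_cor = -0.4, item_noise_sd = 0.5,
                            noise_sd = 1, seed = 1, ...) {
  sub_seeds <- with_seed_if(seed, sample.int(.Machine$integer.max - 1, 4))
  ei <- edge_index(atlas)
  truth <- simulate_ground_truth(n_subj, nrow(ei),
                                 coupled_frac = coupled_frac,
                                 overlap_frac = overlap_frac,
                                 coupling = coupling,
                                 latent_cor = latent_cor,
                                 seed = sub_seeds[1])
  covariates <- simulate_covariates(n_subj, truth, seed = sub_seeds[2])
  ts <- simulate_timeseries(atlas, truth, n_tr = n_tr, tr_s = tr_s,
                            noise_sd = noise_sd, covariates = covariates,
                            seed = sub_seeds[3], ...)
  clinical <- simulate_clinical(truth, covariates,
                                item_noise_sd = item_noise_sd,
                                seed = sub_seeds[4])
  structure(list(timeseries = ts, clinical = clinical,
                 covariates = covariates, truth = truth, atlas = atlas,
                 edge_index = ei, tr_s = tr_s),
            class = "cohort_bundle")
}

#' @export
print.cohort_bundle <- function(x, ...) {
  cat(sprintf(paste0("Synthetic cohort: %d subjects, %d TR x %d ROI ",
                     "(TR %.1f s), %d clinical items\n"),
              length(x$timeseries), nrow(x$timeseries[[1]]),
              ncol(x$timeseries[[1]]), x$tr_s, ncol(x$clinical) - 1))
  cat(sprintf("  planted coupling %.2f on %d behavior / %d cognition edges (%d shared)\n",
              x$truth$coupling,
              length(x$truth$coupled_edges$behavior),
              length(x$truth$coupled_edges$cognition),
              length(x$truth$shared_edges)))
  invisible(x)
}

#' Simulate a simple mediation cohort with known paths
#'
#' Generates `(X, M, Y, age, sex)` from the linear structural model
#' `M = a X + 0.2 z(age) + 0.2 sex + e1`,
#' `Y = c' X + b M + 0.2 z(age) + 0.2 sex + e2`, with `X` standard normal
#' and independent unit-variance errors, so the true indirect effect is
#' `a * b` and the true total effect `c' + a * b`.
#'
#' @param n_subj Number of subjects (>= 10).
#' @param a,b,c_prime Planted standardized path coefficients.
#' @param seed Integer seed.
#' @return Tibble with columns `X`, `M`, `Y`, `age`, `sex`.
#' @export
simulate_mediation_cohort <- function(n_subj, a = 0.5, b = 0.4,
                                      c_prime = 0.2, seed = 1) {
  if (!is_count(n_subj) || n_subj < 10) abort("n_subj must be >= 10")
  with_seed_if(seed, {
    X <- stats::rnorm(n_subj)
    age <- stats::runif(n_subj, 6, 16)
    sex <- stats::rbinom(n_subj, 1, 0.5)
    za <- as.numeric(scale(age))
    M <- a * X + 0.2 * za + 0.2 * sex + stats::rnorm(n_subj)
    Y <- c_prime * X + b * M + 0.2 * za + 0.2 * sex + stats::rnorm(n_subj)
    tibble::tibble(X = X, M = M, Y = Y, age = age, sex = sex)
  })
}
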