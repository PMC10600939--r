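test_that("permutation p follows the add-one formula and its bounds", {
  set.seed(40)
  n <- 30
  z <- rnorm(n)
  X <- matrix(rnorm(n * 4), n) + z
  Y <- matrix(rnorm(n * 3), n) + z
  # identity permutation only: permuted r equals observed r, so p = 1
  pt_id <- permutation_test(X, Y, n_pairs = 1, perms = list(seq_len(n)))
  expect_equal(pt_id$p, 1)
  # observed beats every permutation: p = 1/(n_perm + 1)
  pt <- permutation_test(X, Y, n_pairs = 1, n_perm = 50, seed = 2)
  expect_gte(min(pt$p), 1 / 51)
  if (all(attr(pt, "perm_r")[, 1] < pt$r[1])) {
    expect_equal(pt$p[1], 1 / 51)
  }
  expect_true(all(pt$p > 0 & pt$p <= 1))
})

test_that("BH adjustment reproduces the step-up formula", {
  # oracle: direct Benjamini-Hochberg computation
  p <- c(0.01, 0.02, 0.04, 0.8)
  q <- fdr_adjust(p)
  expect_equal(q, c(0.04, 0.04, 0.0533, 0.8), tolerance = 1e-3)
  bh_direct <- function(p) {
    n <- length(p); o <- order(p)
    q <- p[o] * n / seq_len(n)
    q <- rev(cummin(rev(q)))
    pmin(q, 1)[order(o)]
  }
  for (s in 1:5) {
    pv <- withr::with_seed(s, runif(7))
    expect_equal(fdr_adjust(pv), bh_direct(pv), tolerance = 1e-12)
  }
  expect_equal(fdr_adjust(0.03), 0.03)
  expect_equal(fdr_adjust(rep(0.2, 4)), rep(0.2, 4))
})

test_that("BH output is non-decreasing in the input order statistics", {
  pv <- c(0.5, 0.001, 0.04, 0.2, 0.009)
  q <- fdr_adjust(pv)
  expect_true(all(q >= pv))
  expect_equal(order(q), order(pv))
  expect_true(all(diff(sort(q)) >= 0))
})

test_that("bootstrap stability separates planted from noise features", {
  set.seed(41)
  freqs <- replicate(3, {
    n <- 80
    z <- rnorm(n)
    X <- matrix(rnorm(n * 10), n,
                dimnames = list(NULL, paste0("f", 1:10)))
    X[, 1] <- X[, 1] * 0.3 + z          # strong planted feature
    Y <- matrix(rnorm(n * 3), n) + z
    bs <- bootstrap_stability(X, Y, n_pairs = 1, c_x = 0.4, c_y = 1,
                              n_boot = 100, seed = 3)
    fs <- bs$feature_stats[bs$feature_stats$pair == 1, ]
    c(planted = fs$selection_freq[1],
      noise = median(fs$selection_freq[5:10]))
  })
  expect_gt(median(freqs["planted", ]), 0.9)
  expect_lt(median(freqs["noise", ]), 0.5)
})

test_that("bootstrap handles duplicated rows and deterministic relations", {
  set.seed(42)
  X <- matrix(rnorm(20 * 3), 20)
  X <- rbind(X, X)                      # duplicated subjects
  Y <- cbind(rnorm(40), rnorm(40))
  bs <- bootstrap_stability(X, Y, n_pairs = 1, c_x = 1, c_y = 1,
                            n_boot = 100, seed = 4)
  expect_true(all(bs$feature_stats$selection_freq >= 0 &
                    bs$feature_stats$selection_freq <= 1))
  # a noise-free deterministic relation has (essentially) zero r_se
  X1 <- matrix(rnorm(40), 40)
  bs2 <- bootstrap_stability(X1, X1, n_pairs = 1, c_x = 1, c_y = 1,
                             n_boot = 100, seed = 5)
  expect_lt(bs2$pair_stats$r_se[1], 1e-10)
  expect_equal(bs2$pair_stats$r_mean[1], 1, tolerance = 1e-8)
})

test_that("structure loadings equal direct correlations with the variates", {
  set.seed(43)
  X <- matrix(rnorm(40 * 3), 40, dimnames = list(NULL, paste0("x", 1:3)))
  Y <- matrix(rnorm(40 * 3), 40, dimnames = list(NULL, paste0("y", 1:3)))
  m <- fit_scca(X, Y, n_pairs = 1, c_x = 1, c_y = 1)
  ld <- structure_loadings(X, Y, m)
  xs <- scca_scores(m, X = X)$x_scores[, 1]
  for (j in 1:3) {
    expect_equal(ld$loading[ld$side == "x" & ld$variable == paste0("x", j)],
                 cor(X[, j], xs), tolerance = 1e-10)
  }
  # a variable equal to the variate has loading 1; an orthogonalized one 0
  X2 <- cbind(X, v = xs, o = residuals(lm(rnorm(40) ~ xs)))
  ld2 <- structure_loadings(X2, Y, m, X_fit = X)
  expect_equal(ld2$loading[ld2$variable == "v"], 1, tolerance = 1e-10)
  expect_lt(abs(ld2$loading[ld2$variable == "o"]), 1e-10)
})

test_that("network block sums aggregate absolute loadings with zero fill", {
  atlas <- make_atlas(20, stats::setNames(rep(2, 10),
                                          names(default_network_sizes(227))))
  ei <- edge_index(atlas)
  # enumeration oracle on random loadings over a few edges
  set.seed(44)
  picks <- sample(nrow(ei), 20)
  ld <- tibble::tibble(edge_id = picks, loading = rnorm(20))
  out <- network_block_loadings(ld, ei)
  expect_equal(nrow(out), 55)
  for (b in unique(ei$block[picks])) {
    manual <- sum(abs(ld$loading[ei$block[ld$edge_id] == b]))
    expect_equal(out$sum_abs_loading[out$block == b], manual)
  }
  expect_true(all(out$sum_abs_loading[!out$block %in% ei$block[picks]] == 0))
  # signs do not cancel within a block (use a block with several edges)
  blk <- names(which(table(ei$block) >= 2))[1]
  pair_ids <- ei$edge_id[ei$block == blk][1:2]
  two <- tibble::tibble(edge_id = pair_ids, loading = c(0.3, -0.2))
  out2 <- network_block_loadings(two, ei)
  expect_equal(out2$sum_abs_loading[out2$block == blk], 0.5)
  expect_error(network_block_loadings(
    tibble::tibble(edge_id = 99999L, loading = 1), ei), "unknown edge")
})

test_that("null cohorts give uniform permutation p when selection is refreshed", {
  # scaled-down null soundness: tiny null cohorts through dFC + sCCA,
  # with Relief selection re-run inside each permutation so the null
  # distribution reflects the whole supervised procedure
  # n per replicate is kept moderate: residualized rows are only
  # asymptotically exchangeable, so very small cohorts inflate the
  # left tail slightly (see the vignette)
  atlas <- tiny_atlas(10)
  sel_fun <- function(X, Y) {
    select_top_fraction(
      relief_weights(X, pca_reduce(Y, 1e-12)$scores[, 1], 30), 0.2)
  }
  pvals <- vapply(1:60, function(rep) {
    co <- suppressWarnings(
      simulate_cohort(n_subj = 40, atlas = atlas, n_tr = 60, coupling = 0,
                      item_noise_sd = 1, seed = 5000 + rep))
    cl <- as.matrix(co$clinical[, grep("^cog_", names(co$clinical))])
    d <- compute_dfc(co$timeseries, width_tr = 20)
    X <- residualize(d, co$covariates, c("age", "sex", "mean_fd"))
    Y <- residualize(cl, co$covariates, c("age", "sex"))
    Xs <- X[, sel_fun(X, Y), drop = FALSE]
    permutation_test(Xs, Y, n_pairs = 1, c_x = 0.7, c_y = 0.8,
                     n_perm = 39, seed = rep,
                     X_full = X, select_fun = sel_fun)$p[1]
  }, numeric(1))
  ks <- suppressWarnings(ks.test(pvals, "punif"))
  expect_gt(ks$p.value, 0.01)
  expect_lte(mean(pvals <= 0.05), 0.15)
})
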