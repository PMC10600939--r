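test_that("a shared single column gives a perfect trivial pair", {
  set.seed(30)
  x <- scale(rnorm(30))
  fit <- fit_pmd_pair(x, x, 1, 1)
  expect_equal(fit$r, 1, tolerance = 1e-10)
  expect_equal(abs(fit$u), 1, ignore_attr = TRUE)
  expect_equal(fit$u, fit$v)
})

test_that("unpenalized PMD matches classical CCA on 20 seeded instances", {
  # PMD penalizes the diagonal approximation of the within-block
  # covariances, so the exact equivalence with classical CCA holds on
  # column-whitened blocks (where that approximation is the truth)
  whiten <- function(M) scale(M %*% solve(chol(cov(M))))
  worst <- 0
  for (seed in 1:20) {
    withr::with_seed(400 + seed, {
      p <- sample(3:5, 1); q <- sample(3:5, 1)
      X <- whiten(matrix(rnorm(50 * p), 50))
      Y <- whiten(matrix(rnorm(50 * q), 50))
    })
    fit <- fit_pmd_pair(X, Y, 1, 1, max_iter = 5000, tol = 1e-12)
    # oracle: first canonical correlation from the classical
    # eigendecomposition route
    r_cca <- stats::cancor(X, Y)$cor[1]
    worst <- max(worst, abs(fit$r - r_cca))
  }
  expect_lt(worst, 1e-6)
})

test_that("planted sparse support is recovered across seeds", {
  hits <- vapply(1:10, function(seed) {
    withr::with_seed(500 + seed, {
      n <- 200
      z <- rnorm(n)
      X <- matrix(rnorm(n * 100), n)
      X[, 1:5] <- X[, 1:5] * 0.6 + z
      Y <- matrix(rnorm(n * 10), n)
      Y[, 1:2] <- Y[, 1:2] * 0.6 + z
    })
    fit <- fit_pmd_pair(scale(X), scale(Y), c_x = 0.3, c_y = 0.5)
    sum(which(fit$u != 0) %in% 1:5)
  }, numeric(1))
  expect_gte(median(hits), 4)
})

test_that("deflation removes exactly the fitted rank-one structure", {
  set.seed(32)
  u <- dfclink:::l2_normalize(rnorm(6))
  X1 <- rnorm(40) %*% t(u)                      # exact rank one along u
  d <- deflate(X1, X1, u, u)
  expect_lt(max(abs(d$X)), 1e-10)
  # sparse u touches only its own columns
  X <- matrix(rnorm(40 * 6), 40)
  e1 <- c(1, rep(0, 5))
  d2 <- deflate(X, X, e1, e1)
  expect_equal(d2$X[, 2:6], X[, 2:6])
  expect_lt(max(abs(d2$X[, 1])), 1e-12)
})

test_that("successive pairs on planted single-factor data have shrinking r", {
  set.seed(33)
  n <- 100
  z <- rnorm(n)
  X <- matrix(rnorm(n * 8), n) + z
  Y <- matrix(rnorm(n * 4), n) + z
  m <- fit_scca(X, Y, n_pairs = 2, c_x = 1, c_y = 1)
  expect_gte(m$pairs[[1]]$r, m$pairs[[2]]$r)
})

test_that("multi-pair fit recovers two orthogonal planted factors", {
  cos_own <- matrix(NA_real_, 10, 2); cos_cross <- matrix(NA_real_, 10, 2)
  for (s in 1:10) {
    withr::with_seed(600 + s, {
      n <- 150
      z1 <- rnorm(n); z2 <- rnorm(n)
      X <- matrix(rnorm(n * 20), n) * 0.7
      X[, 1:5] <- X[, 1:5] + z1
      X[, 6:10] <- X[, 6:10] + z2
      Y <- matrix(rnorm(n * 6), n) * 0.7
      Y[, 1:3] <- Y[, 1:3] + z1
      Y[, 4:6] <- Y[, 4:6] + z2
    })
    m <- fit_scca(X, Y, n_pairs = 2, c_x = 0.6, c_y = 0.8)
    pu1 <- c(rep(1, 5), rep(0, 15)) / sqrt(5)
    pu2 <- c(rep(0, 5), rep(1, 5), rep(0, 10)) / sqrt(5)
    us <- sapply(m$pairs, `[[`, "u")
    # align extracted pairs to planted factors by best match
    c11 <- abs(sum(us[, 1] * pu1)); c12 <- abs(sum(us[, 1] * pu2))
    if (c11 >= c12) {
      cos_own[s, ] <- c(c11, abs(sum(us[, 2] * pu2)))
      cos_cross[s, ] <- c(c12, abs(sum(us[, 2] * pu1)))
    } else {
      cos_own[s, ] <- c(c12, abs(sum(us[, 2] * pu1)))
      cos_cross[s, ] <- c(c11, abs(sum(us[, 2] * pu2)))
    }
  }
  expect_gt(median(cos_own), 0.8)
  expect_lt(median(cos_cross), 0.3)
})

test_that("asking for more pairs than rank yields near-zero trailing r", {
  set.seed(34)
  X <- matrix(rnorm(60 * 6), 60)
  Y <- matrix(rnorm(60 * 3), 60)
  m <- fit_scca(X, Y, n_pairs = 5, c_x = 1, c_y = 1)
  r <- vapply(m$pairs, `[[`, numeric(1), "r")
  expect_lt(min(r[4:5]), max(r[1:3]))
  expect_lt(r[5], 0.5)
})

test_that("unit norms and L1 budgets hold after every fit", {
  for (s in 1:5) {
    withr::with_seed(700 + s, {
      X <- matrix(rnorm(40 * 12), 40)
      Y <- matrix(rnorm(40 * 5), 40)
      c_x <- runif(1, 0.3, 1); c_y <- runif(1, 0.5, 1)
    })
    fit <- fit_pmd_pair(scale(X), scale(Y), c_x, c_y)
    expect_equal(sum(fit$u^2), 1, tolerance = 1e-8)
    expect_equal(sum(fit$v^2), 1, tolerance = 1e-8)
    expect_lte(sum(abs(fit$u)), max(c_x * sqrt(12), 1) + 1e-6)
    expect_lte(sum(abs(fit$v)), max(c_y * sqrt(5), 1) + 1e-6)
    expect_gte(fit$r, 0)
  }
})

test_that("shrinking the budget never increases the support of u", {
  set.seed(35)
  X <- matrix(rnorm(50 * 15), 50)
  Y <- matrix(rnorm(50 * 4), 50)
  nz <- vapply(c(1, 0.8, 0.6, 0.4, 0.2), function(cx) {
    sum(fit_pmd_pair(scale(X), scale(Y), cx, 1)$u != 0)
  }, numeric(1))
  expect_true(all(diff(nz) <= 0))
})

test_that("permuting feature columns permutes u and leaves r unchanged", {
  set.seed(36)
  X <- scale(matrix(rnorm(40 * 8), 40))
  Y <- scale(matrix(rnorm(40 * 3), 40))
  fit <- fit_pmd_pair(X, Y, 0.6, 1)
  perm <- sample(8)
  fit_p <- fit_pmd_pair(X[, perm], Y, 0.6, 1)
  expect_equal(fit_p$r, fit$r, tolerance = 1e-6)
  expect_equal(fit_p$u, fit$u[perm], tolerance = 1e-4)
})

test_that("sparsity tuning returns sensible cells", {
  set.seed(37)
  # single-cell grid is returned verbatim
  X <- matrix(rnorm(40 * 6), 40); Y <- matrix(rnorm(40 * 3), 40)
  tn <- tune_sparsity(X, Y, c_x_grid = 0.4, c_y_grid = 0.7, seed = 1)
  expect_equal(c(tn$c_x, tn$c_y), c(0.4, 0.7))
  # planted sparse signal: the chosen cell generalizes at least as well
  # as the densest cell in most replicates
  wins <- vapply(1:10, function(s) {
    withr::with_seed(800 + s, {
      n <- 80
      z <- rnorm(n)
      X <- matrix(rnorm(n * 30), n); X[, 1:3] <- X[, 1:3] * 0.5 + z
      Y <- matrix(rnorm(n * 4), n); Y[, 1] <- Y[, 1] * 0.5 + z
    })
    tn <- tune_sparsity(X, Y, c_x_grid = c(0.2, 0.6, 1),
                        c_y_grid = c(0.5, 1), seed = s)
    dense <- tn$grid[tn$grid$c_x == 1 & tn$grid$c_y == 1, ]
    best <- tn$grid[tn$grid$c_x == tn$c_x & tn$grid$c_y == tn$c_y, ]
    best$cv_r >= dense$cv_r
  }, logical(1))
  expect_gte(mean(wins), 0.6)
})

test_that("tuning on pure noise does not systematically pick the densest cell", {
  densest <- vapply(1:20, function(s) {
    withr::with_seed(900 + s, {
      X <- matrix(rnorm(50 * 20), 50)
      Y <- matrix(rnorm(50 * 4), 50)
    })
    tn <- tune_sparsity(X, Y, c_x_grid = c(0.2, 0.6, 1),
                        c_y_grid = c(0.5, 1), seed = s)
    tn$c_x == 1
  }, logical(1))
  expect_lt(mean(densest), 0.5)
})

test_that("scca tidiers expose weights and pair summaries", {
  set.seed(38)
  X <- matrix(rnorm(30 * 5), 30, dimnames = list(NULL, paste0("e", 1:5)))
  Y <- matrix(rnorm(30 * 3), 30, dimnames = list(NULL, paste0("i", 1:3)))
  m <- fit_scca(X, Y, n_pairs = 2, c_x = 0.8, c_y = 1)
  td <- tidy(m)
  expect_equal(nrow(td), 2 * (5 + 3))
  expect_setequal(unique(td$variable), c(paste0("e", 1:5), paste0("i", 1:3)))
  gl <- glance(m)
  expect_equal(gl$pair, 1:2)
  expect_true(all(gl$r >= 0 & gl$r <= 1))
})
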