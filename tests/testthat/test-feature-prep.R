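covs_fixture <- function(n = 60, seed = 14) {
  withr::with_seed(seed, tibble::tibble(
    age = runif(n, 6, 16), sex = rbinom(n, 1, 0.5),
    mean_fd = exp(rnorm(n, -2, 0.3))))
}

test_that("residualization removes covariates exactly and is idempotent", {
  covs <- covs_fixture()
  set.seed(15)
  X <- cbind(a = 2 * covs$age,                       # pure covariate column
             b = rnorm(60),                          # noise
             c = 0.3 * covs$age + rnorm(60))         # planted age slope
  R <- residualize(X, covs, c("age", "sex", "mean_fd"))
  expect_lt(max(abs(R[, "a"])), 1e-10)
  for (cv in c("age", "sex", "mean_fd")) {
    expect_lt(max(abs(cor(R, covs[[cv]]))), 1e-10)
  }
  expect_lt(abs(coef(lm(R[, "c"] ~ covs$age))[2]), 1e-10)
  R2 <- residualize(R, covs, c("age", "sex", "mean_fd"))
  expect_lt(max(abs(R2 - R)), 1e-10)
})

test_that("a covariate orthogonal to a column leaves the centered column", {
  n <- 50
  cv <- tibble::tibble(z = rep(c(-1, 1), n / 2))
  x <- rep(c(1, 1, -1, -1), length.out = n) + 3   # orthogonal to z
  R <- residualize(cbind(x = x), cv, "z")
  expect_equal(R[, "x"], x - mean(x), tolerance = 1e-12,
               ignore_attr = TRUE)
})

test_that("residualize rejects rank-deficient covariates", {
  cv <- tibble::tibble(a = 1:10, b = 2 * (1:10))
  expect_error(residualize(matrix(rnorm(10)), cv, c("a", "b")),
               "rank-deficient")
})

test_that("Relief finds a separating feature and zeroes constant features", {
  set.seed(16)
  n <- 40
  cls <- rep(0:1, each = n / 2)
  X <- cbind(sep = cls + rnorm(n, sd = 0.05),
             const = rep(3, n),
             matrix(rnorm(n * 8), n))
  w <- relief_weights(X, cls, k_neighbors = 5, mode = "classification")
  expect_equal(which.max(w), 1L, ignore_attr = TRUE)
  expect_identical(unname(w[2]), 0)
})

test_that("classification ReliefF matches a direct enumeration oracle", {
  # independent re-implementation: explicit loops over hits and misses
  set.seed(17)
  n <- 16
  cls <- rep(0:1, each = n / 2)
  X <- cbind(f1 = cls + rnorm(n, sd = 0.3), f2 = rnorm(n))
  k <- 3
  w_pkg <- relief_weights(X, cls, k_neighbors = k, mode = "classification")
  # oracle
  Z <- apply(X, 2, function(v) (v - min(v)) / diff(range(v)))
  D <- as.matrix(dist(Z, method = "manhattan")); diag(D) <- Inf
  w_or <- c(0, 0)
  for (i in 1:n) {
    hits <- which(cls == cls[i]); hits <- hits[order(D[i, hits])][1:k]
    miss <- which(cls != cls[i]); miss <- miss[order(D[i, miss])][1:k]
    for (f in 1:2) {
      w_or[f] <- w_or[f] - mean(abs(Z[hits, f] - Z[i, f])) / n +
        # equal class sizes: prior(miss)/(1 - prior(self)) = 1
        mean(abs(Z[miss, f] - Z[i, f])) / n
    }
  }
  expect_equal(unname(w_pkg), w_or, tolerance = 1e-12)
})

test_that("regression RReliefF matches a direct enumeration oracle", {
  set.seed(18)
  n <- 20
  tau <- rnorm(n)
  X <- cbind(f1 = tau + rnorm(n, sd = 0.4), f2 = rnorm(n))
  k <- 5; sigma <- 5
  w_pkg <- relief_weights(X, tau, k_neighbors = k, mode = "regression",
                          sigma = sigma)
  # oracle: accumulate the three RReliefF counters explicitly
  Z <- apply(X, 2, function(v) (v - min(v)) / diff(range(v)))
  D <- as.matrix(dist(Z, method = "manhattan")); diag(D) <- Inf
  infl <- exp(-((1:k) / sigma)^2); infl <- infl / sum(infl)
  ndc <- 0; nda <- c(0, 0); ndcda <- c(0, 0)
  for (i in 1:n) {
    nb <- order(D[i, ])[1:k]
    dt <- abs(tau[i] - tau[nb]) / diff(range(tau))
    for (jj in 1:k) {
      ndc <- ndc + infl[jj] * dt[jj]
      for (f in 1:2) {
        da <- abs(Z[i, f] - Z[nb[jj], f])
        nda[f] <- nda[f] + infl[jj] * da
        ndcda[f] <- ndcda[f] + infl[jj] * dt[jj] * da
      }
    }
  }
  w_or <- ndcda / ndc - (nda - ndcda) / (n - ndc)
  expect_equal(unname(w_pkg), w_or, tolerance = 1e-12)
  expect_gt(w_pkg[1], w_pkg[2])
})

test_that("duplicating a noise feature leaves the informative rank stable", {
  set.seed(19)
  n <- 40
  tau <- rnorm(n)
  noise <- matrix(rnorm(n * 9), n)
  X1 <- cbind(inf = tau + rnorm(n, sd = 0.3), noise)
  X2 <- cbind(X1, dup = noise[, 1])
  r1 <- which(order(-relief_weights(X1, tau, 8)) == 1)
  r2 <- which(order(-relief_weights(X2, tau, 8)) == 1)
  expect_equal(r1, r2)
})

test_that("Relief weights on pure noise concentrate around zero as n grows", {
  mean_abs <- vapply(c(30, 120), function(n) {
    withr::with_seed(20, {
      X <- matrix(rnorm(n * 10), n)
      mean(abs(relief_weights(X, rnorm(n), 10)))
    })
  }, numeric(1))
  expect_lt(mean_abs[2], mean_abs[1])
})

test_that("classification mode rejects k >= smallest class", {
  X <- matrix(rnorm(20), 10)
  expect_error(relief_weights(X, rep(0:1, 5), 5, mode = "classification"),
               "smaller than the smallest class")
})

test_that("top-fraction selection is ceil-based, ordered and tie-stable", {
  w <- setNames(rnorm(1000), paste0("f", 1:1000))
  expect_length(select_top_fraction(w, 0.01), 10)
  expect_equal(unname(select_top_fraction(w, 1.0)), 1:1000)
  # tie straddling the cutoff: ascending position wins
  wt <- c(a = 1, b = 0.5, c = 0.5, d = 0.5, e = 0)
  expect_equal(names(select_top_fraction(wt, 0.4)), c("a", "b"))
  expect_identical(select_top_fraction(wt, 0.4), select_top_fraction(wt, 0.4))
  expect_length(select_top_fraction(rnorm(5), 0.01), 1)  # never empty
})

test_that("PCA reduction keeps the smallest sufficient component count", {
  set.seed(23)
  base <- matrix(rnorm(40 * 2), 40, 2)
  X2 <- base %*% matrix(rnorm(2 * 6), 2, 6)  # exact rank 2
  expect_equal(pca_reduce(X2, 0.99)$n_components, 2)
  Xf <- matrix(rnorm(30 * 5), 30, 5)
  expect_equal(pca_reduce(Xf, 1.0)$n_components, 5)  # min(n-1, p)
})

test_that("PCA reconstruction error equals the eigenvalue tail sum", {
  set.seed(24)
  X <- matrix(rnorm(50 * 8), 50, 8)
  pr <- pca_reduce(X, 0.6)
  Xc <- scale(X, scale = FALSE)
  recon <- pr$scores %*% t(pr$loadings)
  err <- sum((Xc - recon)^2)
  ev <- eigen(crossprod(Xc), symmetric = TRUE)$values
  expect_equal(err, sum(ev[(pr$n_components + 1):8]), tolerance = 1e-8)
})
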