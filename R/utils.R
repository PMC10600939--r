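#' @keywords internal
"_PACKAGE"

#' @importFrom rlang %||% abort warn inform .data
#' @importFrom stats cor sd lm coef quantile rnorm runif rbinom var
#'   p.adjust prcomp cor.test setNames complete.cases fft
#' @importFrom utils head modifyList
NULL

# run `expr` under a private RNG stream when `seed` is given;
# leaves the caller's RNG state untouched
with_seed_if <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  stopifnot(is.numeric(seed), length(seed) == 1, is.finite(seed))
  withr::with_seed(as.integer(seed), expr)
}

# column standardization that records the constants used
standardize_cols <- function(X) {
  X <- as.matrix(X)
  mu <- colMeans(X)
  s <- col_sds(X)
  if (any(s == 0)) {
    abort(paste0("zero-variance column(s): ",
                 paste(head(which(s == 0), 5), collapse = ", ")))
  }
  Z <- sweep(sweep(X, 2, mu, "-"), 2, s, "/")
  list(Z = Z, mean = mu, sd = s)
}

# apply previously recorded standardization constants
apply_standardization <- function(X, std) {
  sweep(sweep(as.matrix(X), 2, std$mean, "-"), 2, std$sd, "/")
}

# sample SD of each column (denominator n - 1), vectorized
col_sds <- function(X) {
  n <- nrow(X)
  if (n < 2) abort("need at least 2 rows to compute a standard deviation")
  m <- colMeans(X)
  sqrt(pmax(colSums(X^2) - n * m^2, 0) / (n - 1))
}

l2_normalize <- function(x) {
  nx <- sqrt(sum(x^2))
  if (nx == 0) return(x)
  x / nx
}

soft_threshold <- function(x, lambda) {
  sign(x) * pmax(abs(x) - lambda, 0)
}

is_count <- function(x) {
  is.numeric(x) && length(x) == 1 && is.finite(x) && x == round(x) && x >= 1
}
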