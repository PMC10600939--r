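#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a sparse CCA model into one row per weight
#'
#' @param x An `scca` object.
#' @param ... Unused.
#' @return Tibble with `pair`, `side`, `variable`, `weight`.
#' @export
tidy.scca <- function(x, ...) {
  purrr::map_dfr(seq_len(x$n_pairs), function(k) {
    dplyr::bind_rows(
      tibble::tibble(pair = k, side = "x", variable = x$x_names,
                     weight = x$pairs[[k]]$u),
      tibble::tibble(pair = k, side = "y", variable = x$y_names,
                     weight = x$pairs[[k]]$v))
  })
}

#' One-row-per-pair summary of a sparse CCA model
#'
#' @param x An `scca` object.
#' @param ... Unused.
#' @return Tibble with `pair`, `r`, `nonzero_u`, `nonzero_v`,
#'   `converged`.
#' @export
glance.scca <- function(x, ...) {
  tibble::tibble(
    pair = seq_len(x$n_pairs),
    r = vapply(x$pairs, `[[`, numeric(1), "r"),
    nonzero_u = vapply(x$pairs, function(p) sum(p$u != 0), integer(1)),
    nonzero_v = vapply(x$pairs, function(p) sum(p$v != 0), integer(1)),
    converged = vapply(x$pairs, `[[`, logical(1), "converged"))
}

#' @export
tidy.scca_perm <- function(x, ...) {
  tibble::as_tibble(unclass(x))
}

#' Tidy bootstrap stability results (feature level)
#' @param x An `scca_boot` object.
#' @param ... Unused.
#' @export
tidy.scca_boot <- function(x, ...) x$feature_stats

#' @export
glance.scca_boot <- function(x, ...) {
  dplyr::mutate(x$pair_stats, n_boot = x$n_boot)
}

#' Tidy mediation estimates
#' @param x A `mediation_fit` object.
#' @param ... Unused.
#' @export
tidy.mediation_fit <- function(x, ...) x$estimates

#' @export
glance.mediation_fit <- function(x, ...) {
  tibble::tibble(n = x$n, n_boot = x$n_boot, conf = x$conf,
                 covariates = paste(x$covariates, collapse = ","))
}

#' Scatter plot of the canonical variates of one pair
#'
#' @param object An `scca` object.
#' @param X,Y The data matrices the model was fitted on.
#' @param pair Which canonical pair to plot (default 1).
#' @param ... Unused.
#' @return A ggplot: dFC variate score against clinical variate score,
#'   one point per subject, with the canonical correlation in the title.
#' @export
autoplot.scca <- function(object, X, Y, pair = 1, ...) {
  sc <- scca_scores(object, X = X, Y = Y)
  df <- tibble::tibble(x = sc$x_scores[, pair], y = sc$y_scores[, pair])
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = FALSE,
                         linewidth = 0.4, color = "grey40") +
    ggplot2::labs(
      x = "dFC canonical variate", y = "clinical canonical variate",
      title = sprintf("Canonical pair %d (r = %.3f)", pair,
                      object$pairs[[pair]]$r)) +
    ggplot2::theme_minimal()
}

#' Heatmap of network-block loading sums
#'
#' Displays the within/between-network sums of absolute structure
#' loadings as the lower triangle of a network-by-network grid, the
#' standard way these block summaries are visualized.
#'
#' @param block_loadings Tibble from [network_block_loadings()] (one
#'   canonical pair; filter first when it holds several).
#' @return A ggplot heatmap.
#' @export
plot_network_loadings <- function(block_loadings) {
  df <- tidyr::separate(block_loadings, "block", into = c("net_a", "net_b"),
                        sep = "-", remove = FALSE)
  nets <- sort(unique(c(df$net_a, df$net_b)))
  df$net_a <- factor(df$net_a, levels = nets)
  df$net_b <- factor(df$net_b, levels = nets)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$net_a, y = .data$net_b,
                                   fill = .data$sum_abs_loading)) +
    ggplot2::geom_tile(color = "white") +
    ggplot2::scale_fill_viridis_c(name = "sum |loading|") +
    ggplot2::labs(x = NULL, y = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' Path diagram summary of a mediation fit
#'
#' @param x A `mediation_fit`.
#' @return A ggplot showing the a/b paths, direct, indirect and total
#'   effects with their bootstrap CIs as a forest-style plot.
#' @export
plot_mediation <- function(x) {
  stopifnot(inherits(x, "mediation_fit"))
  df <- dplyr::filter(x$estimates, .data$term != "prop_mediated")
  df$term <- factor(df$term, levels = rev(c("a", "b", "c_prime",
                                            "indirect", "total")))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$estimate, y = .data$term)) +
    ggplot2::geom_vline(xintercept = 0, linetype = 2, color = "grey60") +
    ggplot2::geom_pointrange(ggplot2::aes(xmin = .data$ci_lo,
                                          xmax = .data$ci_hi)) +
    ggplot2::labs(x = "standardized effect (95% bootstrap CI)", y = NULL) +
    ggplot2::theme_minimal()
}
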