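#' Default network size profile for a 10-network parcellation
#'
#' Region counts per resting-state network for a cortical/subcortical
#' parcellation of `n_roi` regions assigned to ten canonical large-scale
#' networks (SMN, CON, AUD, DMN, VIS, FPN, SAN, SUB, VAN, DAN). At the
#' default 227 regions the profile follows the network assignment counts of
#' the Power functional atlas after dropping unassigned and cerebellar
#' nodes; for other sizes the profile is scaled proportionally with
#' largest-remainder rounding so the counts still sum to `n_roi`.
#'
#' @param n_roi Total number of regions.
#' @return Named integer vector of length 10 summing to `n_roi`.
#' @export
#' @examples
#' default_network_sizes(227)
default_network_sizes <- function(n_roi = 227) {
  base <- c(SMN = 35, CON = 14, AUD = 13, DMN = 58, VIS = 31,
            FPN = 25, SAN = 18, SUB = 13, VAN = 9, DAN = 11)
  if (n_roi == 227L) return(base)
  if (n_roi < 10) abort("need at least one ROI per network (n_roi >= 10)")
  raw <- base / sum(base) * n_roi
  sizes <- pmax(floor(raw), 1)
  rem <- n_roi - sum(sizes)
  if (rem > 0) {
    extra <- order(raw - floor(raw), decreasing = TRUE)
    # stable largest-remainder top-up
    idx <- rep_len(extra, rem)
    for (i in idx) sizes[i] <- sizes[i] + 1
  } else if (rem < 0) {
    shrink <- order(sizes, decreasing = TRUE)
    i <- 1
    while (rem < 0) {
      j <- shrink[(i - 1) %% 10 + 1]
      if (sizes[j] > 1) { sizes[j] <- sizes[j] - 1; rem <- rem + 1 }
      i <- i + 1
    }
  }
  stats::setNames(as.integer(sizes), names(base))
}

#' Build an atlas table with network labels and nominal coordinates
#'
#' Creates the region-of-interest (ROI) metadata table the rest of the
#' pipeline keys on: unique contiguous `roi_id`, a network label for every
#' ROI, and a nominal 3-D coordinate (metadata only; no spatial model is
#' attached to it). ROIs are ordered by network, so edge/block bookkeeping
#' downstream is reproducible bit-for-bit.
#'
#' @param n_roi Total ROI count (default 227).
#' @param network_sizes Named vector mapping the 10 network names to ROI
#'   counts; must sum to `n_roi`. Defaults to [default_network_sizes()].
#' @param seed Integer seed controlling the (cosmetic) coordinates.
#' @return A tibble with columns `roi_id`, `x`, `y`, `z`, `network`.
#' @export
#' @examples
#' atlas <- make_atlas(20, network_sizes = default_network_sizes(20))
#' dplyr::count(atlas, network)
make_atlas <- function(n_roi = 227, network_sizes = default_network_sizes(n_roi),
                       seed = 1) {
  expected <- names(default_network_sizes(227))
  if (!setequal(names(network_sizes), expected)) {
    abort("network_sizes must name exactly the 10 canonical networks")
  }
  network_sizes <- network_sizes[expected]
  if (sum(network_sizes) != n_roi) {
    abort(sprintf("network sizes sum to %d, not n_roi = %d",
                  sum(network_sizes), n_roi))
  }
  coords <- with_seed_if(seed, matrix(stats::runif(3 * n_roi, -70, 70), ncol = 3))
  tibble::tibble(
    roi_id = seq_len(n_roi),
    x = round(coords[, 1], 1),
    y = round(coords[, 2], 1),
    z = round(coords[, 3], 1),
    network = rep(names(network_sizes), times = network_sizes)
  )
}

#' Edge index for the upper triangle of the connectivity matrix
#'
#' Enumerates all ROI pairs (i < j) in row-major upper-triangle order and
#' labels each edge with its network block: the unordered pair of the two
#' ROIs' networks, written `A-B` with networks in alphabetical order
#' (within-network edges are `A-A`). A 10-network atlas yields 55 distinct
#' blocks (10 within + 45 between).
#'
#' @param atlas Atlas tibble from [make_atlas()].
#' @return Tibble with `edge_id`, `roi_i`, `roi_j`, `net_i`, `net_j`,
#'   `block`, `within`.
#' @export
#' @examples
#' ei <- edge_index(make_atlas(10, default_network_sizes(10)))
#' nrow(ei)  # 45 edges
edge_index <- function(atlas) {
  stopifnot(all(c("roi_id", "network") %in% names(atlas)))
  n <- nrow(atlas)
  if (!identical(as.integer(atlas$roi_id), seq_len(n))) {
    abort("atlas roi_id must be contiguous from 1")
  }
  i <- rep(seq_len(n - 1), times = (n - 1):1)
  j <- unlist(lapply(seq_len(n - 1), function(k) (k + 1):n), use.names = FALSE)
  net_i <- atlas$network[i]
  net_j <- atlas$network[j]
  lo <- pmin(net_i, net_j)
  hi <- pmax(net_i, net_j)
  tibble::tibble(
    edge_id = seq_along(i),
    roi_i = i, roi_j = j,
    net_i = net_i, net_j = net_j,
    block = paste(lo, hi, sep = "-"),
    within = net_i == net_j
  )
}

#' All 55 network block labels of a 10-network atlas
#' @param networks Character vector of network names.
#' @return Character vector of block labels (within first ordering not
#'   imposed; sorted alphabetically).
#' @keywords internal
all_block_labels <- function(networks = names(default_network_sizes(227))) {
  networks <- sort(unique(networks))
  cmb <- utils::combn(networks, 2)
  sort(c(paste(networks, networks, sep = "-"), paste(cmb[1, ], cmb[2, ], sep = "-")))
}
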