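#' Binary directed network container
#'
#' @param adjacency square 0/1 matrix, zero diagonal; entry (i, j) = 1 means
#'   a directed link i -> j.
#' @param node_labels character labels (defaults to the dimnames, else
#'   `N1..Nn`).
#' @return object of class `directed_network`.
#' @export
directed_network <- function(adjacency, node_labels = NULL) {
  A <- as_square_matrix(adjacency, "adjacency")
  if (!all(A %in% c(0, 1))) stop("adjacency must be binary")
  if (any(diag(A) != 0)) stop("self-loops are not allowed")
  storage.mode(A) <- "integer"
  n <- nrow(A)
  node_labels <- node_labels %||% rownames(A) %||% paste0("N", seq_len(n))
  if (length(node_labels) != n) stop("node_labels length mismatch")
  dimnames(A) <- list(node_labels, node_labels)
  structure(list(adjacency = A, node_labels = as.character(node_labels)),
            class = "directed_network")
}

#' @export
print.directed_network <- function(x, ...) {
  A <- x$adjacency
  nbi <- sum(A * t(A)) / 2
  cat(sprintf("directed_network: %d nodes, %d directed links (%d mutual dyads)\n",
              nrow(A), sum(A), nbi))
  invisible(x)
}

net_adjacency <- function(net) {
  if (inherits(net, "directed_network")) net$adjacency else
    directed_network(net)$adjacency
}

#' Binarize a PTE matrix at a threshold
#'
#' Strict-inequality rule: a directed link X -> Y is set iff
#' `PTE_XY > tau`. If both `PTE_XY > tau` and `PTE_YX > tau` the pair is
#' bi-directional (stored as two opposing directed links); with
#' `PTE_XY > tau >= PTE_YX` only the X -> Y link is set.
#'
#' @param pte a [pte_matrix_obj()] or square weight matrix.
#' @param tau finite threshold.
#' @return a [directed_network()].
#' @export
threshold_network <- function(pte, tau) {
  if (!is.finite(tau)) stop("tau must be finite")
  V <- pte_values(pte)
  A <- (V > tau) * 1L
  diag(A) <- 0L
  labels <- if (inherits(pte, "pte_matrix")) pte$region_labels else
    rownames(V)
  directed_network(A, labels)
}

#' Lower threshold of the network interval (distribution percentile)
#'
#' Nearest-rank percentile of the off-diagonal PTE values: the
#' `ceiling(p * M)`-th smallest of the `M = N(N-1)` entries. Thresholding at
#' the returned value with the strict rule retains the top `1 - p` fraction
#' of links (exactly, when all values are distinct); for a 78-node matrix
#' with 6006 distinct values and `percentile = 0.30` the thresholded
#' network keeps 4204 directed links. `percentile <= 0` returns a sentinel
#' below the minimum so the full graph is retained.
#'
#' @param pte a [pte_matrix_obj()], square matrix, or bare numeric vector of
#'   link weights.
#' @param percentile fraction in `[0, 1)`; default 0.30.
#' @return threshold value.
#' @export
find_tau_min <- function(pte, percentile = 0.30) {
  v <- if (is.numeric(pte) && is.null(dim(pte))) as.numeric(pte) else
    off_diagonal(pte_values(pte))
  if (length(unique(v)) < 2L) {
    stop("degenerate input: fewer than 2 distinct off-diagonal values")
  }
  if (percentile <= 0) return(min(v) - 1)
  if (percentile >= 1) stop("percentile must be < 1")
  k <- ceiling(percentile * length(v))
  sort(v, partial = k)[k]
}

#' Upper threshold of the network interval (weak-connectivity limit)
#'
#' Scans the sorted distinct off-diagonal weights and returns the largest
#' candidate threshold whose network still has no isolated nodes and is
#' weakly connected. As the threshold rises, links are only removed, so
#' weak connectivity is monotone and the scan is a binary search. The
#' returned value is the weight of the link whose removal precedes the
#' first disconnection.
#'
#' @param pte a [pte_matrix_obj()] or square weight matrix.
#' @return threshold value.
#' @export
find_tau_max <- function(pte) {
  V <- pte_values(pte)
  vals <- sort(unique(off_diagonal(V)))
  ok <- function(tau) {
    A <- (V > tau)
    diag(A) <- FALSE
    is_weakly_connected(A)
  }
  if (!ok(vals[1L] - 1)) {
    stop("the full graph is not weakly connected; no valid threshold exists")
  }
  if (!ok(vals[1L])) {
    stop("no valid threshold: removing the weakest link already disconnects the network")
  }
  lo <- 1L
  hi <- length(vals)
  if (ok(vals[hi])) return(vals[hi]) # cannot happen for finite graphs w/ links
  while (hi - lo > 1L) {
    mid <- (lo + hi) %/% 2L
    if (ok(vals[mid])) lo <- mid else hi <- mid
  }
  vals[lo]
}

#' The threshold interval [tau_min, tau_max]
#'
#' @param pte a [pte_matrix_obj()] or square weight matrix.
#' @param percentile percentile for [find_tau_min()].
#' @param tau_min,tau_max optional explicit overrides.
#' @return object of class `threshold_interval` with fields `tau_min`,
#'   `tau_max`, `percentile_used`.
#' @export
threshold_interval <- function(pte, percentile = 0.30,
                               tau_min = NULL, tau_max = NULL) {
  tmin <- tau_min %||% find_tau_min(pte, percentile)
  tmax <- tau_max %||% find_tau_max(pte)
  if (!(tmin < tmax)) {
    stop(sprintf("invalid interval: tau_min (%.6g) must be below tau_max (%.6g)",
                 tmin, tmax))
  }
  structure(list(tau_min = tmin, tau_max = tmax,
                 percentile_used = if (is.null(tau_min)) percentile else NA_real_),
            class = "threshold_interval")
}

#' @export
print.threshold_interval <- function(x, ...) {
  cat(sprintf("threshold_interval: [%.6g, %.6g]\n", x$tau_min, x$tau_max))
  invisible(x)
}

#' Summary properties of a binary directed network
#'
#' Counts uni-directional links (ordered pairs with exactly one direction)
#' and bi-directional links (unordered pairs with both directions), and
#' derives average degree `(n_uni + 2 n_bi) / N`, link density
#' `(n_uni + 2 n_bi) / (N (N - 1))`, and degree assortativity. The
#' assortativity is the Pearson correlation, over directed links, of an
#' endpoint degree pairing: `"total-total"` (default) correlates the total
#' degree of the source with the total degree of the target; `"out-in"`
#' correlates source out-degree with target in-degree.
#'
#' @param net a [directed_network()].
#' @param assortativity_mode `"total-total"` or `"out-in"`.
#' @return object of class `network_properties` with fields `n_uni`,
#'   `n_bi`, `n_links` (directed link count), `avg_degree`, `link_density`,
#'   `assortativity` (`NA` when undefined, e.g. the empty network).
#' @export
network_properties <- function(net,
                               assortativity_mode = c("total-total", "out-in")) {
  assortativity_mode <- match.arg(assortativity_mode)
  A <- net_adjacency(net)
  n <- nrow(A)
  mutual <- A * t(A)
  n_bi <- sum(mutual) / 2
  n_links <- sum(A)
  n_uni <- n_links - 2 * n_bi
  avg_degree <- n_links / n
  link_density <- if (n > 1L) n_links / (n * (n - 1L)) else 0
  assort <- NA_real_
  if (n_links >= 2) {
    e <- which(A == 1L, arr.ind = TRUE)
    deg_out <- rowSums(A)
    deg_in <- colSums(A)
    if (assortativity_mode == "total-total") {
      xs <- (deg_out + deg_in)[e[, 1L]]
      ys <- (deg_out + deg_in)[e[, 2L]]
    } else {
      xs <- deg_out[e[, 1L]]
      ys <- deg_in[e[, 2L]]
    }
    if (stats::sd(xs) > 0 && stats::sd(ys) > 0) {
      assort <- stats::cor(xs, ys)
    }
  }
  structure(list(n_uni = as.integer(n_uni), n_bi = as.integer(n_bi),
                 n_links = as.integer(n_links), n_nodes = n,
                 avg_degree = avg_degree, link_density = link_density,
                 assortativity = assort,
                 assortativity_mode = assortativity_mode),
            class = "network_properties")
}

#' @export
print.network_properties <- function(x, ...) {
  cat(sprintf(paste0(
    "network_properties (%d nodes)\n",
    "  uni-directional links : %d\n",
    "  bi-directional links  : %d\n",
    "  average degree        : %.3f\n",
    "  link density          : %.3f\n",
    "  assortativity (%s): %s\n"),
    x$n_nodes, x$n_uni, x$n_bi, x$avg_degree, x$link_density,
    x$assortativity_mode,
    if (is.na(x$assortativity)) "undefined" else sprintf("%.3f", x$assortativity)))
  invisible(x)
}
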