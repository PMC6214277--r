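#' Motif adjacency matrix
#'
#' Symmetric nonnegative integer matrix whose entry (i, j) counts the
#' node-disjoint instances of the chosen motif in which i and j participate
#' together (two instances are node-disjoint when their node sets differ).
#' The motif degree `d_ii = sum_j w_ij` defines the diagonal degree matrix
#' used by the normalized motif Laplacian
#' `L = I - D^{-1/2} W D^{-1/2}`.
#'
#' @param census a [motif_census()] (instances collected) or a
#'   `motif_census_from_instances()` object.
#' @param motif motif id (default 78).
#' @param n number of nodes; defaults to the census's.
#' @return object of class `motif_adjacency`: `w` (N x N matrix), `motif`,
#'   `node_labels`.
#' @export
motif_adjacency <- function(census, motif = 78L, n = NULL) {
  stopifnot(inherits(census, "motif_census"))
  n <- as.integer(n %||% census$n_nodes)
  inst <- census$instances[[as.character(motif)]]
  W <- matrix(0, n, n)
  if (!is.null(inst) && nrow(inst) > 0L) {
    pairs <- rbind(inst[, c(1L, 2L), drop = FALSE],
                   inst[, c(1L, 3L), drop = FALSE],
                   inst[, c(2L, 3L), drop = FALSE])
    idx <- (pmax(pairs[, 1L], pairs[, 2L]) - 1L) * n +
      pmin(pairs[, 1L], pairs[, 2L])
    cnt <- tabulate(idx, nbins = n * n)
    W[] <- cnt
    W <- W + t(W)  # counts were accumulated on one triangle only
  }
  labels <- census$node_labels %||% paste0("N", seq_len(n))
  dimnames(W) <- list(labels, labels)
  structure(list(w = W, motif = as.integer(motif), node_labels = labels),
            class = "motif_adjacency")
}

ma_values <- function(w) {
  if (inherits(w, "motif_adjacency")) w$w else as_square_matrix(w, "motif adjacency")
}

#' @export
print.motif_adjacency <- function(x, ...) {
  d <- rowSums(x$w)
  cat(sprintf("motif_adjacency (motif %d): %d nodes, %d participating\n",
              x$motif, nrow(x$w), sum(d > 0)))
  invisible(x)
}

resolve_nodes <- function(nodes, labels) {
  if (is.character(nodes)) {
    idx <- match(nodes, labels)
    if (anyNA(idx)) stop("unknown node label(s): ",
                         paste(nodes[is.na(idx)], collapse = ", "))
    idx
  } else {
    as.integer(nodes)
  }
}

#' Motif conductance of a bipartition
#'
#' `phi = cut / min(vol_1, vol_2)` on the motif adjacency matrix, where
#' `cut` sums `w_ij` over pairs split by the partition and `vol_a` sums the
#' motif degrees of one side: the ratio of motif instances cut by the
#' partition to the smaller side's preserved motif volume.
#'
#' @param w a [motif_adjacency()] or plain symmetric matrix.
#' @param part1,part2 disjoint non-empty node sets (indices or labels).
#' @return nonnegative scalar; errors when the smaller volume is zero.
#' @export
motif_conductance <- function(w, part1, part2) {
  W <- ma_values(w)
  labels <- rownames(W) %||% as.character(seq_len(nrow(W)))
  i1 <- resolve_nodes(part1, labels)
  i2 <- resolve_nodes(part2, labels)
  if (length(i1) == 0L || length(i2) == 0L) stop("both sets must be non-empty")
  if (length(intersect(i1, i2))) stop("the two sets must be disjoint")
  d <- rowSums(W)
  cutv <- sum(W[i1, i2])
  volmin <- min(sum(d[i1]), sum(d[i2]))
  if (volmin == 0) stop("zero minimum volume: a side holds no motif instances")
  cutv / volmin
}

## minimum-conductance sweep over prefixes of an ordering; returns the best
## split (prefix size, conductance)
sweep_prefixes <- function(W, ord) {
  n <- length(ord)
  d <- rowSums(W)
  total <- sum(d)
  ws <- numeric(nrow(W))  # ws[i] = sum of W[i, S] for current prefix S
  cutv <- 0
  vol1 <- 0
  phis <- rep(NA_real_, n - 1L)
  for (k in seq_len(n - 1L)) {
    i <- ord[k]
    cutv <- cutv + d[i] - 2 * ws[i]
    vol1 <- vol1 + d[i]
    ws <- ws + W[, i]
    mv <- min(vol1, total - vol1)
    phis[k] <- if (mv > 0) cutv / mv else Inf
  }
  phis
}

#' Spectral sweep partition by motif conductance
#'
#' Removes zero-motif-degree nodes as non-participants, forms the
#' normalized motif Laplacian `I - D^{-1/2} W D^{-1/2}` on the remainder,
#' orders the participating nodes by the `D^{-1/2}`-scaled eigenvector of
#' the second smallest eigenvalue (the raw ordering is also swept and the
#' better split kept), evaluates the motif conductance of every prefix
#' split of the ordering and returns the minimum. The returned conductance
#' satisfies `phi <= 4 * sqrt(phi*)` where `phi*` is the true minimum. A
#' motif-disconnected graph is handled by the same global sweep: the zero
#' eigenspace separates components under the scaled ordering, so a
#' zero-conductance split across components is found; the component count
#' is reported.
#'
#' Ties in eigenvector entries are broken by node index; ties in the
#' minimum conductance by the smaller first cluster, then lexicographically.
#'
#' @param w a [motif_adjacency()] or plain symmetric nonnegative matrix.
#' @return object of class `motif_partition`: `cluster1`, `cluster2`,
#'   `non_participants` (label vectors), `conductance`, `lambda2`,
#'   `n_components`, `refused = FALSE`.
#' @export
spectral_sweep <- function(w) {
  W <- ma_values(w)
  labels <- rownames(W) %||% as.character(seq_len(nrow(W)))
  d_all <- rowSums(W)
  part <- which(d_all > 0)
  if (length(part) < 3L) {
    stop("need at least 3 participating nodes (positive motif degree)")
  }
  Wp <- W[part, part, drop = FALSE]
  d <- rowSums(Wp)
  np <- length(part)
  comp <- components_undirected(Wp > 0)
  n_components <- max(comp)
  isd <- 1 / sqrt(d)
  L <- diag(np) - isd * t(isd * Wp)  # D^-1/2 W D^-1/2 symmetric
  eig <- eigen(L, symmetric = TRUE)
  v <- eig$vectors[, np - 1L]
  lambda2 <- eig$values[np - 1L]
  best <- NULL
  for (u in list(isd * v, v)) {
    ord <- order(u, seq_len(np))
    phis <- sweep_prefixes(Wp, ord)
    finite <- which(is.finite(phis))
    if (!length(finite)) next
    for (k in finite[phis[finite] == min(phis[finite])]) {
      n1 <- sort(part[ord[seq_len(k)]])
      cand <- list(phi = phis[k], n1 = n1)
      if (is.null(best) || cand$phi < best$phi ||
          (cand$phi == best$phi &&
           (length(cand$n1) < length(best$n1) ||
            (length(cand$n1) == length(best$n1) &&
             paste(cand$n1, collapse = ",") < paste(best$n1, collapse = ","))))) {
        best <- cand
      }
    }
  }
  if (is.null(best)) stop("sweep failed: no split with positive volumes")
  n1 <- best$n1
  n2 <- sort(setdiff(part, n1))
  ## orient deterministically: cluster1 holds the lowest participating index
  if (min(n2) < min(n1)) { tmp <- n1; n1 <- n2; n2 <- tmp }
  structure(list(cluster1 = labels[n1], cluster2 = labels[n2],
                 non_participants = labels[setdiff(seq_along(labels), part)],
                 conductance = best$phi, lambda2 = lambda2,
                 n_components = n_components,
                 motif = if (inherits(w, "motif_adjacency")) w$motif else NA_integer_,
                 refused = FALSE),
            class = "motif_partition")
}

#' @export
print.motif_partition <- function(x, ...) {
  if (isTRUE(x$refused)) {
    cat("motif_partition: refused -", x$reason, "\n")
    return(invisible(x))
  }
  cat(sprintf(
    "motif_partition: |cluster1| = %d, |cluster2| = %d, %d non-participant(s)\n",
    length(x$cluster1), length(x$cluster2), length(x$non_participants)))
  cat(sprintf("  motif conductance = %.6g (lambda2 = %.6g, %d component(s))\n",
              x$conductance, x$lambda2, x$n_components))
  invisible(x)
}

#' Link-resolved threshold set
#'
#' All thresholds strictly inside `(tau_min, tau_max]` at which the
#' thresholded network changes by exactly one directed link: with distinct
#' weights these are exactly the PTE values of the links removed one by one
#' as the threshold rises. Tied weights inside the interval violate the
#' one-link-per-step guarantee and raise an error by default; `ties =
#' "group"` keeps one threshold per distinct value (several links then drop
#' together).
#'
#' @param pte a [pte_matrix_obj()] or square weight matrix.
#' @param interval a [threshold_interval()].
#' @param ties `"error"` (default) or `"group"`.
#' @return object of class `threshold_set` (ascending numeric `thresholds`
#'   plus the interval).
#' @export
link_resolved_thresholds <- function(pte, interval,
                                     ties = c("error", "group")) {
  ties <- match.arg(ties)
  stopifnot(inherits(interval, "threshold_interval"))
  v <- off_diagonal(pte_values(pte))
  inside <- v[v > interval$tau_min & v <= interval$tau_max]
  if (anyDuplicated(inside) && ties == "error") {
    stop(paste("tied PTE values inside the interval violate the",
               "one-link-per-threshold guarantee; use ties = \"group\""))
  }
  structure(list(thresholds = sort(unique(inside)), interval = interval,
                 ties = ties),
            class = "threshold_set")
}

#' @export
print.threshold_set <- function(x, ...) {
  cat(sprintf("threshold_set: %d link-resolved thresholds in (%.6g, %.6g]\n",
              length(x$thresholds), x$interval$tau_min, x$interval$tau_max))
  invisible(x)
}

#' Aggregated motif adjacency matrix over a threshold set
#'
#' Elementwise sum of the motif adjacency matrices of the thresholded
#' networks over every threshold in the set. Motifs made of strong links
#' survive into more summands and therefore weigh more in the aggregate.
#'
#' @param pte a [pte_matrix_obj()] or square weight matrix.
#' @param t_set a [link_resolved_thresholds()] set (or numeric vector).
#' @param motif motif id (default 78).
#' @return a [motif_adjacency()] whose `w` holds the aggregate.
#' @export
aggregate_motif_adjacency <- function(pte, t_set, motif = 78L) {
  taus <- if (inherits(t_set, "threshold_set")) t_set$thresholds else
    as.numeric(t_set)
  if (length(taus) == 0L) stop("empty threshold set: nothing to aggregate")
  acc <- NULL
  for (tau in taus) {
    net <- threshold_network(pte, tau)
    cen <- motif_census(net)
    wm <- motif_adjacency(cen, motif = motif)
    acc <- if (is.null(acc)) wm$w else acc + wm$w
  }
  out <- structure(list(w = acc, motif = as.integer(motif),
                        node_labels = rownames(acc)),
                   class = "motif_adjacency")
  out
}

#' End-to-end motif-based clustering of a weighted connectivity matrix
#'
#' Composes the stages: threshold interval (percentile lower end,
#' weak-connectivity upper end, either overridable), link-resolved
#' threshold set, aggregated motif adjacency, and the spectral sweep. Nodes
#' with zero aggregated motif degree are reported as a separate third
#' (non-participating) group. When no node participates in any motif
#' instance (e.g. all strong links uni-directional for motif 78), the
#' partition is refused with an informative report rather than an error.
#'
#' @param pte a [pte_matrix_obj()] or square weight matrix.
#' @param motif motif id (default 78).
#' @param percentile lower-threshold percentile (default 0.30).
#' @param tau_min,tau_max optional explicit interval overrides.
#' @param ties tie handling for [link_resolved_thresholds()].
#' @param single_tau if non-`NULL`, skip aggregation and cluster the single
#'   network `G(single_tau)`.
#' @return a `motif_partition` (possibly with `refused = TRUE`); the
#'   aggregate matrix and threshold set are attached as attributes
#'   `"aggregate"` and `"threshold_set"`.
#' @export
cluster_pipeline <- function(pte, motif = 78L, percentile = 0.30,
                             tau_min = NULL, tau_max = NULL,
                             ties = c("error", "group"),
                             single_tau = NULL) {
  ties <- match.arg(ties)
  if (!is.null(single_tau)) {
    net <- threshold_network(pte, single_tau)
    wm <- motif_adjacency(motif_census(net), motif = motif)
    tset <- NULL
  } else {
    interval <- threshold_interval(pte, percentile, tau_min, tau_max)
    tset <- link_resolved_thresholds(pte, interval, ties = ties)
    if (length(tset$thresholds) == 0L) {
      stop("empty threshold interval: no link-resolved thresholds to aggregate")
    }
    wm <- aggregate_motif_adjacency(pte, tset, motif = motif)
  }
  d <- rowSums(wm$w)
  if (sum(d > 0) < 3L) {
    part <- structure(
      list(cluster1 = character(0), cluster2 = character(0),
           non_participants = wm$node_labels,
           conductance = NA_real_, lambda2 = NA_real_,
           n_components = 0L, motif = as.integer(motif), refused = TRUE,
           reason = sprintf(
             "only %d node(s) participate in any motif %d instance; a 2-way partition needs at least 3",
             sum(d > 0), as.integer(motif))),
      class = "motif_partition")
  } else {
    part <- spectral_sweep(wm)
  }
  attr(part, "aggregate") <- wm
  attr(part, "threshold_set") <- tset
  part
}
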