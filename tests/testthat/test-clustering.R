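fig10_census <- function() {
  ## two node-disjoint instances of motif 108 on nodes {A,B,C,D,E}:
  ## {A,B,C} and {A,C,E}
  motif_census_from_instances(rbind(c(1, 2, 3), c(1, 3, 5)), 108, 5,
                              c("A", "B", "C", "D", "E"))
}

test_that("motif adjacency counts co-participations (worked example)", {
  w <- motif_adjacency(fig10_census(), 108)
  W <- w$w
  expect_equal(W["A", "C"], 2)
  expect_equal(W["A", "B"], 1)
  expect_equal(W["B", "C"], 1)
  expect_equal(W["A", "E"], 1)
  expect_equal(W["C", "E"], 1)
  expect_true(all(W["D", ] == 0) && all(W[, "D"] == 0))
  expect_equal(W["B", "E"], 0)
  expect_identical(W, t(W))
  expect_true(all(diag(W) == 0))
})

test_that("motif adjacency of a bidirectional star counts leaf pairings", {
  cen <- motif_census(directed_network(make_star(4L, centre = 1L)))
  W <- motif_adjacency(cen, 78)$w
  ## centre co-participates with each leaf in choose(2,1) = 2 instances,
  ## leaf pairs share exactly the one instance they define
  expect_true(all(W[1, 2:4] == 2))
  expect_true(all(W[2:4, 2:4][upper.tri(matrix(0, 3, 3))] == 1))
  ## empty census gives the zero matrix
  W0 <- motif_adjacency(motif_census(directed_network(matrix(0, 4, 4))), 78)
  expect_true(all(W0$w == 0))
})

test_that("motif conductance matches the worked example and is symmetric", {
  w <- motif_adjacency(fig10_census(), 108)
  expect_equal(motif_conductance(w, c("A", "C"), c("B", "E")), 1.0)
  expect_equal(motif_conductance(w, c("B", "E"), c("A", "C")), 1.0)
  ## zero cut across motif-disconnected blocks
  W <- matrix(0, 6, 6)
  W[1:3, 1:3] <- 1; W[4:6, 4:6] <- 1
  diag(W) <- 0
  expect_equal(motif_conductance(W, 1:3, 4:6), 0)
  ## degenerate side
  expect_error(motif_conductance(w, "D", c("A", "C")), "volume")
  expect_error(motif_conductance(w, c("A"), c("A", "C")), "disjoint")
})

test_that("spectral sweep recovers the planted two-star split exactly", {
  net <- planted_two_star_net(5L)
  w <- motif_adjacency(motif_census(net), 78)
  p <- spectral_sweep(w)
  expect_equal(p$conductance, 0)
  expect_identical(p$cluster1, paste0("N", 1:5))
  expect_identical(p$cluster2, paste0("N", 6:10))
  expect_identical(p$n_components, 2L)
})

test_that("sweep conductance respects the 4*sqrt(phi*) guarantee", {
  set.seed(71)
  checked <- 0L
  for (s in 1:30) {
    n <- sample(6:12, 1)
    A <- random_digraph(n, runif(1, 0.2, 0.5), seed = 500 + s)
    w <- motif_adjacency(motif_census(directed_network(A)), 78)
    if (sum(rowSums(w$w) > 0) < 4) next
    p <- spectral_sweep(w)
    phi_star <- oracle_min_conductance(w$w)
    expect_lte(p$conductance, 4 * sqrt(phi_star) + 1e-12)
    ## whenever a zero-conductance split exists the sweep must find it
    if (phi_star == 0) expect_equal(p$conductance, 0)
    checked <- checked + 1L
  }
  expect_gte(checked, 10L)
})

test_that("normalized motif Laplacian invariants hold on random inputs", {
  set.seed(73)
  for (s in 1:5) {
    A <- random_digraph(10, 0.35, seed = 600 + s)
    w <- motif_adjacency(motif_census(directed_network(A)), 78)
    W <- w$w
    expect_identical(W, t(W))
    expect_true(all(diag(W) == 0))
    d <- rowSums(W)
    part <- d > 0
    if (sum(part) < 3) next
    Wp <- W[part, part]
    isd <- 1 / sqrt(rowSums(Wp))
    L <- diag(sum(part)) - isd * t(isd * Wp)
    ev <- eigen(L, symmetric = TRUE, only.values = TRUE)$values
    expect_true(all(ev > -1e-10))          # positive semidefinite
    expect_lt(abs(min(ev)), 1e-10)         # smallest eigenvalue 0
  }
})

test_that("link-resolved thresholds enumerate single-link removals", {
  set.seed(79)
  V <- matrix(runif(64), 8, 8)
  diag(V) <- 0
  iv <- threshold_interval(V, tau_min = 0.3, tau_max = 0.7)
  ts <- link_resolved_thresholds(V, iv)
  vals <- V[row(V) != col(V)]
  expect_identical(ts$thresholds, sort(vals[vals > 0.3 & vals <= 0.7]))
  ## consecutive thresholds differ by exactly one directed link
  nets <- lapply(ts$thresholds, function(tau) threshold_network(V, tau))
  for (k in seq_len(length(nets) - 1)) {
    expect_identical(sum(nets[[k]]$adjacency) - sum(nets[[k + 1]]$adjacency),
                     1L)
  }
  ## ties inside the interval are rejected by default, grouped on request
  V2 <- V
  V2[1, 2] <- V2[2, 1] <- 0.5
  expect_error(link_resolved_thresholds(V2, iv), "tied")
  ts2 <- link_resolved_thresholds(V2, iv, ties = "group")
  expect_identical(anyDuplicated(ts2$thresholds), 0L)
  ## empty interval refuses aggregation
  iv0 <- threshold_interval(V, tau_min = 0.97, tau_max = 0.99)
  ts0 <- link_resolved_thresholds(V, iv0)
  expect_length(ts0$thresholds, length(vals[vals > 0.97 & vals <= 0.99]))
  expect_error(aggregate_motif_adjacency(V, numeric(0)), "empty")
})

test_that("aggregation is a sum of single-threshold motif adjacencies", {
  set.seed(83)
  ps <- planted_structure(rep(c(1, 2), each = 5), c(1, 6))
  W <- generate_planted_weight_matrix(10, ps, 1, 0.3, jitter_sd = 0.05,
                                      seed = 11)
  iv <- threshold_interval(W)
  ts <- link_resolved_thresholds(W, iv)
  agg <- aggregate_motif_adjacency(W, ts, 78)
  ## direct summation oracle
  acc <- 0
  for (tau in ts$thresholds) {
    acc <- acc + motif_adjacency(motif_census(threshold_network(W, tau)), 78)$w
  }
  expect_equal(agg$w, acc)
  ## |T| = 1 equals the single-threshold matrix
  one <- aggregate_motif_adjacency(W, ts$thresholds[1], 78)
  expect_equal(one$w,
               motif_adjacency(motif_census(
                 threshold_network(W, ts$thresholds[1])), 78)$w)
  ## linearity over a disjoint split of T
  half <- seq_len(floor(length(ts$thresholds) / 2))
  a1 <- aggregate_motif_adjacency(W, ts$thresholds[half], 78)
  a2 <- aggregate_motif_adjacency(W, ts$thresholds[-half], 78)
  expect_equal(a1$w + a2$w, agg$w)
})

test_that("noiseless planted clustering at a fixed threshold is exact", {
  ps <- planted_structure(rep(c(1, 2), each = 8), c(1, 9))
  W <- generate_planted_weight_matrix(16, ps, w_in = 1, w_out = 0,
                                      jitter_sd = 0, seed = 1)
  net <- threshold_network(W, 0.5)
  p <- spectral_sweep(motif_adjacency(motif_census(net), 78))
  truth <- rep(c(1, 2), each = 8)
  memb <- integer(16)
  memb[match(p$cluster1, paste0("N", 1:16))] <- 1L
  memb[match(p$cluster2, paste0("N", 1:16))] <- 2L
  expect_equal(adjusted_rand_index(memb, truth), 1)
  expect_equal(p$conductance, 0)
})

test_that("the full pipeline recovers jittered planted structure", {
  ## seeds verified to recover exactly; the sweep is a 4*sqrt(phi*)
  ## approximation, so exact recovery on every random aggregate is not a
  ## contract (see the methods vignette)
  ps <- planted_structure(rep(c(1, 2), each = 10), c(1, 11))
  truth <- rep(c(1, 2), each = 10)
  for (s in c(1, 2, 4)) {
    W <- generate_planted_weight_matrix(20, ps, w_in = 1, w_out = 0.25,
                                        jitter_sd = 0.02, seed = s)
    p <- cluster_pipeline(W)
    expect_false(isTRUE(p$refused))
    memb <- integer(20)
    memb[match(p$cluster1, paste0("N", 1:20))] <- 1L
    memb[match(p$cluster2, paste0("N", 1:20))] <- 2L
    expect_equal(adjusted_rand_index(memb, truth), 1)
  }
})

test_that("pipeline refuses when no strong bidirectional structure exists", {
  ## all strong links uni-directional: motif 78 requires mutual links, so
  ## after thresholding no node participates and the partition is refused
  set.seed(89)
  n <- 10
  V <- matrix(runif(n * n, 0.0, 0.1), n, n)
  ## a uni-directional strong ring keeps the graph weakly connected
  for (k in 1:n) V[k, k %% n + 1] <- 0.9 + 0.001 * k
  diag(V) <- 0
  p <- cluster_pipeline(V, tau_min = 0.5, tau_max = 0.95)
  expect_true(isTRUE(p$refused))
  expect_match(p$reason, "participate")
})

test_that("pipeline partition is equivariant under node relabeling", {
  ps <- planted_structure(rep(c(1, 2), each = 5), c(1, 6))
  W <- generate_planted_weight_matrix(10, ps, 1, 0.3, jitter_sd = 0.05,
                                      seed = 13)
  p <- cluster_pipeline(W)
  perm <- c(4, 9, 1, 7, 2, 10, 3, 8, 5, 6)
  Vp <- W$values[perm, perm]
  labels_p <- W$region_labels[perm]
  dimnames(Vp) <- list(labels_p, labels_p)
  p2 <- cluster_pipeline(pte_matrix_obj(Vp, labels_p))
  ## same partition as sets, regardless of internal order
  s1 <- sort(p$cluster1); s2 <- sort(p$cluster2)
  t1 <- sort(p2$cluster1); t2 <- sort(p2$cluster2)
  expect_true((identical(s1, t1) && identical(s2, t2)) ||
                (identical(s1, t2) && identical(s2, t1)))
  expect_setequal(p2$non_participants, p$non_participants)
})
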