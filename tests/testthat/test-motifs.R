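test_that("canonical ids match the worked examples and the oracle", {
  star <- matrix(0, 3, 3)
  star[1, 3] <- star[3, 1] <- star[2, 3] <- star[3, 2] <- 1
  expect_identical(canonical_motif_id(star), 78L)

  chain <- matrix(0, 3, 3)
  chain[1, 2] <- chain[2, 3] <- 1
  expect_identical(canonical_motif_id(chain), 12L)
  expect_identical(canonical_motif_id(chain), as.integer(oracle_canonical(chain)))

  tri <- matrix(1, 3, 3) - diag(3)
  expect_identical(canonical_motif_id(tri), 238L)

  expect_error(canonical_motif_id(diag(3)), "diagonal")
})

test_that("canonical id is invariant under relabeling", {
  set.seed(51)
  perms <- list(c(1, 2, 3), c(1, 3, 2), c(2, 1, 3),
                c(2, 3, 1), c(3, 1, 2), c(3, 2, 1))
  for (rep in 1:25) {
    A <- matrix(rbinom(9, 1, 0.5), 3, 3)
    diag(A) <- 0
    ids <- vapply(perms, function(p) canonical_motif_id(A[p, p]), integer(1))
    expect_identical(length(unique(ids)), 1L)
    expect_identical(ids[1], as.integer(oracle_canonical(A)))
  }
})

test_that("the 13 connected 3-motif classes are enumerated", {
  ids <- enumerate_3motifs()
  expect_length(ids, 13L)
  expect_true(all(c(6L, 14L, 74L, 78L, 102L, 108L) %in% ids))
  expect_identical(ids, c(6L, 12L, 14L, 36L, 38L, 46L, 74L, 78L,
                          98L, 102L, 108L, 110L, 238L))
})

test_that("census classifies worked examples and degenerate cases", {
  ## single instance: 1 <-> 3 <-> 2
  A <- matrix(0L, 3, 3)
  A[1, 3] <- A[3, 1] <- A[2, 3] <- A[3, 2] <- 1L
  cen <- motif_census(directed_network(A))
  expect_identical(unname(cen$counts[["78"]]), 1L)
  expect_identical(sum(cen$counts), 1L)

  ## bidirectional star with 3 leaves: one instance per leaf pair
  cen_star <- motif_census(directed_network(make_star(4L, centre = 1L)))
  expect_identical(unname(cen_star$counts[["78"]]), 3L)

  ## empty network
  cen0 <- motif_census(directed_network(matrix(0, 5, 5)))
  expect_identical(sum(cen0$counts), 0L)
  expect_length(cen0$instances, 0L)
})

test_that("census equals the brute-force all-subsets oracle", {
  set.seed(57)
  cases <- data.frame(n = c(6, 9, 12, 20, 30), p = c(0.5, 0.4, 0.3, 0.2, 0.1))
  for (k in seq_len(nrow(cases))) {
    A <- random_digraph(cases$n[k], cases$p[k], seed = 200 + k)
    cen <- motif_census(directed_network(A))
    expected <- oracle_census(A)
    got <- cen$counts[cen$counts > 0]
    compare_census(got, expected)
    ## total = number of connected 3-subsets; instance lists match counts
    expect_identical(sum(cen$counts), sum(expected))
    lens <- vapply(cen$instances, nrow, integer(1))
    expect_identical(unname(lens[names(got)]), unname(got))
  }
})

test_that("removing one uni-directional link from the two-hop path motif
           degenerates it to ids 14 and 74", {
  star <- matrix(0, 3, 3)
  star[1, 3] <- star[3, 1] <- star[2, 3] <- star[3, 2] <- 1
  ids <- integer(0)
  for (e in which(star == 1)) {
    B <- star
    B[e] <- 0
    ids <- c(ids, canonical_motif_id(B))
  }
  expect_identical(sort(unique(ids)), c(14L, 74L))
})

test_that("apex-ratio distinguishes hub, leaf and non-participant", {
  A <- make_star(5L, centre = 2L)
  A <- rbind(cbind(A, 0), 0)  # add isolated node 6
  cen <- motif_census(directed_network(A))
  r <- apex_ratio(cen)
  expect_equal(unname(r[2]), 1)            # centre is always the apex
  expect_equal(unname(r[1]), 0)            # leaves participate, never apex
  expect_true(is.na(r[6]))                 # isolated: undefined
  expect_error(apex_ratio(cen, motif = 14), "apex")
})

test_that("high-degree rule uses mean plus one population sd", {
  ## hub of total degree 10 among degree-2 leaves: hub clears
  ## mean + one population sd, leaves do not
  A <- matrix(0L, 7, 7)
  A[7, 1:5] <- 1L; A[1:5, 7] <- 1L    # hub 7: degree 10, leaves 1..5: 2
  A[6, 1] <- 1L; A[1, 6] <- 1L        # node 6: degree 2 (node 1 -> 4)
  net <- directed_network(A)
  deg <- rowSums(A) + colSums(A)
  thr <- mean(deg) + sqrt(mean((deg - mean(deg))^2))
  hubs <- high_degree_nodes(net)
  expect_identical(hubs, net$node_labels[deg >= thr])
  expect_identical(hubs, "N7")
  ## regular network: sd = 0, every node qualifies
  ring <- matrix(0L, 5, 5)
  ring[cbind(1:5, c(2:5, 1))] <- 1L
  expect_length(high_degree_nodes(directed_network(ring)), 5L)
  ## empty network: no hubs
  expect_length(high_degree_nodes(directed_network(matrix(0, 3, 3))), 0L)
})

test_that("apex-degree correlation handles perfect, degenerate and planted cases", {
  ## perfect linearity: ratios proportional to degree on qualifying nodes
  A <- make_star(6L, centre = 1L)
  net <- directed_network(A)
  ratios <- c(0.2, 0.4, 0.6, 0.8, 1.0, 0.5)
  names(ratios) <- net$node_labels
  deg <- rowSums(A) + colSums(A)
  ratios[] <- deg / max(deg)  # exactly proportional
  expect_equal(apex_degree_correlation(ratios, net), 1)
  ## constant ratios: zero variance -> undefined
  const <- ratios; const[] <- 0.5
  expect_true(is.na(apex_degree_correlation(const, net)))
  ## fewer than 3 positive ratios -> undefined
  few <- ratios; few[] <- 0; few[1] <- 1; few[2] <- 0.5
  expect_true(is.na(apex_degree_correlation(few, net)))
  ## planted hub chain: three bidirectional hubs of decreasing degree
  ## (1 <-> 2 <-> 3 with 4, 2 and 1 private leaves) give apex-ratios that
  ## decrease with degree -> strictly positive correlation over the three
  ## positive-ratio nodes
  C <- matrix(0L, 10, 10)
  link <- function(M, i, j) { M[i, j] <- 1L; M[j, i] <- 1L; M }
  C <- link(C, 1, 2); C <- link(C, 2, 3)
  for (leaf in 4:7) C <- link(C, 1, leaf)
  for (leaf in 8:9) C <- link(C, 2, leaf)
  C <- link(C, 3, 10)
  net2 <- directed_network(C)
  cen2 <- motif_census(net2)
  r2 <- apex_ratio(cen2)
  expect_identical(names(which(!is.na(r2) & r2 > 0)), c("N1", "N2", "N3"))
  expect_gt(apex_degree_correlation(r2, net2), 0)
})

test_that("z-scores follow the overexpression formula", {
  null <- structure(list(motif_ids = c(14L, 78L),
                         j_original = c(`14` = 5L, `78` = 110L),
                         mu = c(`14` = 5, `78` = 100),
                         sigma = c(`14` = 0, `78` = 5),
                         p_exceed = c(`14` = 0.5, `78` = 0.002),
                         n_random = 1000L),
                    class = "null_summary")
  expect_equal(motif_zscore(110, null, 78), 2)
  expect_equal(motif_zscore(100, null, 78), 0)
  expect_true(is.na(motif_zscore(5, null, 14)))   # sigma = 0 flagged
  expect_error(motif_zscore(1, null, 99), "unknown")
})

test_that("overexpression needs all three criteria", {
  mk_null <- function(mu, p) {
    ids <- enumerate_3motifs()
    structure(list(motif_ids = ids,
                   j_original = stats::setNames(integer(13), ids),
                   mu = stats::setNames(rep(mu, 13), ids),
                   sigma = stats::setNames(rep(1, 13), ids),
                   p_exceed = stats::setNames(rep(p, 13), ids),
                   n_random = 1000L),
              class = "null_summary")
  }
  mk_census <- function(count78) {
    motif_census_from_instances(
      matrix(rep(1:3, count78), ncol = 3, byrow = TRUE), 78, 10)
  }
  pick78 <- function(calls) calls[calls$motif_id == 78, ]
  ## all pass: p = 0.005, count = 10, ratio = 10/8 = 1.25
  expect_true(pick78(call_overexpression(mk_census(10), mk_null(8, 0.005)))$overexpressed)
  ## count criterion fails at 3 occurrences despite p and ratio
  expect_false(pick78(call_overexpression(mk_census(3), mk_null(1.5, 0.005)))$overexpressed)
  ## ratio criterion fails at 1.05
  expect_false(pick78(call_overexpression(mk_census(21), mk_null(20, 0.005)))$overexpressed)
  ## p criterion fails at 0.05
  expect_false(pick78(call_overexpression(mk_census(10), mk_null(8, 0.05)))$overexpressed)
  ## zero null mean with positive count passes the ratio, flagged
  calls <- call_overexpression(mk_census(10), mk_null(0, 0.005))
  row78 <- pick78(calls)
  expect_true(row78$overexpressed)
  expect_identical(row78$flag, "null-mean-zero")
})
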