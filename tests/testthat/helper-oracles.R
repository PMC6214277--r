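## Independent oracles for the dual-route checks. These deliberately avoid
## the package's code paths: canonical ids via string/bit conversion,
## connectivity via igraph, census by per-subset classification,
## conductance by exhaustive enumeration.

oracle_code <- function(A) {
  strtoi(paste(as.integer(t(A)), collapse = ""), base = 2L)
}

oracle_canonical <- function(A) {
  perms <- list(c(1, 2, 3), c(1, 3, 2), c(2, 1, 3),
                c(2, 3, 1), c(3, 1, 2), c(3, 2, 1))
  min(vapply(perms, function(p) oracle_code(A[p, p]), numeric(1)))
}

oracle_weakly_connected <- function(A) {
  g <- igraph::graph_from_adjacency_matrix(A, mode = "directed")
  igraph::is_connected(g, mode = "weak")
}

## classify every 3-subset independently; returns named count vector.
## connectivity = "igraph" uses the igraph oracle (slower); "fast" checks
## two-step reachability on the symmetrized 3x3 matrix directly.
oracle_census <- function(A, connectivity = c("igraph", "fast")) {
  connectivity <- match.arg(connectivity)
  conn3 <- if (connectivity == "igraph") {
    oracle_weakly_connected
  } else {
    function(B) {
      M <- ((B + t(B)) > 0) + diag(3)
      all(M %*% M > 0)
    }
  }
  n <- nrow(A)
  out <- integer(0)
  if (n < 3) return(out)
  subsets <- utils::combn(n, 3)
  for (k in seq_len(ncol(subsets))) {
    s <- subsets[, k]
    B <- A[s, s]
    if (!conn3(B)) next
    id <- as.character(oracle_canonical(B))
    out[id] <- (if (is.na(out[id])) 0L else out[id]) + 1L
  }
  out[order(as.integer(names(out)))]
}

## compare a package census (nonzero counts, named) with an oracle census,
## tolerant of the empty case's name attribute
compare_census <- function(got, expected) {
  if (length(expected) == 0) {
    testthat::expect_length(got, 0)
  } else {
    testthat::expect_identical(got[order(as.integer(names(got)))], expected)
  }
}

## exhaustive minimum motif conductance over all bipartitions of the
## participating nodes of W
oracle_min_conductance <- function(W) {
  d <- rowSums(W)
  part <- which(d > 0)
  np <- length(part)
  stopifnot(np >= 2, np <= 20)
  Wp <- W[part, part, drop = FALSE]
  dp <- rowSums(Wp)
  total <- sum(dp)
  best <- Inf
  for (mask in 1:(2^(np - 1) - 1)) {  # fix node np in side 2: halves the work
    s1 <- which(bitwAnd(mask, 2^(seq_len(np) - 1)) > 0)
    s2 <- setdiff(seq_len(np), s1)
    v1 <- sum(dp[s1])
    mv <- min(v1, total - v1)
    if (mv == 0) next
    phi <- sum(Wp[s1, s2]) / mv
    if (phi < best) best <- phi
  }
  best
}

## plug-in conditional entropy H(Xf | Xn) over binned sequences (natural log)
oracle_cond_entropy <- function(xf, xn, nb) {
  m <- length(xf)
  h <- 0
  for (a in 1:nb) for (b in 1:nb) {
    p_ab <- sum(xf == a & xn == b) / m
    if (p_ab > 0) {
      p_b <- sum(xn == b) / m
      h <- h - p_ab * log(p_ab / p_b)
    }
  }
  h
}

adjusted_rand_index <- function(a, b) {
  tab <- table(a, b)
  n <- sum(tab)
  sij <- sum(choose(tab, 2))
  si <- sum(choose(rowSums(tab), 2))
  sj <- sum(choose(colSums(tab), 2))
  e <- si * sj / choose(n, 2)
  (sij - e) / ((si + sj) / 2 - e)
}

random_digraph <- function(n, p, seed) {
  set.seed(seed)
  A <- matrix(rbinom(n * n, 1, p), n, n)
  diag(A) <- 0
  A
}

## bidirectional star: centre linked both ways to every leaf
make_star <- function(n, centre = 1L) {
  A <- matrix(0L, n, n)
  leaves <- setdiff(seq_len(n), centre)
  A[centre, leaves] <- 1L
  A[leaves, centre] <- 1L
  A
}

## two bidirectional k-stars plus uni-directional links placed only BETWEEN
## the stars (leaf -> leaf): no observed two-hop-path instance is spoiled,
## while rewiring relocates uni links into within-star (spoiling)
## positions, so the motif is genuinely overexpressed against the null
rich_motif78_net <- function(k = 7L) {
  n <- 2L * k
  A <- matrix(0L, n, n)
  A[1:k, 1:k] <- make_star(k)
  A[(k + 1):n, (k + 1):n] <- make_star(k)
  l1 <- 2:k
  l2 <- (k + 2):n
  m <- k - 1L
  for (i in seq_len(m)) {
    A[l1[i], l2[i]] <- 1L
    A[l2[i], l1[(i %% m) + 1L]] <- 1L
    A[l1[i], l2[(i %% m) + 1L]] <- 1L
  }
  directed_network(A)
}

planted_two_star_net <- function(k = 5L) {
  ## two k-node bidirectional stars joined by one uni-directional link
  n <- 2L * k
  A <- matrix(0L, n, n)
  A[1:k, 1:k] <- make_star(k)
  A[(k + 1):n, (k + 1):n] <- make_star(k)
  A[k, k + 1L] <- 1L  # bridge: participates in no bi-directional 2-hop path
  directed_network(A)
}
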