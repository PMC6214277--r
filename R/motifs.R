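## ---- canonical 3-node motif identification -------------------------------
##
## A 3-node digraph (no self-loops) is read row-major as a 9-bit integer
## (a11 most significant). Its canonical id is the minimum of that code
## over the 6 simultaneous row/column permutations; connected classes form
## the fixed 13-element motif set, with id 78 the bi-directional two-hop
## path whose centre is the apex node.

.perm3 <- list(c(1L, 2L, 3L), c(1L, 3L, 2L), c(2L, 1L, 3L),
               c(2L, 3L, 1L), c(3L, 1L, 2L), c(3L, 2L, 1L))
.bitw3 <- matrix(c(256, 128, 64, 32, 16, 8, 4, 2, 1), 3, 3, byrow = TRUE)

motif_code <- function(A) sum(A * .bitw3)

decode_motif <- function(code) {
  bits <- (code %/% 2^(8:0)) %% 2
  matrix(bits, 3, 3, byrow = TRUE)
}

#' Canonical id of a 3-node motif
#'
#' Reads the 3x3 binary adjacency matrix row-major as a 9-bit integer
#' (entry (1,1) most significant) and minimizes over the 6 simultaneous
#' row/column permutations, making the id invariant under node relabeling.
#' The bi-directional two-hop path (centre bidirectionally linked to two
#' otherwise unlinked nodes) has id 78.
#'
#' @param adj3 3x3 binary matrix with zero diagonal.
#' @return integer motif id in `[1, 238]`.
#' @export
canonical_motif_id <- function(adj3) {
  A <- as_square_matrix(adj3, "motif adjacency")
  if (nrow(A) != 3L) stop("adj3 must be 3x3")
  if (!all(A %in% c(0, 1))) stop("adj3 must be binary")
  if (any(diag(A) != 0)) stop("self-loops (nonzero diagonal) are not allowed")
  as.integer(min(vapply(.perm3, function(p) motif_code(A[p, p]), numeric(1))))
}

## lookup tables over all 512 codes: canonical id and weak connectivity
.motif_tables_env <- new.env(parent = emptyenv())

motif_tables <- function() {
  if (!is.null(.motif_tables_env$canon)) {
    return(.motif_tables_env)
  }
  canon <- rep(NA_integer_, 512L)
  conn <- rep(FALSE, 512L)
  for (code in 0:511) {
    A <- decode_motif(code)
    if (any(diag(A) != 0)) next
    canon[code + 1L] <- canonical_motif_id(A)
    M <- ((A + t(A)) > 0) + diag(3)
    conn[code + 1L] <- all(M %*% M > 0)
  }
  .motif_tables_env$canon <- canon
  .motif_tables_env$conn <- conn
  .motif_tables_env
}

#' The 13 connected directed 3-node motif classes
#'
#' Enumerates all 64 labeled digraphs on 3 nodes (no self-loops), keeps the
#' weakly connected ones, canonicalizes and returns the distinct ids in
#' ascending order.
#'
#' @return integer vector of 13 motif ids.
#' @export
enumerate_3motifs <- function() {
  tab <- motif_tables()
  sort(unique(tab$canon[which(tab$conn)]))
}

## ---- census --------------------------------------------------------------

## vectorized per-triple codes; A integer matrix, triples m x 3
triple_codes <- function(A, triples) {
  n <- nrow(A)
  i1 <- triples[, 1L]; i2 <- triples[, 2L]; i3 <- triples[, 3L]
  a <- function(i, j) A[(j - 1L) * n + i]
  128L * a(i1, i2) + 64L * a(i1, i3) + 32L * a(i2, i1) +
    8L * a(i2, i3) + 4L * a(i3, i1) + 2L * a(i3, i2)
}

all_triples <- function(n) {
  if (n < 3L) return(matrix(integer(0), 0L, 3L))
  t(utils::combn(n, 3L))
}

## fast path used by the null model: counts over the 13 ids only
census_counts13 <- function(A, triples, motif_ids) {
  tab <- motif_tables()
  codes <- triple_codes(A, triples)
  keep <- tab$conn[codes + 1L]
  ids <- tab$canon[codes[keep] + 1L]
  counts <- tabulate(match(ids, motif_ids), nbins = length(motif_ids))
  names(counts) <- motif_ids
  counts
}

#' Exhaustive induced 3-node motif census
#'
#' Classifies every weakly connected induced 3-node subgraph by its
#' canonical motif id; each node subset is counted once (induced-subgraph
#' census). For motif 78 the apex (the bidirectionally connected centre) of
#' every instance is also recorded.
#'
#' @param net a [directed_network()].
#' @param collect_instances keep per-motif instance node-set lists (needed
#'   by [motif_adjacency()] and [apex_ratio()]).
#' @return object of class `motif_census`: `counts` (named integer over the
#'   13 ids), `instances` (named list of m x 3 node-index matrices),
#'   `apex78` (integer vector, apex node of each motif-78 instance),
#'   `n_nodes`, `node_labels`.
#' @export
motif_census <- function(net, collect_instances = TRUE) {
  A <- net_adjacency(net)
  n <- nrow(A)
  motif_ids <- enumerate_3motifs()
  tab <- motif_tables()
  triples <- all_triples(n)
  if (nrow(triples) == 0L) {
    counts <- stats::setNames(integer(length(motif_ids)), motif_ids)
    return(structure(list(counts = counts, instances = list(),
                          apex78 = integer(0), n_nodes = n,
                          node_labels = rownames(A)),
                     class = "motif_census"))
  }
  codes <- triple_codes(A, triples)
  keep <- tab$conn[codes + 1L]
  ids <- tab$canon[codes[keep] + 1L]
  ktrip <- triples[keep, , drop = FALSE]
  counts <- tabulate(match(ids, motif_ids), nbins = length(motif_ids))
  names(counts) <- motif_ids
  instances <- list()
  apex78 <- integer(0)
  if (collect_instances) {
    for (m in motif_ids[counts > 0]) {
      instances[[as.character(m)]] <- ktrip[ids == m, , drop = FALSE]
    }
    inst78 <- instances[["78"]]
    if (!is.null(inst78) && nrow(inst78) > 0L) {
      ## the apex has all four directed links inside the triple
      dtr <- function(i, j) A[cbind(i, j)] + A[cbind(j, i)]
      d1 <- dtr(inst78[, 1L], inst78[, 2L]) + dtr(inst78[, 1L], inst78[, 3L])
      d2 <- dtr(inst78[, 2L], inst78[, 1L]) + dtr(inst78[, 2L], inst78[, 3L])
      apex_pos <- ifelse(d1 == 4L, 1L, ifelse(d2 == 4L, 2L, 3L))
      apex78 <- inst78[cbind(seq_len(nrow(inst78)), apex_pos)]
    }
  }
  structure(list(counts = counts, instances = instances, apex78 = apex78,
                 n_nodes = n, node_labels = rownames(A)),
            class = "motif_census")
}

#' @export
print.motif_census <- function(x, ...) {
  nz <- x$counts[x$counts > 0]
  cat(sprintf("motif_census over %d nodes: %d connected triples\n",
              x$n_nodes, sum(x$counts)))
  if (length(nz)) {
    cat(paste(sprintf("  motif %s: %d", names(nz), nz), collapse = "\n"), "\n")
  }
  invisible(x)
}

#' Build a census object from an explicit instance list
#'
#' Useful when motif instances are given directly (e.g. a worked example)
#' rather than found by search.
#'
#' @param instances m x 3 matrix (or list of length-3 vectors) of node
#'   indices, one row per instance.
#' @param motif the motif id the instances belong to.
#' @param n number of nodes of the host network.
#' @param node_labels optional labels.
#' @return a `motif_census` containing only the given motif.
#' @export
motif_census_from_instances <- function(instances, motif, n,
                                        node_labels = NULL) {
  if (is.list(instances)) instances <- do.call(rbind, instances)
  instances <- matrix(as.integer(instances), ncol = 3L)
  motif_ids <- enumerate_3motifs()
  counts <- stats::setNames(integer(length(motif_ids)), motif_ids)
  counts[as.character(motif)] <- nrow(instances)
  structure(list(counts = counts,
                 instances = stats::setNames(list(instances),
                                             as.character(motif)),
                 apex78 = integer(0), n_nodes = as.integer(n),
                 node_labels = node_labels %||% paste0("N", seq_len(n))),
            class = "motif_census")
}

## ---- null model ----------------------------------------------------------

#' Degree- and mutuality-preserving rewired network
#'
#' Randomizes a directed network with the edge-switching algorithm:
#' `switch_factor` times the number of directed links attempted pair swaps,
#' where uni-directional links are swapped with uni-directional links and
#' mutual (bi-directional) dyads with mutual dyads. Every accepted swap
#' preserves each node's in- and out-degree, creates no self-loop or
#' duplicate link, and leaves the number of bi-directional links unchanged.
#' Networks admitting no legal swap are returned unchanged with
#' `attr(, "n_swaps") == 0`.
#'
#' @param net a [directed_network()].
#' @param switch_factor attempted swaps per directed link (default 100).
#' @param seed optional integer seed (uses the current RNG state if `NULL`).
#' @return a rewired [directed_network()] with attribute `n_swaps`.
#' @export
rewire_null <- function(net, switch_factor = 100L, seed = NULL) {
  A <- net_adjacency(net)
  if (!is.null(seed)) set.seed(as.integer(seed))
  attempts <- as.integer(switch_factor) * sum(A)
  res <- rewire_switching(A, attempts)
  out <- directed_network(res$adjacency,
                          if (inherits(net, "directed_network"))
                            net$node_labels else rownames(A))
  attr(out, "n_swaps") <- res$n_swaps
  out
}

#' Null distribution of motif counts under rewiring
#'
#' Censuses `n_random` independently rewired networks and reports, per
#' motif id, the mean and (population) standard deviation of the null
#' counts and the empirical exceedance probability
#' `Pr[J_rand >= J_original]` (weak inequality, so a motif absent from both
#' the original and every null has probability 1). A single seed fans out
#' to per-draw substreams, making the draws order-independent.
#'
#' @param net a [directed_network()].
#' @param n_random number of rewired networks (default 1000).
#' @param switch_factor see [rewire_null()].
#' @param seed integer seed.
#' @return object of class `null_summary` with fields `motif_ids`,
#'   `j_original`, `mu`, `sigma`, `p_exceed`, `n_random`.
#' @export
null_distribution <- function(net, n_random = 1000L, switch_factor = 100L,
                              seed = 1L) {
  A <- net_adjacency(net)
  n_random <- as.integer(n_random)
  if (n_random < 1L) stop("n_random must be >= 1")
  motif_ids <- enumerate_3motifs()
  triples <- all_triples(nrow(A))
  j_orig <- census_counts13(A, triples, motif_ids)
  set.seed(as.integer(seed))
  sub_seeds <- sample.int(.Machine$integer.max - 1L, n_random)
  counts <- matrix(0L, n_random, length(motif_ids),
                   dimnames = list(NULL, motif_ids))
  attempts <- as.integer(switch_factor) * sum(A)
  for (r in seq_len(n_random)) {
    set.seed(sub_seeds[r])
    Ar <- rewire_switching(A, attempts)$adjacency
    counts[r, ] <- census_counts13(Ar, triples, motif_ids)
  }
  mu <- colMeans(counts)
  sigma <- apply(counts, 2L, sd_pop)
  p_exceed <- colMeans(counts >= matrix(j_orig, n_random,
                                        length(motif_ids), byrow = TRUE))
  structure(list(motif_ids = motif_ids, j_original = j_orig,
                 mu = mu, sigma = sigma, p_exceed = p_exceed,
                 n_random = n_random, null_counts = counts),
            class = "null_summary")
}

#' @export
print.null_summary <- function(x, ...) {
  cat(sprintf("null_summary: %d rewired networks\n", x$n_random))
  df <- data.frame(motif = x$motif_ids, J = x$j_original, mu = x$mu,
                   sigma = x$sigma, p = x$p_exceed)
  print(df[df$J > 0 | df$mu > 0, ], row.names = FALSE)
  invisible(x)
}

#' Motif overexpression z-score
#'
#' `z = (J - mu) / sigma` of the observed count against the rewired-null
#' mean and (population) standard deviation. Undefined (`NA`) when
#' `sigma = 0`.
#'
#' @param j_original observed motif count.
#' @param null a [null_distribution()] summary.
#' @param motif motif id.
#' @return numeric z-score, `NA` if the null is degenerate.
#' @export
motif_zscore <- function(j_original, null, motif) {
  m <- as.character(motif)
  i <- match(as.integer(motif), null$motif_ids)
  if (is.na(i)) stop(sprintf("unknown motif id %s", m))
  if (null$sigma[i] == 0) return(NA_real_)
  unname((j_original - null$mu[i]) / null$sigma[i])
}

#' Overexpression calls for all motifs
#'
#' A motif is overexpressed iff all three criteria hold: (i) the empirical
#' probability that a rewired network contains the motif at least as often
#' as the original is below 0.01; (ii) the motif occurs at least 4 times
#' with distinct node sets in the original network; (iii) the ratio of the
#' observed count to the null mean is at least 1.1 (a zero null mean with a
#' positive observed count passes the ratio criterion and is flagged).
#'
#' @param census a [motif_census()] of the original network.
#' @param null a [null_distribution()] of the same network.
#' @return data.frame (class `overexpression_call`) with columns
#'   `motif_id`, `count`, `mu`, `sigma`, `z`, `p`, `ratio`, `passes_p`,
#'   `passes_count`, `passes_ratio`, `overexpressed`, `flag`.
#' @export
call_overexpression <- function(census, null) {
  stopifnot(inherits(census, "motif_census"), inherits(null, "null_summary"))
  ids <- null$motif_ids
  J <- census$counts[as.character(ids)]
  z <- (J - null$mu) / ifelse(null$sigma > 0, null$sigma, NA)
  ratio <- ifelse(null$mu > 0, J / null$mu, ifelse(J > 0, Inf, NA))
  passes_p <- null$p_exceed < 0.01
  passes_count <- J >= 4
  passes_ratio <- !is.na(ratio) & ratio >= 1.1
  flag <- ifelse(null$mu == 0 & J > 0, "null-mean-zero",
                 ifelse(null$sigma == 0, "null-sd-zero", ""))
  out <- data.frame(motif_id = ids, count = as.integer(J),
                    mu = null$mu, sigma = null$sigma, z = z,
                    p = null$p_exceed, ratio = ratio,
                    passes_p = passes_p, passes_count = passes_count,
                    passes_ratio = passes_ratio,
                    overexpressed = passes_p & passes_count & passes_ratio,
                    flag = flag, row.names = NULL)
  class(out) <- c("overexpression_call", "data.frame")
  out
}

## ---- apex statistics -----------------------------------------------------

#' Apex-ratio of every node for the bi-directional two-hop path motif
#'
#' For each node, the number of motif-78 instances in which it occupies the
#' apex position (the bidirectionally connected centre) divided by its
#' total participation in motif-78 instances. A node in no instance has an
#' undefined ratio (`NA`): 1 marks a node that is always the apex, 0 one
#' that participates only as a leaf.
#'
#' @param census a [motif_census()] with instances collected.
#' @param motif motif id; only 78 has a distinguished apex position.
#' @return named numeric vector over all nodes (`NA` = non-participant).
#' @export
apex_ratio <- function(census, motif = 78L) {
  stopifnot(inherits(census, "motif_census"))
  if (as.integer(motif) != 78L) {
    stop("only motif 78 has a distinguished apex position")
  }
  n <- census$n_nodes
  inst <- census$instances[["78"]]
  part <- numeric(n)
  apex <- numeric(n)
  if (!is.null(inst) && nrow(inst) > 0L) {
    part <- tabulate(as.vector(inst), nbins = n)
    apex <- tabulate(census$apex78, nbins = n)
  }
  out <- ifelse(part > 0, apex / part, NA_real_)
  names(out) <- census$node_labels
  out
}

#' High-degree (hub) nodes
#'
#' Nodes whose total degree (incoming + outgoing links) is at least the
#' network's mean total degree plus one standard deviation (population sd
#' by default; in a regular network every node qualifies).
#'
#' @param net a [directed_network()].
#' @param sd_type `"population"` (default) or `"sample"`.
#' @return character vector of node labels.
#' @export
high_degree_nodes <- function(net, sd_type = c("population", "sample")) {
  sd_type <- match.arg(sd_type)
  A <- net_adjacency(net)
  deg <- rowSums(A) + colSums(A)
  if (sum(deg) == 0) return(character(0))
  s <- if (sd_type == "population") sd_pop(deg) else stats::sd(deg)
  rownames(A)[deg >= mean(deg) + s]
}

#' Correlation between apex-ratio and degree
#'
#' Pearson correlation between the apex-ratio and the total degree over all
#' nodes with a positive apex-ratio. Undefined (`NA`, with a `"reason"`
#' attribute) when fewer than 3 nodes qualify or either variable is
#' constant.
#'
#' @param ratios output of [apex_ratio()].
#' @param net the [directed_network()] the ratios were computed on.
#' @return numeric scalar or `NA`.
#' @export
apex_degree_correlation <- function(ratios, net) {
  A <- net_adjacency(net)
  deg <- rowSums(A) + colSums(A)
  keep <- !is.na(ratios) & ratios > 0
  if (sum(keep) < 3L) {
    return(structure(NA_real_, reason = "fewer than 3 nodes with positive apex-ratio"))
  }
  x <- ratios[keep]
  y <- deg[keep]
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    return(structure(NA_real_, reason = "zero variance"))
  }
  stats::cor(x, y)
}
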