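#' Specification of a coupled phase-oscillator ensemble
#'
#' Describes the stochastic model from which [generate_coupled_phases()]
#' draws: per subject and epoch, each region's phase performs a wrapped
#' random walk with intrinsic angular increment `omega_i`, Kuramoto-style
#' sine coupling to lagged phases of the other regions, and Gaussian phase
#' noise. Defaults mirror the structure of resting-state MEG recordings
#' parcellated into 78 cortical regions (67 subjects, 20 epochs of 4096
#' samples at 1250 Hz; an alpha-band rhythm of 10-13 Hz advances by
#' 0.050-0.065 rad per sample, which is the default `intrinsic_freqs`
#' range).
#'
#' @param n_regions number of regions (network nodes).
#' @param n_subjects number of subjects.
#' @param n_epochs epochs per subject; epochs are re-initialized
#'   independently, not sliced from one long run.
#' @param n_samples samples per epoch; must be at least `coupling_lag + 2`.
#' @param intrinsic_freqs per-region angular increment in radians/sample
#'   (scalar recycled, or length `n_regions`).
#' @param coupling nonnegative `n_regions x n_regions` matrix; entry (j, i)
#'   is the strength of the directed influence j -> i. Zero diagonal.
#' @param coupling_lag integer lag (samples, >= 1) of the driving phase.
#' @param noise_sd standard deviation (radians) of the per-step phase noise.
#' @param seed integer RNG seed; identical specs give bit-identical output.
#' @return object of class `coupling_spec`.
#' @seealso [generate_coupled_phases()]
#' @export
coupling_spec <- function(n_regions = 78L,
                          n_subjects = 67L,
                          n_epochs = 20L,
                          n_samples = 4096L,
                          intrinsic_freqs = seq(0.050, 0.065,
                                                length.out = n_regions),
                          coupling = matrix(0, n_regions, n_regions),
                          coupling_lag = 1L,
                          noise_sd = 0.1,
                          seed = 1L) {
  n_regions <- as.integer(n_regions)
  n_subjects <- as.integer(n_subjects)
  n_epochs <- as.integer(n_epochs)
  n_samples <- as.integer(n_samples)
  coupling_lag <- as.integer(coupling_lag)
  if (n_regions < 1L || n_subjects < 1L || n_epochs < 1L) {
    stop("n_regions, n_subjects and n_epochs must be positive")
  }
  if (length(intrinsic_freqs) == 1L) {
    intrinsic_freqs <- rep(intrinsic_freqs, n_regions)
  }
  if (length(intrinsic_freqs) != n_regions) {
    stop("intrinsic_freqs must have length 1 or n_regions")
  }
  coupling <- as_square_matrix(coupling, "coupling")
  if (nrow(coupling) != n_regions) {
    stop("coupling must be n_regions x n_regions")
  }
  if (any(coupling < 0)) stop("coupling strengths must be nonnegative")
  if (any(diag(coupling) != 0)) stop("coupling diagonal must be zero")
  if (coupling_lag < 1L) stop("coupling_lag must be >= 1")
  if (n_samples < coupling_lag + 2L) {
    stop("n_samples must be >= coupling_lag + 2")
  }
  if (noise_sd < 0) stop("noise_sd must be nonnegative")
  structure(
    list(n_regions = n_regions, n_subjects = n_subjects,
         n_epochs = n_epochs, n_samples = n_samples,
         intrinsic_freqs = intrinsic_freqs, coupling = coupling,
         coupling_lag = coupling_lag, noise_sd = noise_sd,
         seed = as.integer(seed)),
    class = "coupling_spec")
}

#' Construct a phase ensemble from an array of phases
#'
#' @param data numeric array `subjects x epochs x regions x samples`, all
#'   values in (-pi, pi].
#' @param region_labels character vector of region names (defaults to
#'   `R1..Rn`).
#' @return object of class `phase_ensemble`.
#' @export
phase_ensemble <- function(data, region_labels = NULL) {
  if (length(dim(data)) != 4L) {
    stop("data must be a 4-d array: subjects x epochs x regions x samples")
  }
  n_regions <- dim(data)[3L]
  region_labels <- region_labels %||% paste0("R", seq_len(n_regions))
  if (length(region_labels) != n_regions) {
    stop("region_labels length does not match the region dimension")
  }
  if (any(data <= -pi | data > pi)) {
    stop("all phases must lie in (-pi, pi]")
  }
  structure(list(data = data, region_labels = as.character(region_labels)),
            class = "phase_ensemble")
}

#' @export
print.phase_ensemble <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf(
    "phase_ensemble: %d subject(s) x %d epoch(s) x %d region(s) x %d samples\n",
    d[1], d[2], d[3], d[4]))
  invisible(x)
}

#' Simulate a coupled phase-oscillator ensemble
#'
#' Each subject-epoch series is initialized from Uniform(-pi, pi] and
#' evolves by
#' `x_i(t+1) = wrap(x_i(t) + omega_i + sum_j c_ji * sin(x_j(t - lag) - x_i(t)) + eps)`
#' with `eps ~ N(0, noise_sd^2)`. The coupling term is zero while
#' `t - lag < 1` (burn-in shorter than the lag). With zero coupling every
#' region is an independent wrapped Gaussian random walk, so downstream PTE
#' sits at the histogram-bias level.
#'
#' @param spec a [coupling_spec()].
#' @return a [phase_ensemble()].
#' @export
generate_coupled_phases <- function(spec) {
  stopifnot(inherits(spec, "coupling_spec"))
  set.seed(spec$seed)
  n <- spec$n_regions
  ns <- spec$n_samples
  lag <- spec$coupling_lag
  C <- spec$coupling
  omega <- spec$intrinsic_freqs
  coupled <- any(C > 0)
  out <- array(NA_real_,
               dim = c(spec$n_subjects, spec$n_epochs, n, ns))
  for (s in seq_len(spec$n_subjects)) {
    for (e in seq_len(spec$n_epochs)) {
      x <- matrix(NA_real_, n, ns)
      x[, 1L] <- wrap_phase(stats::runif(n, -pi, pi))
      eps <- if (spec$noise_sd > 0) {
        matrix(stats::rnorm(n * (ns - 1L), 0, spec$noise_sd), n, ns - 1L)
      } else {
        matrix(0, n, ns - 1L)
      }
      for (t in seq_len(ns - 1L)) {
        drift <- omega
        if (coupled && t - lag >= 1L) {
          ## M[j, i] = sin(x_j(t - lag) - x_i(t))
          M <- sin(outer(x[, t - lag], x[, t], "-"))
          drift <- drift + colSums(C * M)
        }
        x[, t + 1L] <- wrap_phase(x[, t] + drift + eps[, t])
      }
      out[s, e, , ] <- x
    }
  }
  phase_ensemble(out)
}

#' Planted two-cluster ground truth with designated apex hubs
#'
#' @param cluster_assignment integer vector over nodes with values 1 or 2;
#'   both clusters must be non-empty.
#' @param apex_nodes indices of nodes designated as bidirectional hubs.
#' @return object of class `planted_structure`.
#' @export
planted_structure <- function(cluster_assignment, apex_nodes) {
  cluster_assignment <- as.integer(cluster_assignment)
  if (!all(cluster_assignment %in% c(1L, 2L))) {
    stop("cluster_assignment values must be 1 or 2")
  }
  if (!all(c(1L, 2L) %in% cluster_assignment)) {
    stop("both clusters must be non-empty")
  }
  apex_nodes <- as.integer(apex_nodes)
  if (any(apex_nodes < 1L | apex_nodes > length(cluster_assignment))) {
    stop("apex_nodes out of range")
  }
  structure(list(cluster_assignment = cluster_assignment,
                 apex_nodes = unique(apex_nodes)),
            class = "planted_structure")
}

#' Generate a weighted connectivity matrix with planted hub structure
#'
#' Within-cluster ordered pairs incident to an apex node are drawn around
#' `w_in` in both directions (so that thresholding inside `(w_out, w_in)`
#' produces bidirectional hub-and-spoke links, a structure rich in the
#' bi-directional two-hop path motif); every other ordered pair is drawn
#' around `w_out`. Gaussian jitter with sd `jitter_sd` is added and the
#' result reflected at zero (absolute value), keeping all off-diagonal
#' entries nonnegative and distinct with probability 1 when
#' `jitter_sd > 0`. An optional `directional_offset` is added to background
#' (non-apex) links from lower to higher node index, planting a
#' sender/receiver asymmetry.
#'
#' @param n number of nodes (>= 6).
#' @param structure a [planted_structure()] over `n` nodes.
#' @param w_in,w_out mean within-hub / background weights; `w_in > w_out >= 0`.
#' @param jitter_sd standard deviation of the additive weight jitter.
#' @param seed RNG seed.
#' @param directional_offset added to background entries (i, j) with
#'   `i < j`; default 0 (no planted asymmetry).
#' @param labels optional node labels.
#' @return a [pte_matrix_obj()] (N x N nonnegative matrix, zero diagonal).
#' @export
generate_planted_weight_matrix <- function(n, structure, w_in, w_out,
                                           jitter_sd = 0, seed = 1L,
                                           directional_offset = 0,
                                           labels = NULL) {
  stopifnot(inherits(structure, "planted_structure"))
  n <- as.integer(n)
  if (n < 6L) stop("n must be >= 6")
  if (length(structure$cluster_assignment) != n) {
    stop("structure does not cover n nodes")
  }
  if (!(w_in > w_out)) stop("w_in must exceed w_out")
  if (w_out < 0) stop("w_out must be nonnegative")
  set.seed(as.integer(seed))
  cl <- structure$cluster_assignment
  apex <- logical(n)
  apex[structure$apex_nodes] <- TRUE
  same_cluster <- outer(cl, cl, "==")
  apex_pair <- outer(apex, apex, "|") & same_cluster
  W <- matrix(w_out, n, n)
  if (directional_offset != 0) {
    idx <- which(upper.tri(W) & !apex_pair)
    W[idx] <- W[idx] + directional_offset
  }
  W[apex_pair] <- w_in
  if (jitter_sd > 0) {
    W <- W + matrix(stats::rnorm(n * n, 0, jitter_sd), n, n)
    W <- abs(W)
  }
  diag(W) <- 0
  labels <- labels %||% paste0("N", seq_len(n))
  pte_matrix_obj(W, labels,
                 meta = list(source = "planted",
                             w_in = w_in, w_out = w_out,
                             jitter_sd = jitter_sd, seed = seed))
}
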