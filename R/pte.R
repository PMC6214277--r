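#' Pairwise phase-transfer-entropy matrix container
#'
#' Holds an `N x N` nonnegative matrix of pairwise PTE values (entry (X, Y)
#' is the flow from X to Y), with zero diagonal. Asymmetry is expected:
#' `PTE_XY != PTE_YX` in general.
#'
#' @param values square numeric matrix, nonnegative, zero diagonal.
#' @param region_labels character labels (defaults to `R1..Rn` or the
#'   dimnames of `values`).
#' @param meta list of provenance fields (delay used, bin count, number of
#'   subject-epoch units averaged, ...).
#' @return object of class `pte_matrix`.
#' @export
pte_matrix_obj <- function(values, region_labels = NULL, meta = list()) {
  values <- as_square_matrix(values, "PTE matrix")
  if (any(values < 0)) stop("PTE values must be nonnegative")
  if (any(diag(values) != 0)) stop("PTE diagonal must be exactly zero")
  n <- nrow(values)
  region_labels <- region_labels %||% rownames(values) %||%
    paste0("R", seq_len(n))
  if (length(region_labels) != n) stop("region_labels length mismatch")
  dimnames(values) <- list(region_labels, region_labels)
  structure(list(values = values,
                 region_labels = as.character(region_labels),
                 meta = meta),
            class = "pte_matrix")
}

#' @export
print.pte_matrix <- function(x, ...) {
  n <- nrow(x$values)
  off <- x$values[row(x$values) != col(x$values)]
  cat(sprintf("pte_matrix: %d regions, %d off-diagonal entries in [%.4g, %.4g]\n",
              n, n * (n - 1L), min(off), max(off)))
  invisible(x)
}

pte_values <- function(x) {
  if (inherits(x, "pte_matrix")) x$values else as_square_matrix(x, "PTE matrix")
}

off_diagonal <- function(V) V[row(V) != col(V)]

#' Default phase-histogram bin count
#'
#' The binning rule of the PTE literature:
#' `round(exp(0.626 + 0.4 * log(n_samples - 1)))`. For 4096-sample epochs
#' this gives 52 bins.
#'
#' @param n_samples samples per epoch.
#' @return integer bin count (at least 2).
#' @export
default_n_bins <- function(n_samples) {
  max(2L, as.integer(round(exp(0.626 + 0.4 * log(n_samples - 1)))))
}

## delay from raw counts: h = round(Ns * Nroi / Npm), half away from zero,
## clamped to >= 1
delay_from_counts <- function(n_samples, n_regions, n_sign_changes) {
  if (n_sign_changes < 1) {
    stop("degenerate input: no sign changes in the phase series")
  }
  max(1L, as.integer(round_half_away(n_samples * n_regions / n_sign_changes)))
}

count_sign_changes <- function(X) {
  ## X: regions x samples matrix of phases; counts strict sign changes of
  ## consecutive values, pooled over regions
  if (is.null(dim(X))) X <- matrix(X, nrow = 1L)
  a <- X[, -ncol(X), drop = FALSE]
  b <- X[, -1L, drop = FALSE]
  sum(a * b < 0)
}

#' Estimate the PTE prediction delay from the phase data
#'
#' The delay is `h = round(N_s * N_ROI / N_pm)` where `N_pm` counts the sign
#' changes of consecutive phase values across time and regions within an
#' epoch (rounded half away from zero, clamped to >= 1). The delay is
#' computed per epoch; the headline `h` pools the sign-change counts over
#' all subject-epoch units.
#'
#' @param ensemble a [phase_ensemble()] with at least 2 samples per epoch.
#' @return object of class `delay_estimate` with fields `h` (pooled),
#'   `per_epoch` (subjects x epochs integer matrix), `n_samples`,
#'   `n_regions`, `n_sign_changes` (total).
#' @export
estimate_delay <- function(ensemble) {
  stopifnot(inherits(ensemble, "phase_ensemble"))
  d <- dim(ensemble$data)
  if (d[4L] < 2L) stop("epochs must contain at least 2 samples")
  per_epoch <- matrix(NA_integer_, d[1L], d[2L])
  total_changes <- 0
  for (s in seq_len(d[1L])) {
    for (e in seq_len(d[2L])) {
      npm <- count_sign_changes(ensemble$data[s, e, , , drop = TRUE])
      if (npm < 1) {
        stop("degenerate input: epoch with constant-sign phases (no sign changes)")
      }
      per_epoch[s, e] <- delay_from_counts(d[4L], d[3L], npm)
      total_changes <- total_changes + npm
    }
  }
  h <- delay_from_counts(d[4L] * d[1L] * d[2L], d[3L], total_changes)
  structure(list(h = h, per_epoch = per_epoch,
                 n_samples = d[4L], n_regions = d[3L],
                 n_sign_changes = total_changes),
            class = "delay_estimate")
}

#' @export
print.delay_estimate <- function(x, ...) {
  cat(sprintf("delay_estimate: h = %d (Ns = %d, Nroi = %d, sign changes = %d)\n",
              x$h, x$n_samples, x$n_regions, x$n_sign_changes))
  invisible(x)
}

bin_phase <- function(x, n_bins) {
  b <- ceiling((x + pi) / (2 * pi) * n_bins)
  b[b < 1L] <- 1L
  b[b > n_bins] <- n_bins
  as.integer(b)
}

#' Phase transfer entropy between two phase series
#'
#' Plug-in estimate of
#' `sum Pr[x_{t+h}, x_t, y_t] * log( Pr[x_{t+h} | x_t, y_t] / Pr[x_{t+h} | x_t] )`
#' with all probabilities taken from joint histograms of the binned phases
#' over the epoch. Zero-probability cells contribute 0 and the result is
#' clamped at 0 against floating-point round-off (the quantity is a
#' conditional mutual information, hence nonnegative).
#'
#' @param x,y numeric phase sequences of equal length greater than `h`.
#'   The returned value is `PTE_XY` with `x` playing the role of the target
#'   series `X`: the improvement in predicting `x_{t+h}` from `y_t` beyond
#'   what `x_t` already provides.
#' @param h prediction delay in samples (positive integer).
#' @param n_bins number of equal-width phase bins over (-pi, pi] (>= 2).
#' @param log_base base of the logarithm; natural log by default.
#' @return nonnegative scalar.
#' @export
pte_pair <- function(x, y, h, n_bins, log_base = exp(1)) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  h <- as.integer(h)
  if (h < 1L) stop("h must be >= 1")
  if (length(x) <= h) stop("sequences must be longer than h")
  n_bins <- as.integer(n_bins)
  if (n_bins < 2L) stop("n_bins must be >= 2")
  bx <- bin_phase(wrap_phase(x), n_bins)
  by <- bin_phase(wrap_phase(y), n_bins)
  m <- length(x) - h
  xf <- bx[(h + 1L):length(x)]
  xn <- bx[1L:m]
  yn <- by[1L:m]
  nb <- n_bins
  cnt <- tabulate(xf + nb * (xn - 1L) + nb * nb * (yn - 1L), nbins = nb^3)
  p <- array(cnt / m, dim = c(nb, nb, nb)) # [xf, xn, yn]
  p_xn_yn <- apply(p, c(2L, 3L), sum)
  p_xf_xn <- apply(p, c(1L, 2L), sum)
  p_xn <- colSums(p_xf_xn)
  nz <- which(p > 0, arr.ind = TRUE)
  pj <- p[nz]
  terms <- pj * (log(pj) + log(p_xn[nz[, 2L]]) -
                   log(p_xn_yn[nz[, c(2L, 3L), drop = FALSE]]) -
                   log(p_xf_xn[nz[, c(1L, 2L), drop = FALSE]]))
  val <- sum(terms) / log(log_base)
  max(0, val)
}

#' Pairwise PTE matrix averaged over subjects and epochs
#'
#' For every ordered region pair, computes [pte_pair()] per subject-epoch
#' unit (using that epoch's estimated delay, or a fixed `h` if supplied)
#' and returns the arithmetic mean across all units. Averaging over
#' subjects and epochs removes individual measurement bias.
#'
#' @param ensemble a [phase_ensemble()].
#' @param n_bins phase bins; default [default_n_bins()] of the epoch length.
#' @param h optional fixed delay overriding the per-epoch estimate.
#' @param log_base logarithm base.
#' @return a [pte_matrix_obj()] whose `meta` records the per-epoch delays,
#'   bin count and number of units averaged.
#' @export
pte_matrix <- function(ensemble, n_bins = NULL, h = NULL,
                       log_base = exp(1)) {
  stopifnot(inherits(ensemble, "phase_ensemble"))
  d <- dim(ensemble$data)
  if (d[1L] * d[2L] < 1L) stop("ensemble must contain at least one epoch")
  n_bins <- as.integer(n_bins %||% default_n_bins(d[4L]))
  delays <- if (is.null(h)) estimate_delay(ensemble)$per_epoch else
    matrix(as.integer(h), d[1L], d[2L])
  n <- d[3L]
  acc <- matrix(0, n, n)
  units <- 0L
  for (s in seq_len(d[1L])) {
    for (e in seq_len(d[2L])) {
      X <- ensemble$data[s, e, , , drop = TRUE]
      if (n == 1L) X <- matrix(X, nrow = 1L)
      he <- delays[s, e]
      for (i in seq_len(n)) {
        for (j in seq_len(n)) {
          if (i == j) next
          ## entry (i, j) is the flow i -> j: predict j's future phase
          ## from i's present beyond j's own past
          acc[i, j] <- acc[i, j] +
            pte_pair(x = X[j, ], y = X[i, ], h = he, n_bins = n_bins,
                     log_base = log_base)
        }
      }
      units <- units + 1L
    }
  }
  pte_matrix_obj(acc / units, ensemble$region_labels,
                 meta = list(h_per_epoch = delays, n_bins = n_bins,
                             n_units = units, log_base = log_base))
}

#' Directed PTE
#'
#' `dPTE_XY = PTE_XY / (PTE_XY + PTE_YX)`; values above 0.5 mark
#' preferential flow from X to Y, and `dPTE_XY + dPTE_YX = 1` for every
#' defined pair. Pairs with `PTE_XY + PTE_YX = 0` (and the diagonal) are
#' undefined and returned as `NA`; their count is attached as the
#' `"n_undefined"` attribute rather than raised as an error.
#'
#' @param pte a [pte_matrix_obj()] or square nonnegative matrix.
#' @return `N x N` matrix in `[0, 1]` with `NA` at undefined entries.
#' @export
dpte <- function(pte) {
  V <- pte_values(pte)
  tot <- V + t(V)
  out <- V / tot
  undef <- tot == 0 & row(V) != col(V)
  out[undef] <- NA_real_
  diag(out) <- NA_real_
  attr(out, "n_undefined") <- sum(undef)
  out
}
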