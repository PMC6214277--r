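#' Wrap angles into the half-open interval (-pi, pi]
#'
#' Phases are represented on (-pi, pi] throughout the package; this is the
#' canonical wrapping used by the synthetic generator and by any caller that
#' shifts phases by multiples of 2*pi.
#'
#' @param x numeric vector/array of angles in radians.
#' @return object of the same shape with every value in (-pi, pi].
#' @examples
#' wrap_phase(c(pi, -pi, 3 * pi / 2))
#' @export
wrap_phase <- function(x) {
  x - 2 * pi * ceiling((x - pi) / (2 * pi))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

## BFS on an undirected adjacency pattern; returns component label per node.
## Used for weak connectivity of directed networks (directions ignored) and
## for components of motif-weight graphs. Kept dependency-free on purpose:
## igraph is reserved for the test suite as an independent oracle.
components_undirected <- function(U) {
  n <- nrow(U)
  comp <- integer(n)
  cur <- 0L
  for (s in seq_len(n)) {
    if (comp[s] != 0L) next
    cur <- cur + 1L
    queue <- s
    comp[s] <- cur
    while (length(queue)) {
      v <- queue[[1L]]
      queue <- queue[-1L]
      nb <- which(U[v, ] != 0 & comp == 0L)
      comp[nb] <- cur
      queue <- c(queue, nb)
    }
  }
  comp
}

is_weakly_connected <- function(A) {
  if (nrow(A) <= 1L) return(TRUE)
  U <- (A != 0) | (t(A) != 0)
  max(components_undirected(U)) == 1L
}

## validate + normalize a square numeric matrix with labels
as_square_matrix <- function(x, what = "matrix") {
  x <- as.matrix(x)
  if (nrow(x) != ncol(x)) {
    stop(sprintf("%s must be square, got %d x %d", what, nrow(x), ncol(x)))
  }
  if (!is.numeric(x)) stop(sprintf("%s must be numeric", what))
  x
}

## population standard deviation (divide by N); the package's z-scores and
## hub rule are descriptive over a fixed sample, not inferential
sd_pop <- function(x) {
  m <- mean(x)
  sqrt(mean((x - m)^2))
}

## round half away from zero (base round() rounds half to even)
round_half_away <- function(x) {
  sign(x) * floor(abs(x) + 0.5)
}
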