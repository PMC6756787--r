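#' Minimal distance between phases on the ring
#'
#' Distance between two phases in \[0, 1) with periodic boundary conditions:
#' `min(|x| mod 1, 1 - |x| mod 1)`. Vectorised; accepts any real input.
#'
#' @param x Phase difference(s), any real number(s).
#' @return Distances in \[0, 0.5\], same shape as `x`.
#' @examples
#' ring_distance(0.8)   # 0.2: wraps around
#' ring_distance(1.7)   # 0.3
#' @export
ring_distance <- function(x) {
  y <- abs(x) %% 1
  pmin(y, 1 - y)
}

#' Minimal distance between phases on the twisted torus
#'
#' Euclidean distance between two 2D phase points on the torus obtained by
#' identifying points that differ by integer combinations of the lattice
#' generators ([hex_basis()]): the minimum of
#' \eqn{\lVert v - k_1 u_1 - k_2 u_2 \rVert} over integers
#' \eqn{k_1, k_2} in a window.
#'
#' @param dx,dy Cartesian components of the phase difference(s); vectors,
#'   matrices or arrays of equal shape.
#' @param basis 2x2 matrix of lattice generators (columns); defaults to the
#'   rhombic grid-cell lattice.
#' @param window Integer: search over \eqn{k_{1,2} \in \{-window..window\}}.
#'   The default window of 2 is sufficient for differences of points taken
#'   from one unit cell.
#' @return Distances with the shape of `dx`.
#' @examples
#' torus_distance(1, 0)      # u1 is identified with the origin: 0
#' torus_distance(0.9, 0)    # 0.1
#' @export
torus_distance <- function(dx, dy, basis = hex_basis(), window = 2L) {
  if (length(dx) != length(dy)) stop("`dx` and `dy` must have equal length")
  best <- dx * 0 + Inf # keeps dim attributes
  for (k1 in -window:window) {
    for (k2 in -window:window) {
      ox <- k1 * basis[1, 1] + k2 * basis[1, 2]
      oy <- k1 * basis[2, 1] + k2 * basis[2, 2]
      best <- pmin(best, sqrt((dx - ox)^2 + (dy - oy)^2))
    }
  }
  best
}

#' Unwrap a periodic phase trajectory by nearest-image continuity
#'
#' Successive samples of a phase in \[0, 1) that jump by more than 0.5 are
#' assumed to have crossed the periodic boundary; the jump is corrected by
#' the nearest integer so the returned trajectory is continuous on the real
#' line.
#'
#' @param p Numeric vector of wrapped phases, or a matrix whose columns are
#'   unwrapped independently.
#' @return Unwrapped trajectory, same shape as `p`.
#' @export
unwrap_phase <- function(p) {
  if (is.matrix(p)) return(apply(p, 2, unwrap_phase))
  if (length(p) < 2) return(p)
  dp <- diff(p)
  dp <- dp - round(dp)
  cumsum(c(p[1], dp))
}
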