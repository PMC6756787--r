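#' Specify a single grid-cell module
#'
#' A module is a continuous attractor network: a double ring in 1D (right and
#' left sub-populations) or a twisted torus in 2D (right, left, up and down
#' sub-populations arranged on a rhombic sheet with periodic boundaries).
#' The spec collects the architectural and gain parameters shared by all
#' neurons of the module.
#'
#' Defaults are the reference parameter set used throughout the package:
#' synaptic time constant 10 ms, constant drive \eqn{I_0 = 3}, connectivity
#' amplitude \eqn{A = 200}, squared connectivity width \eqn{\sigma^2 = 0.1}
#' (phase units), outgoing-weight shift \eqn{\varphi = 0.2}, and 1000 neurons
#' per sub-population in 1D (\eqn{64^2} in 2D at full scale).
#'
#' @param dims Spatial dimensionality of the represented variable, 1 or 2.
#' @param N Neurons per sub-population. In 2D this must be a perfect square
#'   (the sub-population is a \eqn{\sqrt{N}\times\sqrt{N}} sheet).
#' @param tau Synaptic time constant in seconds.
#' @param I0 Constant feedforward drive (dimensionless drive units).
#' @param A Connectivity amplitude.
#' @param sigma2 Squared connectivity width, in squared phase units.
#' @param phi_shift Outgoing-weight phase offset \eqn{\varphi}, in (0, 0.5).
#' @param gamma External velocity gain \eqn{\gamma} (drive units per m/s).
#'
#' @return An object of class `module_spec`.
#' @seealso [build_network()]
#' @examples
#' spec <- module_spec(dims = 1, N = 128)
#' spec
#' @export
module_spec <- function(dims = 1,
                        N = if (dims == 1) 1000L else 64L^2,
                        tau = 0.01,
                        I0 = 3,
                        A = 200,
                        sigma2 = 0.1,
                        phi_shift = 0.2,
                        gamma = 0.06) {
  if (!dims %in% c(1, 2)) stop("`dims` must be 1 or 2")
  N <- as.integer(N)
  if (N < 4) stop("`N` must be at least 4 neurons per sub-population")
  if (dims == 2) {
    side <- sqrt(N)
    if (side != round(side)) {
      stop("in 2D, `N` must be a perfect square (got N = ", N, ")")
    }
  }
  if (tau <= 0) stop("`tau` must be positive")
  if (sigma2 <= 0) stop("`sigma2` must be positive")
  if (phi_shift <= 0 || phi_shift >= 0.5) {
    stop("`phi_shift` must lie strictly between 0 and 0.5")
  }
  if (gamma < 0) stop("`gamma` must be nonnegative")
  structure(
    list(dims = as.integer(dims), N = N, tau = tau, I0 = I0, A = A,
         sigma2 = sigma2, phi_shift = phi_shift, gamma = gamma,
         n_sub = 2L * as.integer(dims), n_neurons = 2L * as.integer(dims) * N),
    class = "module_spec"
  )
}

#' @export
print.module_spec <- function(x, ...) {
  cat(sprintf(
    "<module_spec> %dD, %d neurons/sub-population (%d total)\n",
    x$dims, x$N, x$n_neurons
  ))
  cat(sprintf(
    "  tau = %g s, I0 = %g, A = %g, sigma2 = %g, phi = %g, gamma = %g\n",
    x$tau, x$I0, x$A, x$sigma2, x$phi_shift, x$gamma
  ))
  invisible(x)
}

#' Basis of the rhombic (twisted-torus) phase lattice
#'
#' Columns are the lattice generators u1 = (1, 0) and
#' u2 = (1/2, sqrt(3)/2). A 2D module phase is a point on the torus obtained
#' by gluing opposite edges of the rhombus spanned by u1 and u2; gluing along
#' this 60-degree rhombus is what makes single-cell firing fields hexagonal.
#'
#' @return A 2x2 matrix with the generators as columns.
#' @export
hex_basis <- function() {
  matrix(c(1, 0, 0.5, sqrt(3) / 2), nrow = 2, ncol = 2)
}
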