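#' Distance-dependent weight kernel
#'
#' All recurrent weights are drawn from
#' \eqn{w(\theta) = \frac{A}{n}[\exp(-\theta^2 / 2\sigma^2) - 1]}
#' evaluated at the periodic distance between the (shifted) preferred phases,
#' where `n` is the total number of neurons in the module (2N in 1D, 4N in
#' 2D). The kernel is zero at distance zero and negative elsewhere:
#' the network is inhibition-dominated and the bump forms where inhibition is
#' weakest.
#'
#' @param d Periodic distance(s), phase units (nonnegative).
#' @param spec A [module_spec()].
#' @return Weight value(s), all in \eqn{(-A/n, 0]}.
#' @export
weight_kernel <- function(d, spec) {
  (spec$A / spec$n_neurons) * (exp(-d^2 / (2 * spec$sigma2)) - 1)
}

# One block-row of the recurrent weight matrix. All block-rows are identical
# (every sub-population receives the same recurrent input), so dynamics only
# ever need this N x n_neurons slab.
ring_block_row <- function(spec, phases) {
  D <- outer(phases, phases, "-")
  Wp <- weight_kernel(ring_distance(D - spec$phi_shift), spec)
  Wm <- weight_kernel(ring_distance(D + spec$phi_shift), spec)
  cbind(Wp, Wm)
}

torus_block_row <- function(spec, theta) {
  DX <- outer(theta[, 1], theta[, 1], "-")
  DY <- outer(theta[, 2], theta[, 2], "-")
  phi <- spec$phi_shift
  WR <- weight_kernel(torus_distance(DX - phi, DY), spec)
  WL <- weight_kernel(torus_distance(DX + phi, DY), spec)
  WU <- weight_kernel(torus_distance(DX, DY - phi), spec)
  WD <- weight_kernel(torus_distance(DX, DY + phi), spec)
  cbind(WR, WL, WU, WD)
}

check_uniform_phases <- function(phases) {
  N <- length(phases)
  ref <- phases[1] + (0:(N - 1)) / N
  if (max(abs((phases - ref) %% 1)) > 1e-12 &&
      max(abs(1 - (phases - ref) %% 1)) > 1e-12) {
    stop("preferred phases must form a uniform grid on [0, 1)")
  }
  invisible(TRUE)
}

#' Recurrent weights of a 1D double-ring module
#'
#' Assembles the full \eqn{2N \times 2N} connectivity: outgoing weights from
#' the right (left) sub-population are shifted clockwise (anti-clockwise) by
#' `phi_shift`, i.e. \eqn{W^\pm_{ij} = w(|\theta_i - \theta_j \mp
#' \varphi|_P)}, and both block-rows (inputs to R and to L) are identical.
#'
#' @param spec A 1D [module_spec()].
#' @param phases Optional neuron preferred phases; must be a uniform grid on
#'   \[0, 1). Defaults to `(0:(N-1))/N`.
#' @return The \eqn{2N \times 2N} weight matrix.
#' @export
ring_weights <- function(spec, phases = NULL) {
  if (spec$dims != 1) stop("`spec` must be one-dimensional")
  if (is.null(phases)) phases <- (0:(spec$N - 1)) / spec$N
  if (length(phases) != spec$N) stop("`phases` must have length N")
  check_uniform_phases(phases)
  br <- ring_block_row(spec, phases)
  rbind(br, br)
}

#' Recurrent weights of a 2D twisted-torus module
#'
#' Assembles the full \eqn{4N \times 4N} connectivity of a four-population
#' (R/L/U/D) module whose neurons sit on a regular \eqn{\sqrt N \times \sqrt
#' N} lattice over the rhombic unit cell. Outgoing weights of the R/L
#' sub-populations are shifted by \eqn{\mp(\varphi, 0)} and those of U/D by
#' \eqn{\mp(0, \varphi)} (Cartesian phase coordinates); all four block-rows
#' are identical.
#'
#' @param spec A 2D [module_spec()] (N must be a perfect square).
#' @return The \eqn{4N \times 4N} weight matrix.
#' @export
torus_weights <- function(spec) {
  if (spec$dims != 2) stop("`spec` must be two-dimensional")
  net <- build_network(spec)
  net$W
}

#' Build a single-module attractor network
#'
#' Realises the connectivity and neuron geometry of one module: preferred
#' phases on a uniform ring (1D) or regular rhombic lattice (2D),
#' sub-population labels, and the recurrent weight matrix. The 2D lattice is
#' deterministic (evenly spaced), which makes discrete translations exact
#' symmetries of the network.
#'
#' @param spec A [module_spec()].
#' @param phases Optional 1D preferred phases (uniform grid); ignored in 2D.
#' @return An object of class `attractor_network` with elements
#'   `spec`, `phases` (1D: vector; 2D: N x 2 matrix of Cartesian phase
#'   coordinates), `lattice` (2D only: N x 2 matrix of lattice coordinates in
#'   \[0,1)), `subpop` (factor with levels R,L and in 2D U,D), `W` (full
#'   weight matrix) and `W_red` (the single distinct block-row used by the
#'   integrator).
#' @examples
#' net <- build_network(module_spec(dims = 1, N = 64))
#' dim(net$W)
#' @export
build_network <- function(spec, phases = NULL) {
  stopifnot(inherits(spec, "module_spec"))
  if (spec$dims == 1) {
    if (is.null(phases)) phases <- (0:(spec$N - 1)) / spec$N
    if (length(phases) != spec$N) stop("`phases` must have length N")
    check_uniform_phases(phases)
    W_red <- ring_block_row(spec, phases)
    subpop <- factor(rep(c("R", "L"), each = spec$N), levels = c("R", "L"))
    lattice <- NULL
    theta <- phases
  } else {
    side <- as.integer(sqrt(spec$N))
    g <- (0:(side - 1)) / side
    lat <- cbind(a = rep(g, times = side), b = rep(g, each = side))
    B <- hex_basis()
    theta <- lat %*% t(B) # Cartesian phase coordinates
    W_red <- torus_block_row(spec, theta)
    subpop <- factor(rep(c("R", "L", "U", "D"), each = spec$N),
                     levels = c("R", "L", "U", "D"))
    lattice <- lat
  }
  W <- do.call(rbind, rep(list(W_red), spec$n_sub))
  structure(
    list(spec = spec, phases = theta, lattice = lattice,
         subpop = subpop, W = W, W_red = W_red),
    class = "attractor_network"
  )
}

#' @export
print.attractor_network <- function(x, ...) {
  cat(sprintf("<attractor_network> %dD, %d neurons (%s)\n",
              x$spec$dims, x$spec$n_neurons,
              paste(levels(x$subpop), collapse = "/")))
  invisible(x)
}

# Row indices of one sub-population within the stacked synaptic vector.
subpop_index <- function(net, pop) {
  k <- match(pop, levels(net$subpop))
  (k - 1L) * net$spec$N + seq_len(net$spec$N)
}

#' Synaptic state of one module
#'
#' Bundles the synaptic activation vector with the current time. Firing
#' rates, when available from the last integration step, ride along in `r`.
#'
#' @param s Synaptic activation vector (length `n_neurons`).
#' @param t Time in seconds.
#' @param r Optional firing-rate vector from the producing step.
#' @return An object of class `synaptic_state`.
#' @export
synaptic_state <- function(s, t = 0, r = NULL) {
  if (any(!is.finite(s))) {
    stop("non-finite synaptic activation at neuron ",
         which(!is.finite(s))[1])
  }
  structure(list(s = as.numeric(s), t = t, r = r), class = "synaptic_state")
}

#' Gaussian initial bump
#'
#' Initial condition for relaxation: a Gaussian activity profile of width
#' `width` (phase units) centred at `phase`, copied into every
#' sub-population.
#'
#' @param net An [build_network()] result.
#' @param phase Centre phase: scalar (1D) or lattice-coordinate pair (2D).
#' @param width Gaussian width; defaults to the connectivity width
#'   \eqn{\sigma}.
#' @return A [synaptic_state()].
#' @export
bump_state <- function(net, phase = 0, width = sqrt(net$spec$sigma2)) {
  spec <- net$spec
  if (spec$dims == 1) {
    d <- ring_distance(net$phases - phase)
  } else {
    if (length(phase) == 1) phase <- c(phase, phase)
    B <- hex_basis()
    ctr <- as.vector(B %*% phase)
    d <- torus_distance(net$phases[, 1] - ctr[1], net$phases[, 2] - ctr[2])
  }
  prof <- exp(-d^2 / (2 * width^2))
  synaptic_state(rep(prof, spec$n_sub), t = 0)
}

# Periodic (bi)linear interpolation used to translate a per-sub-population
# field by a fractional number of lattice sites.
shift_field_1d <- function(f, dphase) {
  N <- length(f)
  k <- dphase * N
  k0 <- floor(k)
  w <- k - k0
  idx <- seq_len(N)
  i0 <- ((idx - 1 - k0) %% N) + 1
  i1 <- ((idx - 2 - k0) %% N) + 1
  (1 - w) * f[i0] + w * f[i1]
}

shift_field_2d <- function(f, side, da, db) {
  # f is a length side^2 vector in lattice order (a fastest)
  M <- matrix(f, side, side)
  ka <- da * side; kb <- db * side
  a0 <- floor(ka); wa <- ka - a0
  b0 <- floor(kb); wb <- kb - b0
  rot <- function(M, ra, rb) {
    ia <- ((seq_len(side) - 1 - ra) %% side) + 1
    ib <- ((seq_len(side) - 1 - rb) %% side) + 1
    M[ia, ib, drop = FALSE]
  }
  out <- (1 - wa) * (1 - wb) * rot(M, a0, b0) +
    wa * (1 - wb) * rot(M, a0 + 1, b0) +
    (1 - wa) * wb * rot(M, a0, b0 + 1) +
    wa * wb * rot(M, a0 + 1, b0 + 1)
  as.vector(out)
}

#' Translate a module state along the attractor
#'
#' Shifts the activity pattern by `dphase` (1D: scalar phase; 2D: lattice
#' coordinate pair). Integer numbers of lattice sites are exact neuron
#' permutations; fractional shifts use periodic (bi)linear interpolation of
#' the per-sub-population fields, which is accurate because the bump is wide
#' compared to the lattice spacing.
#'
#' @param net The network.
#' @param state A [synaptic_state()] (or bare numeric vector).
#' @param dphase Shift, phase units (per lattice coordinate in 2D).
#' @return The translated state (same class as the input).
#' @export
translate_state <- function(net, state, dphase) {
  s <- if (inherits(state, "synaptic_state")) state$s else state
  spec <- net$spec
  N <- spec$N
  out <- numeric(length(s))
  for (k in seq_len(spec$n_sub)) {
    idx <- (k - 1L) * N + seq_len(N)
    if (spec$dims == 1) {
      out[idx] <- shift_field_1d(s[idx], dphase)
    } else {
      side <- as.integer(sqrt(N))
      out[idx] <- shift_field_2d(s[idx], side, dphase[1], dphase[2])
    }
  }
  if (inherits(state, "synaptic_state")) {
    r <- if (!is.null(state$r)) translate_state(net, state$r, dphase) else NULL
    synaptic_state(out, t = state$t, r = r)
  } else {
    out
  }
}
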