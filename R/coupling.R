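#' Linear velocity readout of a module
#'
#' The difference between the summed synaptic activations of the two
#' oppositely-shifted sub-populations approximates the bump's phase
#' velocity: \eqn{\omega_x = (\beta/\tau)(\sum_{i \in R} s_i - \sum_{i \in L}
#' s_i)}, and in 2D \eqn{\omega_y} likewise from U and D. This linear
#' functional of the activity is the signal broadcast between modules.
#'
#' @param state A [synaptic_state()] or activation vector.
#' @param net The network.
#' @param beta Readout scale \eqn{\beta}; the dynamics are invariant to it
#'   because the input-scaling factor `a` absorbs it.
#' @return Named numeric: `x` (and `y` in 2D), phase units per second.
#' @export
velocity_readout <- function(state, net, beta = 1) {
  s <- if (inherits(state, "synaptic_state")) state$s else state
  spec <- net$spec
  f <- beta / spec$tau
  out <- c(x = f * (sum(s[subpop_index(net, "R")]) -
                      sum(s[subpop_index(net, "L")])))
  if (spec$dims == 2) {
    out <- c(out, y = f * (sum(s[subpop_index(net, "U")]) -
                             sum(s[subpop_index(net, "D")])))
  }
  out
}

#' Input-scaling factor of the coupling
#'
#' The factor \eqn{a = [\beta \sum_i \phi'(\sum_j W_{ij}\bar s_j + I_0)]^{-1}}
#' evaluated at the steady bump \eqn{\bar s}. With the rectified-linear
#' transfer function, \eqn{\phi'} is \eqn{1/\tau} on neurons with positive
#' net input and 0 otherwise (the subgradient 0 is used at exactly zero), so
#' `a = tau / (beta * n_active)`. It normalises the units of the coupling
#' strengths and makes the product `a * omega` independent of `beta`.
#'
#' @param net The network.
#' @param state The relaxed steady state.
#' @param beta Readout scale.
#' @return The scalar `a`.
#' @export
compute_input_scaling <- function(net, state, beta = 1) {
  s <- if (inherits(state, "synaptic_state")) state$s else state
  spec <- net$spec
  u <- rep(as.vector(net$W_red %*% s), spec$n_sub) + spec$I0
  n_act <- sum(u > 0)
  if (n_act == 0) stop("no active neurons: input-scaling factor undefined")
  spec$tau / (beta * n_act)
}

#' Coupling weights between two modules as explicit synapses
#'
#' The velocity coupling can be realised by all-to-all synapses whose
#' magnitude is uniform (\eqn{\beta/\tau}) and whose sign depends only on
#' the sub-populations of the pre- and post-synaptic neurons: positive
#' between same-polarity populations (R-R, L-L, U-U, D-D), negative between
#' opposite polarities within a channel, and zero across the horizontal
#' (R/L) and vertical (U/D) channels.
#'
#' @param beta Readout scale.
#' @param tau Synaptic time constant.
#' @param subpop_post,subpop_pre Factors/character vectors of sub-population
#'   labels ("R","L","U","D") for the post- and pre-synaptic module.
#' @return Matrix of dimension `length(subpop_post) x length(subpop_pre)`.
#' @export
coupling_weight_matrix <- function(beta, tau, subpop_post, subpop_pre) {
  chan <- c(R = 1, L = 1, U = 2, D = 2)
  sgn <- c(R = 1, L = -1, U = 1, D = -1)
  post_c <- unname(chan[as.character(subpop_post)])
  pre_c <- unname(chan[as.character(subpop_pre)])
  post_s <- unname(sgn[as.character(subpop_post)])
  pre_s <- unname(sgn[as.character(subpop_pre)])
  same <- outer(post_c, pre_c, "==")
  (beta / tau) * outer(post_s, pre_s) * same
}

#' Published coupling matrices
#'
#' Reference coupling-strength matrices for two and three modules, with self
#' coupling \eqn{C_s = -20} on the diagonal. For `m = 2` the inter-module
#' couplings follow \eqn{C_1 = -C_s/\lambda}, \eqn{C_2 = -C_s\lambda} with
#' spacing ratio \eqn{\lambda = \sqrt 2}; for `m = 3` the matrix is
#' tridiagonal (coupling only between modules of adjacent spacing).
#' Entry \eqn{C_{\mu\rho}} is the coupling from module \eqn{\rho} to module
#' \eqn{\mu}.
#'
#' @param m Module count, 2 or 3; other values require a user-supplied
#'   matrix.
#' @return The m x m coupling matrix.
#' @examples
#' standard_coupling(2)
#' check_stability(standard_coupling(3))
#' @export
standard_coupling <- function(m) {
  lam <- sqrt(2)
  if (m == 2) {
    rbind(c(-20, 20 / lam),
          c(20 * lam, -20))
  } else if (m == 3) {
    rbind(c(-20, 14.14, 0),
          c(9.4, -20, 9.4),
          c(0, 28.3, -20))
  } else {
    stop("reference coupling matrices are shipped for m = 2 or 3 only; ",
         "supply your own matrix for other module counts")
  }
}

#' Spacing ratio between successive modules
#'
#' @return \eqn{\lambda = \sqrt 2}, the ratio of grid spacings of successive
#'   modules implied by the reference couplings and velocity gains.
#' @export
spacing_ratio <- function() sqrt(2)

#' Assemble a system of identically built, velocity-coupled modules
#'
#' Builds one attractor network (all modules share the architecture), relaxes
#' it to the steady bump, places each module's bump at the requested phase by
#' translation, and computes the input-scaling factor `a` once from the
#' uncoupled steady state (it is then held fixed during runs).
#'
#' @param spec A [module_spec()] shared by all modules.
#' @param m Number of modules.
#' @param C m x m coupling matrix (`C[mu, rho]` couples module `rho` into
#'   module `mu`); `standard_coupling(m)` by default. Use a zero matrix for
#'   uncoupled controls.
#' @param beta Readout scale.
#' @param phases Initial bump phases: scalar, vector of length m (1D), or
#'   m x 2 matrix of lattice coordinates (2D).
#' @param relax_dt,T_relax Relaxation integrator settings.
#' @param net,base_state Optionally reuse an already-built network and its
#'   relaxed steady state (e.g. when constructing coupled and uncoupled
#'   variants of the same architecture).
#' @return An object of class `coupled_system`: the shared `net`, `C`,
#'   `beta`, `a`, the relaxed `base_state` and per-module `states`.
#' @export
coupled_system <- function(spec, m, C = standard_coupling(m), beta = 1,
                           phases = 0, relax_dt = 1e-4,
                           T_relax = 50 * spec$tau,
                           net = NULL, base_state = NULL) {
  stopifnot(inherits(spec, "module_spec"))
  C <- as.matrix(C)
  if (!all(dim(C) == c(m, m))) stop("`C` must be an m x m matrix")
  if (any(!is.finite(C))) stop("`C` must be finite")
  if (is.null(net)) net <- build_network(spec)
  base <- if (!is.null(base_state)) base_state else
    relax_to_bump(net, phase = if (spec$dims == 1) 0.5 else c(0.5, 0.5),
                  dt = relax_dt, T_relax = T_relax)
  a <- compute_input_scaling(net, base, beta)
  u <- rep(as.vector(net$W_red %*% base$s), spec$n_sub) + spec$I0
  n_act <- sum(u > 0)
  p0 <- attr(base, "phase")
  ph <- normalize_phases(phases, m, spec$dims)
  states <- lapply(seq_len(m), function(mu) {
    dp <- if (spec$dims == 1) ph[mu] - p0 else ph[mu, ] - p0
    translate_state(net, base, dp)
  })
  structure(
    list(net = net, m = m, C = C, beta = beta, a = a,
         n_act = n_act, v_scale = 1 / n_act,
         base_state = base, states = states),
    class = "coupled_system"
  )
}

normalize_phases <- function(phases, m, dims) {
  if (dims == 1) {
    if (length(phases) == 1) phases <- rep(phases, m)
    if (length(phases) != m) stop("`phases` must have length m")
    phases
  } else {
    if (is.null(dim(phases))) {
      if (length(phases) == 1) phases <- c(phases, phases)
      if (length(phases) == 2) {
        phases <- matrix(phases, m, 2, byrow = TRUE)
      }
    }
    phases <- as.matrix(phases)
    if (!all(dim(phases) == c(m, 2))) stop("`phases` must be m x 2 in 2D")
    phases
  }
}

#' @export
print.coupled_system <- function(x, ...) {
  cat(sprintf("<coupled_system> m = %d modules, %dD, %d neurons each\n",
              x$m, x$net$spec$dims, x$net$spec$n_neurons))
  cat("  coupling C:\n")
  print(round(x$C, 3))
  cat(sprintf("  beta = %g, a = %g\n", x$beta, x$a))
  invisible(x)
}

#' Per-neuron feedforward drives of the coupled system
#'
#' Neuron i of module \eqn{\mu} in sub-population R receives
#' \eqn{I_0 + b_{\mu,x} + a \sum_\rho C_{\mu\rho}\,\omega_{\rho,x}}; L
#' receives the same with a minus sign; U/D likewise with the y components.
#' Horizontal and vertical channels are fully independent.
#'
#' @param system A [coupled_system()].
#' @param b External velocity inputs: vector of length m (1D) or m x 2
#'   matrix (2D), drive units.
#' @param states Optional list of per-module states (defaults to
#'   `system$states`).
#' @return List of per-neuron feedforward vectors, one per module, with the
#'   total velocity inputs in `attr(, "v")` and readouts in
#'   `attr(, "omega")`.
#' @export
assemble_coupled_drive <- function(system, b, states = NULL) {
  spec <- system$net$spec
  m <- system$m
  dims <- spec$dims
  if (is.null(states)) states <- system$states
  b <- if (dims == 1) matrix(b, ncol = 1) else as.matrix(b)
  if (nrow(b) != m || ncol(b) != dims) {
    stop("`b` must supply one scalar per module per direction (m x dims)")
  }
  omega <- t(vapply(states, function(st)
    velocity_readout(st, system$net, system$beta), numeric(dims)))
  omega <- matrix(omega, nrow = m)
  v <- b + system$a * (system$C %*% omega)
  N <- spec$N
  ff <- lapply(seq_len(m), function(mu) {
    if (dims == 1) {
      spec$I0 + c(rep(v[mu, 1], N), rep(-v[mu, 1], N))
    } else {
      spec$I0 + c(rep(v[mu, 1], N), rep(-v[mu, 1], N),
                  rep(v[mu, 2], N), rep(-v[mu, 2], N))
    }
  })
  attr(ff, "v") <- v
  attr(ff, "omega") <- omega
  ff
}
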