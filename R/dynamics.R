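#' One Euler step of the rate dynamics
#'
#' Integrates \eqn{\tau^{-1}}-rectified rate dynamics
#' \eqn{\dot s_i = -s_i/\tau + r_i}, with
#' \eqn{r_i = \phi(\sum_j W_{ij} s_j + \mathrm{ff}_i)} and
#' \eqn{\phi(x) = \tau^{-1}\max(x, 0)}, by one explicit Euler step.
#'
#' @param net An `attractor_network`.
#' @param state A [synaptic_state()].
#' @param feedforward Per-neuron feedforward drive (length `n_neurons`);
#'   includes the constant input and any velocity terms.
#' @param dt Time step in seconds; must satisfy `dt <= tau/10`.
#' @return The updated state; the firing rates used for the step are
#'   returned in `$r`.
#' @export
step_rate_dynamics <- function(net, state, feedforward, dt) {
  spec <- net$spec
  check_dt(dt, spec$tau)
  s <- state$s
  if (length(feedforward) != spec$n_neurons) {
    stop("`feedforward` must have one entry per neuron (",
         spec$n_neurons, ")")
  }
  u <- rep(as.vector(net$W_red %*% s), spec$n_sub) + feedforward
  r <- pmax(u, 0) / spec$tau
  s_new <- s + dt * (r - s / spec$tau)
  bad <- which(!is.finite(s_new) | !is.finite(r))
  if (length(bad)) {
    stop("non-finite synaptic activation or rate at neuron ", bad[1])
  }
  synaptic_state(s_new, t = state$t + dt, r = r)
}

#' One Euler step of the Poisson-spiking dynamics
#'
#' Replaces the deterministic rate by a Poisson spike train: per-neuron spike
#' counts are drawn with mean \eqn{r_i \, dt} (rates defined exactly as in
#' [step_rate_dynamics()]), each spike increments the neuron's synaptic
#' activation by one, and the activation decays with time constant
#' \eqn{\tau}. Uses R's global random-number generator; seed the caller for
#' reproducibility.
#'
#' @inheritParams step_rate_dynamics
#' @return A list with the updated `state` and the integer vector `spikes`
#'   of counts emitted this step.
#' @export
step_poisson_dynamics <- function(net, state, feedforward, dt) {
  spec <- net$spec
  check_dt(dt, spec$tau)
  s <- state$s
  if (length(feedforward) != spec$n_neurons) {
    stop("`feedforward` must have one entry per neuron (",
         spec$n_neurons, ")")
  }
  u <- rep(as.vector(net$W_red %*% s), spec$n_sub) + feedforward
  r <- pmax(u, 0) / spec$tau
  spikes <- stats::rpois(length(r), r * dt)
  s_new <- s * (1 - dt / spec$tau) + spikes
  list(state = synaptic_state(s_new, t = state$t + dt, r = r),
       spikes = spikes)
}

check_dt <- function(dt, tau) {
  if (dt <= 0 || dt > tau / 10 + 1e-15) {
    stop("`dt` must be positive and at most tau/10 = ", tau / 10, " s")
  }
  invisible(TRUE)
}

bump_ratio <- function(net, s) {
  stot <- rowSums(matrix(s, net$spec$N, net$spec$n_sub))
  m <- mean(stot)
  if (m <= 0) return(0)
  max(stot) / m
}

#' Relax a module to its steady activity bump
#'
#' Integrates the rate dynamics with constant drive `I0` and zero velocity
#' input until the activity settles on the stationary bump. The returned
#' state is the steady state used as the starting point of every simulation
#' and analysis.
#'
#' @param net The network.
#' @param phase Requested bump centre (scalar in 1D, lattice pair in 2D);
#'   used to build the Gaussian initial condition when `init` is `NULL`.
#' @param init Optional initial [synaptic_state()] (overrides `phase`).
#' @param T_relax Relaxation time in seconds, at least `50 * tau`.
#' @param dt Integration step.
#' @param drift_tol Maximum tolerated bump-phase drift over the last 10% of
#'   the relaxation, phase units.
#' @return The relaxed [synaptic_state()] with rates in `$r` and the bump
#'   phase in `attr(, "phase")`.
#' @export
relax_to_bump <- function(net, phase = 0, init = NULL,
                          T_relax = 50 * net$spec$tau, dt = 1e-4,
                          drift_tol = 1e-4) {
  spec <- net$spec
  if (T_relax < 50 * spec$tau) stop("`T_relax` must be at least 50 * tau")
  state <- if (is.null(init)) bump_state(net, phase) else init
  ff <- rep(spec$I0, spec$n_neurons)
  nstep <- ceiling(T_relax / dt)
  tail_start <- floor(0.9 * nstep)
  p_tail <- NA_real_
  for (k in seq_len(nstep)) {
    state <- step_rate_dynamics(net, state, ff, dt)
    if (k == tail_start) {
      assert_bump(net, state)
      p_tail <- estimate_phase(state, net)
    }
  }
  assert_bump(net, state)
  p_end <- estimate_phase(state, net)
  drift <- max(abs(ring_distance(p_end - p_tail)))
  if (drift > drift_tol) {
    stop("bump phase still drifting after relaxation (drift = ",
         signif(drift, 3), " phase units)")
  }
  attr(state, "phase") <- p_end
  state
}

assert_bump <- function(net, state, min_ratio = 1.5) {
  if (bump_ratio(net, state$s) < min_ratio) {
    stop("no bump formed: population activity profile is flat ",
         "(max/mean ratio below ", min_ratio, ")")
  }
  invisible(TRUE)
}

#' Estimate the bump phase by the circular population vector
#'
#' For each periodic coordinate, the phase is the argument of
#' \eqn{\sum_i s_i e^{2\pi i \theta_i} / 2\pi}, summed over all
#' sub-populations. In 2D the two lattice coordinates are estimated
#' independently.
#'
#' @param state A [synaptic_state()] (or bare activation vector).
#' @param net The network.
#' @return Scalar phase in \[0, 1) (1D) or the lattice-coordinate pair (2D).
#' @export
estimate_phase <- function(state, net) {
  s <- if (inherits(state, "synaptic_state")) state$s else state
  spec <- net$spec
  stot <- rowSums(matrix(s, spec$N, spec$n_sub))
  m <- mean(stot)
  if (m <= 0 || max(stot) / m < 1.5) {
    stop("flat activity: cannot estimate a bump phase")
  }
  if (spec$dims == 1) {
    (Arg(sum(stot * exp(2i * pi * net$phases))) / (2 * pi)) %% 1
  } else {
    a <- (Arg(sum(stot * exp(2i * pi * net$lattice[, 1]))) / (2 * pi)) %% 1
    b <- (Arg(sum(stot * exp(2i * pi * net$lattice[, 2]))) / (2 * pi)) %% 1
    c(a = a, b = b)
  }
}
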