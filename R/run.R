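#' Integrate a coupled multi-module system
#'
#' Steps all modules simultaneously: at every time step each module's
#' feedforward drive is assembled from the external velocity input, the
#' velocity readouts of all modules weighted by the coupling matrix, and the
#' constant input. Phases (estimated by the circular population vector and
#' unwrapped by nearest-image continuity) and velocity readouts are recorded
#' at a configurable stride.
#'
#' @param system A [coupled_system()].
#' @param b External velocity input: `NULL` (zero input), a function of time
#'   returning an m x dims matrix, a [make_velocity_drive()] object, or an
#'   array `[m, nstep, dims]`.
#' @param T Duration in seconds (required unless `b` is an array/drive whose
#'   length defines it).
#' @param dt Integration step, seconds.
#' @param mode `"rate"` for deterministic dynamics, `"poisson"` for spiking.
#' @param record_dt Sampling interval of the recorded trajectories.
#' @param seed Optional seed (Poisson mode).
#' @param collect_spikes Keep the full spike raster (Poisson mode; intended
#'   for small networks).
#' @param s_ceiling Abort threshold on `|s|`; exceeding it aborts with a
#'   pointer to [check_stability()].
#' @return A list of class `coupled_run`: `t`, `theta` (array
#'   `[n_rec, m, dims]`, unwrapped), `theta_wrapped`, `omega` (same shape),
#'   `final_states`, and optionally `spikes`.
#' @export
run_coupled <- function(system, b = NULL, T = NULL, dt = 1e-4,
                        mode = c("rate", "poisson"), record_dt = 0.01,
                        seed = NULL, collect_spikes = FALSE,
                        s_ceiling = 1e3) {
  mode <- match.arg(mode)
  spec <- system$net$spec
  dims <- spec$dims
  m <- system$m
  if (!is.null(seed)) set.seed(seed)

  barr <- drive_to_array(b, m, dims, T, dt)
  nstep <- dim(barr$Bx)[3]
  if (is.null(nstep)) nstep <- ceiling(T / dt)
  stride <- max(1L, round(record_dt / dt))

  S0 <- do.call(cbind, lapply(system$states, function(st) st$s))
  res <- integrate_modules(
    system$net, m = m, K = 1L, C = system$C, a = system$a,
    beta = system$beta, S0 = S0, Bx = barr$Bx, By = barr$By,
    dt = dt, nstep = nstep, mode = mode, record_stride = stride,
    collect_spikes = collect_spikes, v_scale = system$v_scale,
    s_ceiling = s_ceiling
  )

  n_rec <- length(res$t)
  theta_w <- array(NA_real_, c(n_rec, m, dims))
  theta_w[, , 1] <- res$phase_a
  if (dims == 2) theta_w[, , 2] <- res$phase_b
  theta <- theta_w
  for (mu in seq_len(m)) {
    for (d in seq_len(dims)) theta[, mu, d] <- unwrap_phase(theta[, mu, d])
  }
  omega <- array(NA_real_, c(n_rec, m, dims))
  omega[, , 1] <- res$omega_x
  if (dims == 2) omega[, , 2] <- res$omega_y

  final <- lapply(seq_len(m), function(mu)
    synaptic_state(res$S[, mu], t = nstep * dt))
  structure(
    list(t = res$t, theta = theta, theta_wrapped = theta_w, omega = omega,
         final_states = final, spikes = res$spikes, dt = dt, mode = mode),
    class = "coupled_run"
  )
}

# Normalise the many accepted forms of the external velocity input to
# [m, 1, nstep] arrays per direction (K = 1).
drive_to_array <- function(b, m, dims, T, dt) {
  if (is.null(b)) {
    if (is.null(T)) stop("supply `T` when `b` is NULL")
    nstep <- ceiling(T / dt)
    return(list(Bx = array(0, c(m, 1, nstep)),
                By = if (dims == 2) array(0, c(m, 1, nstep)) else NULL))
  }
  if (inherits(b, "velocity_drive")) {
    if (abs(b$dt - dt) > 1e-12) {
      stop("drive sampled at dt = ", b$dt, " but integrator uses dt = ", dt)
    }
    nstep <- dim(b$b)[2]
    Bx <- array(b$b[, , 1], c(m, 1, nstep))
    By <- if (dims == 2) array(b$b[, , 2], c(m, 1, nstep)) else NULL
    return(list(Bx = Bx, By = By))
  }
  if (is.function(b)) {
    if (is.null(T)) stop("supply `T` when `b` is a function")
    nstep <- ceiling(T / dt)
    Bx <- array(0, c(m, 1, nstep))
    By <- if (dims == 2) array(0, c(m, 1, nstep)) else NULL
    for (k in seq_len(nstep)) {
      bk <- b((k - 1) * dt)
      bk <- if (dims == 1) matrix(bk, ncol = 1) else as.matrix(bk)
      Bx[, 1, k] <- bk[, 1]
      if (dims == 2) By[, 1, k] <- bk[, 2]
    }
    return(list(Bx = Bx, By = By))
  }
  b <- as.array(b)
  if (length(dim(b)) == 2) b <- array(b, c(dim(b), 1)) # [m, nstep] 1D
  if (dim(b)[1] != m || dim(b)[3] < dims) {
    stop("`b` array must be [m, nstep, dims]")
  }
  nstep <- dim(b)[2]
  list(Bx = array(b[, , 1], c(m, 1, nstep)),
       By = if (dims == 2) array(b[, , 2], c(m, 1, nstep)) else NULL)
}

#' Measured velocity gains and spacings of a (possibly coupled) system
#'
#' Runs the system for a short time under a constant common velocity `V`
#' (applied through each module's gain `gamma`), measures each module's
#' Cartesian phase velocity, and converts to gains and grid spacings:
#' spacing is the distance travelled per full phase cycle,
#' \eqn{\lambda_\mu = V / \dot\theta_\mu}. In 2D both axes are probed
#' separately: at moderate lattice sizes the discrete rhombic sheet makes
#' the gain slightly anisotropic, and a decoder built on the measured
#' per-axis gains inverts the network's actual response.
#'
#' @param system A [coupled_system()].
#' @param gamma Vector of external velocity gains, one per module.
#' @param V Probe speed, m/s.
#' @param T Probe duration, seconds.
#' @param dt Integration step.
#' @return Data frame with `module`, `gain_x` (phase velocity per m/s,
#'   `gain_y` in 2D), and `spacing_m` (from the axis-averaged gain).
#' @export
calibrate_spacings <- function(system, gamma, V = 0.2, T = 0.5, dt = NULL) {
  spec <- system$net$spec
  if (is.null(dt)) dt <- spec$tau / 20
  m <- system$m
  if (length(gamma) != m) stop("`gamma` must have length m")

  probe <- function(axis) {
    bfun <- function(t) {
      if (spec$dims == 1) gamma * V
      else if (axis == 1) cbind(gamma * V, 0) else cbind(0, gamma * V)
    }
    run <- run_coupled(system, b = bfun, T = T, dt = dt, record_dt = 5 * dt)
    n <- length(run$t)
    i0 <- max(2L, ceiling(n / 3)) # discard the filter transient
    vapply(seq_len(m), function(mu) {
      if (spec$dims == 1) {
        th <- run$theta[, mu, 1]
      } else {
        B <- hex_basis()
        cart <- cbind(run$theta[, mu, 1], run$theta[, mu, 2]) %*% t(B)
        th <- cart[, axis]
      }
      fit <- stats::lm(th[i0:n] ~ run$t[i0:n])
      unname(stats::coef(fit)[2]) / V
    }, numeric(1))
  }

  gx <- probe(1)
  if (spec$dims == 1) {
    return(data.frame(module = seq_len(m), gain_x = gx, spacing_m = 1 / gx))
  }
  gy <- probe(2)
  data.frame(module = seq_len(m), gain_x = gx, gain_y = gy,
             spacing_m = 2 / (gx + gy))
}
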