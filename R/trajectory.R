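#' Synthetic foraging trajectory
#'
#' Generates a smooth, bounded random path emulating the statistics of a
#' foraging rodent: each velocity component follows a mean-reverting
#' (Ornstein-Uhlenbeck) process, giving a persistent heading on the time
#' scale `tau_v` and a Rayleigh-distributed speed (2D) with the requested
#' mean; reflecting walls keep the path inside the rectangular arena.
#' Positions are the exact Euler integral of the returned velocities, so
#' finite differences of the positions reproduce the velocities to machine
#' precision.
#'
#' @param T Duration, seconds.
#' @param dt Sampling interval, seconds.
#' @param dims 1 or 2.
#' @param arena Arena side lengths in meters (length `dims`); default a
#'   1.5 m x 1.5 m box, a typical foraging enclosure.
#' @param speed_mean Mean running speed, m/s.
#' @param tau_v Velocity correlation time, seconds.
#' @param seed Seed; the trajectory is a deterministic function of it.
#' @param start Start position; defaults to the arena centre.
#' @return Object of class `trajectory`: data frame `path` with columns
#'   `t`, `x`(, `y`) and velocity columns `vx`(, `vy`), plus `dt`, `arena`.
#'   `vx[k]` is the velocity used on the step from sample k to k+1.
#' @export
generate_trajectory <- function(T, dt, dims = 2,
                                arena = rep(1.5, dims),
                                speed_mean = 0.2, tau_v = 0.7,
                                seed = NULL, start = arena / 2) {
  if (T <= 0 || dt <= 0) stop("`T` and `dt` must be positive")
  if (length(arena) != dims) stop("`arena` must have length `dims`")
  if (any(arena <= 0)) stop("arena sides must be positive")
  if (any(arena < speed_mean * dt)) {
    stop("arena smaller than a single step at the requested speed")
  }
  if (!is.null(seed)) set.seed(seed)
  n <- ceiling(T / dt) + 1L
  # stationary per-component sd giving the requested mean speed
  sd_c <- if (dims == 2) speed_mean / sqrt(pi / 2) else
    speed_mean * sqrt(pi / 2)
  v <- matrix(0, n, dims)
  x <- matrix(start, n, dims, byrow = TRUE)
  if (speed_mean > 0) {
    v[1, ] <- stats::rnorm(dims, 0, sd_c)
    noise_sd <- sd_c * sqrt(2 * dt / tau_v)
    eta <- matrix(stats::rnorm((n - 1) * dims, 0, noise_sd), n - 1, dims)
    for (k in seq_len(n - 1)) {
      vk <- v[k, ]
      xk <- x[k, ] + vk * dt
      # reflecting walls
      for (d in seq_len(dims)) {
        if (xk[d] < 0) { xk[d] <- -xk[d]; vk[d] <- -vk[d] }
        if (xk[d] > arena[d]) { xk[d] <- 2 * arena[d] - xk[d]; vk[d] <- -vk[d] }
      }
      v[k, ] <- vk # velocity actually applied on this step
      x[k + 1, ] <- xk
      v[k + 1, ] <- vk - (dt / tau_v) * vk + eta[k, ]
    }
    # make stored velocities the exact finite differences
    v[seq_len(n - 1), ] <- (x[-1, , drop = FALSE] -
                              x[-n, , drop = FALSE]) / dt
    v[n, ] <- v[n - 1, ]
  }
  path <- data.frame(t = (0:(n - 1)) * dt)
  if (dims == 1) {
    path$x <- x[, 1]; path$vx <- v[, 1]
  } else {
    path$x <- x[, 1]; path$y <- x[, 2]
    path$vx <- v[, 1]; path$vy <- v[, 2]
  }
  structure(list(path = path, dt = dt, arena = arena, dims = dims),
            class = "trajectory")
}

#' @export
print.trajectory <- function(x, ...) {
  sp <- if (x$dims == 2) sqrt(x$path$vx^2 + x$path$vy^2) else abs(x$path$vx)
  cat(sprintf(
    "<trajectory> %dD, %.1f s @ dt = %g s, arena %s m, mean speed %.3f m/s\n",
    x$dims, max(x$path$t), x$dt,
    paste(signif(x$arena, 3), collapse = " x "), mean(sp)))
  invisible(x)
}

#' Noisy per-module velocity drives
#'
#' Converts a trajectory's velocity into the external input of each module:
#' \eqn{b_{\mu,q}(t) = \gamma_\mu (V_q(t) + \eta_{\mu,q}(t))}, with
#' \eqn{\eta} a white-noise process of intensity `eta` (units
#' \eqn{m\,s^{-1/2}}), independent across modules and directions. The
#' discrete-time realisation draws Gaussian deviates of standard deviation
#' \eqn{\eta/\sqrt{dt}} per sample, honouring the continuum correlator
#' \eqn{\langle\eta(t)\eta(t')\rangle = \eta^2 \delta(t - t')}.
#'
#' @param traj A [generate_trajectory()] result (or a data frame with `t`,
#'   `vx`(, `vy`)).
#' @param gamma Velocity gains, one per module (drive units per m/s).
#' @param eta Noise intensity, m s^-1/2 (0.02 in the noisy-input
#'   experiments; 0 for noiseless drives).
#' @param seed Seed for the noise (independent of the trajectory's seed).
#' @return Object of class `velocity_drive`: array `b` of dimension
#'   `[m, nstep, dims]` plus `dt`, `gamma`, `eta`.
#' @export
make_velocity_drive <- function(traj, gamma, eta = 0, seed = NULL) {
  path <- if (inherits(traj, "trajectory")) traj$path else traj
  dt <- if (inherits(traj, "trajectory")) traj$dt else diff(path$t[1:2])
  dims <- if ("vy" %in% names(path)) 2L else 1L
  m <- length(gamma)
  if (any(gamma < 0)) stop("`gamma` must be nonnegative")
  if (eta < 0) stop("`eta` must be nonnegative")
  if (!is.null(seed)) set.seed(seed)
  nstep <- nrow(path) - 1L
  V <- cbind(path$vx[seq_len(nstep)],
             if (dims == 2) path$vy[seq_len(nstep)])
  b <- array(0, c(m, nstep, dims))
  sd_n <- eta / sqrt(dt)
  for (q in seq_len(dims)) {
    for (mu in seq_len(m)) {
      noise <- if (eta > 0) stats::rnorm(nstep, 0, sd_n) else 0
      b[mu, , q] <- gamma[mu] * (V[, q] + noise)
    }
  }
  structure(list(b = b, dt = dt, gamma = gamma, eta = eta, dims = dims),
            class = "velocity_drive")
}

#' Read/write trajectories as CSV
#'
#' Plain-text interchange: columns `t`, `x`(, `y`). Velocities are
#' reconstructed from finite differences on read.
#'
#' @param traj A `trajectory`.
#' @param file Path.
#' @return `read_trajectory_csv` returns a `trajectory` (arena = bounding
#'   box).
#' @export
write_trajectory_csv <- function(traj, file) {
  cols <- intersect(c("t", "x", "y"), names(traj$path))
  utils::write.csv(traj$path[cols], file, row.names = FALSE)
  invisible(file)
}

#' @rdname write_trajectory_csv
#' @export
read_trajectory_csv <- function(file) {
  d <- utils::read.csv(file)
  if (!all(c("t", "x") %in% names(d))) stop("need columns t, x[, y]")
  dims <- if ("y" %in% names(d)) 2L else 1L
  dt <- d$t[2] - d$t[1]
  n <- nrow(d)
  d$vx <- c(diff(d$x) / dt, NA)
  d$vx[n] <- d$vx[n - 1]
  if (dims == 2) {
    d$vy <- c(diff(d$y) / dt, NA)
    d$vy[n] <- d$vy[n - 1]
  }
  arena <- if (dims == 2) c(max(d$x), max(d$y)) else max(d$x)
  structure(list(path = d, dt = dt, arena = arena, dims = dims),
            class = "trajectory")
}
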