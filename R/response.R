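#' Calibrate the single-module velocity gain
#'
#' The gain \eqn{\alpha} maps a (slow) velocity input b onto the phase
#' velocity of an uncoupled module, \eqn{\dot\theta = \alpha b}. No closed
#' form is exposed by the rectified network, so \eqn{\alpha} is measured:
#' the module is driven at several constant input levels spanning the linear
#' regime and the phase velocity is fitted by least squares.
#'
#' @param spec A [module_spec()] (a fresh network is built and relaxed), or
#'   an existing `attractor_network`.
#' @param b_levels Constant input levels (drive units); at least 5.
#' @param T Run length per level, seconds (the first third is discarded).
#' @param dt Integration step.
#' @param min_r2 Linearity guard: the fit must achieve this R-squared,
#'   otherwise an error suggests a smaller input range.
#' @return List of class `gain_fit`: `alpha`, `r2`, `intercept`, and the
#'   per-level data. The fit is through-origin symmetric by construction of
#'   the default levels.
#' @export
calibrate_gain <- function(spec, b_levels = c(-0.03, -0.015, 0.0075, 0.015, 0.03),
                           T = 0.3, dt = NULL, min_r2 = 0.999) {
  net <- if (inherits(spec, "attractor_network")) spec else
    build_network(spec)
  sp <- net$spec
  if (sp$dims != 1) stop("gain calibration uses a one-dimensional module")
  if (length(b_levels) < 5) stop("supply at least 5 input levels")
  if (is.null(dt)) dt <- sp$tau / 20
  base <- relax_to_bump(net, phase = 0.5, dt = dt)
  K <- length(b_levels)
  nstep <- ceiling(T / dt)
  Bx <- array(rep(b_levels, times = nstep), c(1, K, nstep))
  res <- integrate_modules(net, m = 1L, K = K, C = matrix(0, 1, 1), a = 1,
                           beta = 1, S0 = matrix(base$s, sp$n_neurons, K),
                           Bx = Bx, dt = dt, nstep = nstep,
                           record_stride = max(1L, round(0.005 / dt)))
  n <- length(res$t)
  i0 <- max(2L, ceiling(n / 3))
  thdot <- vapply(seq_len(K), function(k) {
    th <- unwrap_phase(res$phase_a[, k])
    unname(stats::coef(stats::lm(th[i0:n] ~ res$t[i0:n]))[2])
  }, numeric(1))
  fit <- stats::lm(thdot ~ b_levels)
  r2 <- summary(fit)$r.squared
  if (r2 < min_r2) {
    stop("phase velocity is not linear in the input over the requested ",
         "range (R^2 = ", signif(r2, 4), "); use smaller `b_levels`")
  }
  structure(
    list(alpha = unname(stats::coef(fit)[2]),
         intercept = unname(stats::coef(fit)[1]),
         r2 = r2,
         data = data.frame(b = b_levels, theta_dot = thdot)),
    class = "gain_fit"
  )
}

#' @export
print.gain_fit <- function(x, ...) {
  cat(sprintf("<gain_fit> alpha = %.4g phase/s per drive unit (R^2 = %.6f)\n",
              x$alpha, x$r2))
  invisible(x)
}

#' Linear response tensor of the coupled modules
#'
#' For velocity inputs that vary slowly compared to the synaptic time
#' constant, the module phase velocities follow
#' \eqn{\dot{\vec\theta} = X \vec b} with
#' \eqn{X = \alpha (I - C)^{-1}}. Its eigenstructure separates the gain for
#' coordinated motion (large) from the gain for relative motion
#' (suppressed). For two modules with equal self coupling the closed-form
#' eigenvalues \eqn{X_\pm = \alpha / (1 - (C_s \pm \sqrt{C_{12} C_{21}}))}
#' are also reported.
#'
#' @param C Coupling matrix.
#' @param alpha Single-module gain (any positive number; ratios of
#'   eigenvalues do not depend on it).
#' @return List of class `response_tensor`: `X`, `alpha`, `eigenvalues`,
#'   `eigenvectors`, and for the two-module symmetric case `X_plus`,
#'   `X_minus`.
#' @export
response_tensor <- function(C, alpha = 1) {
  C <- as.matrix(C)
  ev_C <- eigen(C, only.values = TRUE)$values
  if (any(abs(ev_C - 1) < 1e-12)) {
    stop("I - C is singular (C has an eigenvalue at 1): the system sits on ",
         "the stability boundary; see check_stability()")
  }
  X <- alpha * solve(diag(nrow(C)) - C)
  ev <- eigen(X)
  out <- list(X = X, alpha = alpha,
              eigenvalues = ev$values, eigenvectors = ev$vectors)
  if (nrow(C) == 2 && abs(C[1, 1] - C[2, 2]) < 1e-12) {
    Cs <- C[1, 1]
    root <- sqrt(C[1, 2] * C[2, 1] + 0i)
    out$X_plus <- alpha / (1 - (Cs + root))
    out$X_minus <- alpha / (1 - (Cs - root))
    if (abs(Im(out$X_plus)) < 1e-12) {
      out$X_plus <- Re(out$X_plus); out$X_minus <- Re(out$X_minus)
    }
  }
  structure(out, class = "response_tensor")
}

#' @export
print.response_tensor <- function(x, ...) {
  cat("<response_tensor>\n")
  print(signif(x$X, 4))
  cat("  eigenvalues:", paste(signif(x$eigenvalues, 4), collapse = ", "),
      "\n")
  invisible(x)
}

#' Stability screen of a coupling matrix
#'
#' The coupled dynamics are stable when every eigenvalue of C has real part
#' below unity; at unity the velocity feedback loop through the exponential
#' synaptic filter reaches unit gain and the system destabilises. The
#' published criterion addresses real spectra; for complex eigenvalues the
#' real part is used.
#'
#' @param C Square coupling matrix.
#' @return List: `stable` (logical) and `values` (the eigenvalues).
#' @examples
#' check_stability(standard_coupling(2))$stable # TRUE
#' check_stability(matrix(c(2, 0, 0, 0), 2))$stable # FALSE
#' @export
check_stability <- function(C) {
  C <- as.matrix(C)
  if (nrow(C) != ncol(C)) stop("`C` must be square")
  ev <- eigen(C, only.values = TRUE)$values
  list(stable = all(Re(ev) < 1), values = ev)
}

#' Integrate the phase-reduction dynamics
#'
#' The reduced description of the coupled system:
#' \eqn{\dot{\vec\theta} = \alpha \vec b(t) + C (f * \dot{\vec\theta})},
#' where f is the unit-area exponential filter with the synaptic time scale.
#' The convolution is integrated in delay-free form with the auxiliary
#' filtered velocity \eqn{\vec z = f * \dot{\vec\theta}}:
#' \eqn{\dot{\vec\theta} = \alpha \vec b + C \vec z},
#' \eqn{\dot{\vec z} = (\dot{\vec\theta} - \vec z)/\tau}.
#'
#' @param C Coupling matrix (m x m).
#' @param alpha Velocity gain.
#' @param b Input: function of time returning an m-vector, or an
#'   `[m, nstep]` matrix sampled at `dt`.
#' @param tau Filter time constant, seconds.
#' @param dt Euler step; at most `tau/10`.
#' @param T Duration (needed when `b` is a function).
#' @param theta0 Initial phases (recycled to length m).
#' @return List of class `phase_reduction_run`: `t` (length nstep + 1),
#'   `theta` (matrix `[nstep + 1, m]`), `C`, `alpha`, `tau`.
#' @export
phase_reduction <- function(C, alpha, b, tau = 0.01, dt = 1e-3, T = NULL,
                            theta0 = 0) {
  C <- as.matrix(C)
  m <- nrow(C)
  check_reduction_dt(C, tau, dt)
  if (is.function(b)) {
    if (is.null(T)) stop("supply `T` when `b` is a function")
    nstep <- ceiling(T / dt)
    B <- vapply(seq_len(nstep), function(k) b((k - 1) * dt), numeric(m))
    B <- matrix(B, m, nstep)
  } else {
    B <- as.matrix(b)
    if (nrow(B) != m) stop("`b` matrix must have m rows")
    nstep <- ncol(B)
  }
  sv <- check_stability(C)
  if (!sv$stable) {
    warning("coupling matrix fails the stability screen; ",
            "the reduction will diverge")
  }
  theta <- matrix(NA_real_, nstep + 1, m)
  theta[1, ] <- rep_len(theta0, m)
  th <- theta[1, ]
  z <- numeric(m)
  for (k in seq_len(nstep)) {
    thdot <- alpha * B[, k] + as.vector(C %*% z)
    th <- th + dt * thdot
    z <- z + dt * (thdot - z) / tau
    theta[k + 1, ] <- th
  }
  structure(list(t = (0:nstep) * dt, theta = theta, C = C, alpha = alpha,
                 tau = tau),
            class = "phase_reduction_run")
}

# Batched phase reduction: B is [m, K, nstep]; returns theta [n_rec, m, K]
# sampled every `record_stride` steps. Used by the drift experiments.
phase_reduction_batch <- function(C, alpha, B, tau = 0.01, dt = 1e-3,
                                  record_stride = 10L, theta0 = 0) {
  C <- as.matrix(C)
  m <- nrow(C)
  check_reduction_dt(C, tau, dt)
  K <- dim(B)[2]
  nstep <- dim(B)[3]
  n_rec <- nstep %/% record_stride
  TH <- array(NA_real_, c(n_rec, m, K))
  th <- matrix(rep_len(theta0, m), m, K)
  z <- matrix(0, m, K)
  rec <- 0L
  for (k in seq_len(nstep)) {
    thdot <- alpha * B[, , k] + C %*% z
    th <- th + dt * thdot
    z <- z + (dt / tau) * (thdot - z)
    if (k %% record_stride == 0L) {
      rec <- rec + 1L
      TH[rec, , ] <- th
    }
  }
  list(t = seq_len(n_rec) * record_stride * dt, theta = TH)
}

# The filtered-velocity subsystem has eigenvalues (eig(C) - 1)/tau; with
# strong self coupling the explicit Euler scheme is stiff and needs
# dt < 2 tau / |eig - 1| to remain stable (e.g. ~0.49 ms for the reference
# couplings), on top of the tau/10 accuracy guard.
check_reduction_dt <- function(C, tau, dt) {
  if (dt > tau / 10 + 1e-15) stop("`dt` must be at most tau/10")
  lam <- max(abs(Re(eigen(C, only.values = TRUE)$values - 1)))
  lim <- 1.8 * tau / max(lam, 1)
  if (dt > lim) {
    stop("explicit Euler is unstable for this coupling matrix at dt = ", dt,
         ": the filtered-velocity mode decays at ", signif(lam / tau, 3),
         "/s; use dt <= ", signif(lim, 3), " s")
  }
  invisible(TRUE)
}

#' Predicted grid spacings from the response tensor
#'
#' Under a slow common velocity V, module \eqn{\mu} moves at phase velocity
#' \eqn{(X\vec\gamma)_\mu V}, so its grid spacing (distance per phase cycle)
#' is \eqn{\lambda_\mu = 1 / (X\vec\gamma)_\mu}. Also checks that the
#' joint-motion vector \eqn{\vec u} with \eqn{u_\mu \propto 1/\lambda_\mu}
#' is (close to) an eigenvector of X, which is what makes the spacing ratios
#' robust to the individual input gains.
#'
#' @param gamma Velocity gains, one per module.
#' @param C Coupling matrix.
#' @param alpha Single-module gain.
#' @return List of class `spacing_prediction`: data frame `spacings`
#'   (module, gain, spacing_m), `u` (joint-motion vector, unit norm) and
#'   `u_alignment` (cosine between `u` and `X u`, 1 = exact eigenvector).
#' @export
predicted_spacings <- function(gamma, C, alpha) {
  rt <- response_tensor(C, alpha)
  g <- as.vector(rt$X %*% gamma)
  if (any(g <= 0)) {
    stop("non-positive predicted velocity gain: module ",
         which(g <= 0)[1], " would not follow the velocity input")
  }
  spac <- 1 / g
  u <- (1 / spac) / sqrt(sum((1 / spac)^2))
  Xu <- as.vector(rt$X %*% u)
  align <- sum(Xu * u) / sqrt(sum(Xu^2))
  structure(
    list(spacings = data.frame(module = seq_along(g), gain = g,
                               spacing_m = spac),
         u = u, u_alignment = align, X = rt$X),
    class = "spacing_prediction"
  )
}

#' Predicted effect of disconnecting one module
#'
#' Disconnecting a module removes its couplings to and from the other
#' modules but leaves every module's negative self coupling intact. The
#' disconnected module therefore responds more weakly to velocity inputs
#' (its gain drops to \eqn{\alpha/(1 - C_s)}), which increases its grid
#' spacing; modules formerly coupled to it lose that positive drive and
#' increase their spacing too.
#'
#' @param C Coupling matrix.
#' @param gamma Velocity gains.
#' @param alpha Single-module gain.
#' @param removed Index of the disconnected module.
#' @return List of class `removal_prediction`: `before` and `after` spacing
#'   data frames and `delta` (after - before spacings).
#' @export
module_removal_prediction <- function(C, gamma, alpha, removed) {
  C <- as.matrix(C)
  m <- nrow(C)
  if (removed < 1 || removed > m) stop("`removed` out of range")
  if (!check_stability(C)$stable) stop("`C` fails the stability screen")
  C2 <- C
  C2[removed, -removed] <- 0
  C2[-removed, removed] <- 0
  if (!check_stability(C2)$stable) {
    stop("coupling matrix after removal fails the stability screen")
  }
  before <- predicted_spacings(gamma, C, alpha)$spacings
  after <- predicted_spacings(gamma, C2, alpha)$spacings
  structure(
    list(before = before, after = after,
         delta = after$spacing_m - before$spacing_m, removed = removed),
    class = "removal_prediction"
  )
}
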