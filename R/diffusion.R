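#' Steady state and Jacobian of the coupled drift
#'
#' Linearises the deterministic coupled dynamics
#' \eqn{\dot s = -s/\tau + \phi(W s + I_0 \pm a \sum_\rho C_{\mu\rho}
#' \omega_\rho(s))} around the joint steady state (all bumps at their
#' relaxed positions, readouts zero). The velocity readout is a linear
#' functional of s, so its contribution enters the Jacobian as a
#' sign-patterned rank-limited term per module pair. The Jacobian has m
#' near-zero eigenvalues, one per module, spanning the attractor manifold of
#' joint phase translations. One-dimensional modules only.
#'
#' @param system A [coupled_system()] with `dims == 1`.
#' @return List of class `coupled_linearization`: `sbar` (stacked steady
#'   state), `rates` (steady rates, Hz), `J` (the
#'   \eqn{2Nm \times 2Nm} Jacobian), `active` (logical), `tangent_residual`
#'   (relative norm of J applied to the numerical phase tangents).
#' @export
coupled_steady_state_and_jacobian <- function(system) {
  spec <- system$net$spec
  if (spec$dims != 1) {
    stop("the diffusion analysis is implemented for 1D modules ",
         "(the 2D channels decouple into two copies of the 1D problem)")
  }
  net <- system$net
  m <- system$m
  N <- spec$N
  n <- spec$n_neurons # 2N
  tau <- spec$tau
  sbar <- unlist(lapply(system$states, function(st) st$s))
  Wfull <- net$W

  # signs of the velocity term per neuron (R: +, L: -)
  sgn <- rep(c(1, -1), each = N)
  omega <- vapply(system$states, function(st)
    velocity_readout(st, net, system$beta)[1], numeric(1))
  v <- system$a * as.vector(system$C %*% omega)

  ntot <- n * m
  J <- matrix(0, ntot, ntot)
  act_all <- logical(ntot)
  rates <- numeric(ntot)
  for (mu in seq_len(m)) {
    rows <- (mu - 1) * n + seq_len(n)
    u <- as.vector(Wfull %*% sbar[rows]) + spec$I0 + sgn * v[mu]
    act <- u > 0
    act_all[rows] <- act
    rates[rows] <- pmax(u, 0) / tau
    for (rho in seq_len(m)) {
      cols <- (rho - 1) * n + seq_len(n)
      blk <- (system$a * system$C[mu, rho] * system$beta / tau) *
        outer(sgn, sgn)
      if (rho == mu) blk <- blk + Wfull
      blk <- blk * (act / tau) # row scaling by phi'
      J[rows, cols] <- blk
    }
  }
  diag(J) <- diag(J) - 1 / tau

  Tm <- phase_tangents(system)
  num <- sqrt(colSums((J %*% Tm)^2))
  den <- sqrt(colSums(Tm^2)) / tau
  structure(
    list(sbar = sbar, rates = rates, J = J, active = act_all,
         tangent_residual = max(num / den), m = m, N = N, tau = tau),
    class = "coupled_linearization"
  )
}

#' Numerical tangent vectors of the attractor manifold
#'
#' Central finite differences of the steady state translated by one lattice
#' site in each module (exact permutations of the network), scaled to a unit
#' phase step: \eqn{T_\mu = [\bar s(+1\ \mathrm{site}) - \bar s(-1\
#' \mathrm{site})] / (2/N)}. Tangent \eqn{\mu} has support only on module
#' \eqn{\mu}'s neurons.
#'
#' @param system A [coupled_system()] with 1D modules.
#' @return Matrix `[2Nm, m]`, one tangent per column.
#' @export
phase_tangents <- function(system) {
  spec <- system$net$spec
  if (spec$dims != 1) stop("tangents implemented for 1D modules")
  m <- system$m
  n <- spec$n_neurons
  N <- spec$N
  Tm <- matrix(0, n * m, m)
  for (mu in seq_len(m)) {
    s <- system$states[[mu]]$s
    sp <- translate_state(system$net, s, 1 / N)
    sm <- translate_state(system$net, s, -1 / N)
    Tm[(mu - 1) * n + seq_len(n), mu] <- (sp - sm) / (2 / N)
  }
  Tm
}

#' Left null eigenvectors of the linearized dynamics
#'
#' Finds the m left eigenvectors of the Jacobian with near-zero eigenvalue
#' and bi-orthonormalises them against the attractor tangents so that
#' \eqn{\nu_\mu \cdot T_\rho = \delta_{\mu\rho}}: \eqn{\nu_\mu} then reads
#' out, to linear order, the phase shift of module \eqn{\mu} caused by a
#' state perturbation.
#'
#' Small problems use a full eigendecomposition with the spectral-gap check;
#' large ones use shifted inverse subspace iteration started from the
#' tangents (one LAPACK QR factorisation, a few solves), verifying the
#' Rayleigh quotients against the same tolerance.
#'
#' @param lin A `coupled_linearization` (or a bare Jacobian matrix, in which
#'   case `tangents` and `tau` are required).
#' @param tangents Tangent matrix from [phase_tangents()].
#' @param tau Synaptic time constant (sets the eigenvalue scale).
#' @param tol Near-zero threshold on |eigenvalue|, default `1e-3/tau`.
#' @param gap_factor Required ratio between the first non-null mode and
#'   `tol` (eigen method).
#' @param method `"auto"` (eigen below 1500 neurons total), `"eigen"`, or
#'   `"inverse"`.
#' @return List of class `null_modes`: `nu` (m x n matrix, rows are the
#'   bi-orthonormalised null covectors), `values` (the m null eigenvalues),
#'   `cond` (condition number of the bi-orthonormalisation).
#' @export
null_left_eigenvectors <- function(lin, tangents = NULL, tau = NULL,
                                   tol = NULL, gap_factor = 10,
                                   method = c("auto", "eigen", "inverse")) {
  method <- match.arg(method)
  if (inherits(lin, "coupled_linearization")) {
    J <- lin$J
    tau <- lin$tau
  } else {
    J <- lin
    if (is.null(tau)) stop("supply `tau` with a bare Jacobian")
  }
  if (is.null(tangents)) stop("supply the attractor `tangents`")
  ntot <- nrow(J)
  m <- ncol(tangents)
  if (is.null(tol)) tol <- 1e-3 / tau
  if (method == "auto") method <- if (ntot <= 1500) "eigen" else "inverse"
  B <- t(J)

  if (method == "eigen") {
    ev <- eigen(B)
    mag <- Mod(ev$values)
    ord <- order(mag)
    vals <- ev$values[ord[seq_len(m)]]
    if (any(Mod(vals) >= tol)) {
      stop("attractor manifold not found: fewer than m = ", m,
           " eigenvalues below |eig| < ", signif(tol, 3))
    }
    gap <- mag[ord[m + 1]]
    if (gap < gap_factor * tol) {
      stop("spectral gap too small: next mode at |eig| = ", signif(gap, 3),
           " is within ", gap_factor, "x the null tolerance")
    }
    V <- ev$vectors[, ord[seq_len(m)], drop = FALSE]
    if (max(abs(Im(V))) > 1e-8 * max(abs(Re(V)))) {
      stop("null eigenvectors are not real; unexpected complex manifold")
    }
    V <- Re(V)
    vals <- Re(vals)
  } else {
    shift <- 1e-6 / tau
    A <- B
    diag(A) <- diag(A) - shift
    qa <- qr(A, LAPACK = TRUE)
    V <- qr.Q(qr(tangents)) # deterministic start with guaranteed overlap
    for (it in 1:3) {
      V <- qr.coef(qa, V)
      V <- qr.Q(qr(V))
    }
    H <- crossprod(V, B %*% V)
    eh <- eigen(H)
    if (max(abs(Im(eh$values))) > tol) {
      stop("attractor manifold not found: inverse iteration converged to ",
           "complex modes")
    }
    V <- V %*% Re(eh$vectors)
    vals <- Re(eh$values)
    if (any(abs(vals) >= tol)) {
      stop("attractor manifold not found: fewer than m = ", m,
           " eigenvalues below |eig| < ", signif(tol, 3))
    }
  }

  G <- crossprod(V, tangents) # m x m
  cn <- kappa(G, exact = TRUE)
  if (!is.finite(cn) || cn > 1e8) {
    stop("bi-orthonormalisation ill-conditioned (condition number ",
         signif(cn, 3), ")")
  }
  nu <- solve(G, t(V)) # rows: nu_mu, with nu %*% tangents = I
  structure(list(nu = nu, values = vals, cond = cn, method = method),
            class = "null_modes")
}

#' Phase diffusion tensor from null modes and steady rates
#'
#' Under Poisson spiking, each spike of neuron i kicks the synaptic state by
#' one unit along coordinate i; projected on the attractor the phases
#' diffuse with tensor
#' \eqn{D_{\mu\rho} = \frac{1}{2}\sum_i \nu_{\mu,i}\,\nu_{\rho,i}\,\bar r_i}
#' (phase^2 per second). Its eigenstructure quantifies how strongly
#' coupling suppresses relative (incompatible) drift versus coordinated
#' drift.
#'
#' @param nu `null_modes` object (or bare m x n matrix of covectors).
#' @param rates Steady-state firing rates, Hz (length n, nonnegative).
#' @return List of class `diffusion_tensor`: `D`, `eigenvalues` (decreasing),
#'   `eigenvectors`.
#' @export
diffusion_tensor <- function(nu, rates) {
  V <- if (inherits(nu, "null_modes")) nu$nu else as.matrix(nu)
  if (any(rates < 0)) stop("`rates` must be nonnegative")
  if (ncol(V) != length(rates)) stop("`nu` and `rates` sizes differ")
  D <- 0.5 * V %*% (rates * t(V))
  asym <- max(abs(D - t(D))) / max(abs(D))
  if (is.finite(asym) && asym > 1e-10) {
    stop("computed diffusion tensor is asymmetric beyond tolerance ",
         "(relative asymmetry ", signif(asym, 3), ")")
  }
  D <- (D + t(D)) / 2
  ed <- eigen(D, symmetric = TRUE)
  structure(list(D = D, eigenvalues = ed$values, eigenvectors = ed$vectors),
            class = "diffusion_tensor")
}

#' @export
print.diffusion_tensor <- function(x, ...) {
  cat("<diffusion_tensor> (phase^2/s)\n")
  print(signif(x$D, 4))
  cat("  eigenvalues:", paste(signif(x$eigenvalues, 4), collapse = ", "),
      "\n")
  if (length(x$eigenvalues) == 2 && x$eigenvalues[2] > 0) {
    cat("  anisotropy D+/D-:",
        signif(x$eigenvalues[1] / x$eigenvalues[2], 4), "\n")
  }
  invisible(x)
}

#' Full diffusion-tensor pipeline for a coupled system
#'
#' Convenience wrapper: linearise ([coupled_steady_state_and_jacobian()]),
#' build tangents, extract bi-orthonormalised null modes, and evaluate the
#' diffusion tensor at the steady state.
#'
#' @param system A [coupled_system()] with 1D modules.
#' @param ... Passed to [null_left_eigenvectors()].
#' @return A `diffusion_tensor` with the linearisation attached as
#'   `attr(, "linearization")` and null modes as `attr(, "modes")`.
#' @export
phase_diffusion <- function(system, ...) {
  lin <- coupled_steady_state_and_jacobian(system)
  Tm <- phase_tangents(system)
  nm <- null_left_eigenvectors(lin$J, tangents = Tm, tau = lin$tau, ...)
  out <- diffusion_tensor(nm, lin$rates)
  attr(out, "linearization") <- lin
  attr(out, "modes") <- nm
  out
}

#' Monte-Carlo estimate of the phase diffusion tensor
#'
#' Runs independent Poisson-spiking simulations of the system at zero
#' external input and estimates D from the growth of the phase covariance:
#' \eqn{\mathrm{cov}(\theta_\mu, \theta_\rho)(t) \approx 2 D_{\mu\rho} t}.
#' Covariance slopes are fitted by least squares through the origin;
#' bootstrap resampling of trials yields confidence intervals.
#'
#' @param system A [coupled_system()] (1D).
#' @param T Duration per trial, seconds.
#' @param trials Number of independent trials (batched in one run).
#' @param dt Integration step.
#' @param record_dt Sampling interval for the phase trajectories.
#' @param seed Seed for the spiking noise.
#' @param boot Bootstrap replicates for the CIs.
#' @param min_r2 Linearity guard on the fitted covariance growth; below it a
#'   warning is issued and the CI is widened (x2).
#' @return List of class `empirical_diffusion`: `D_hat`, `ci_lo`, `ci_hi`
#'   (matrices), `r2`, and the per-time covariance curves.
#' @export
empirical_diffusion <- function(system, T = 5, trials = 50, dt = 1e-4,
                                record_dt = 0.02, seed = NULL, boot = 200,
                                min_r2 = 0.9) {
  spec <- system$net$spec
  if (spec$dims != 1) stop("implemented for 1D systems")
  m <- system$m
  if (trials < 2) stop("need at least 2 trials")
  if (!is.null(seed)) set.seed(seed)
  nstep <- ceiling(T / dt)
  stride <- max(1L, round(record_dt / dt))
  S0 <- do.call(cbind, lapply(system$states, function(st) st$s))
  S0 <- S0[, rep(seq_len(m), times = trials), drop = FALSE]
  res <- integrate_modules(system$net, m = m, K = trials, C = system$C,
                           a = system$a, beta = system$beta, S0 = S0,
                           dt = dt, nstep = nstep, mode = "poisson",
                           record_stride = stride,
                           v_scale = system$v_scale)
  TH <- split_columns(res$phase_a, m, trials) # [n_rec, m, K]
  n_rec <- length(res$t)
  for (mu in seq_len(m)) {
    TH[, mu, ] <- apply(TH[, mu, , drop = FALSE][, 1, ], 2, unwrap_phase)
  }
  # displacement from the first record
  DISP <- sweep(TH, c(2, 3), TH[1, , ], "-")
  tt <- res$t - res$t[1]

  slope_fit <- function(idx) {
    Dh <- matrix(0, m, m)
    r2 <- matrix(NA_real_, m, m)
    for (mu in seq_len(m)) {
      for (rho in mu:m) {
        cv <- vapply(seq_len(n_rec), function(i) {
          x <- DISP[i, mu, idx]; y <- DISP[i, rho, idx]
          mean(x * y) - mean(x) * mean(y)
        }, numeric(1))
        sl <- sum(cv * tt) / sum(tt^2) # through-origin LS
        Dh[mu, rho] <- Dh[rho, mu] <- sl / 2
        ss_res <- sum((cv - sl * tt)^2)
        ss_tot <- sum((cv - mean(cv))^2)
        r2[mu, rho] <- r2[rho, mu] <-
          if (ss_tot > 0) 1 - ss_res / ss_tot else NA_real_
      }
    }
    list(D = Dh, r2 = r2)
  }

  fit <- slope_fit(seq_len(trials))
  bs <- array(NA_real_, c(boot, m, m))
  for (bi in seq_len(boot)) {
    bs[bi, , ] <- slope_fit(sample.int(trials, replace = TRUE))$D
  }
  ci_lo <- apply(bs, c(2, 3), stats::quantile, probs = 0.025)
  ci_hi <- apply(bs, c(2, 3), stats::quantile, probs = 0.975)
  widened <- FALSE
  if (any(fit$r2 < min_r2, na.rm = TRUE)) {
    warning("covariance growth deviates from linearity (R^2 < ", min_r2,
            "); widening the confidence interval")
    mid <- (ci_lo + ci_hi) / 2
    ci_lo <- mid - 2 * (mid - ci_lo)
    ci_hi <- mid + 2 * (ci_hi - mid)
    widened <- TRUE
  }
  structure(list(D_hat = fit$D, ci_lo = ci_lo, ci_hi = ci_hi, r2 = fit$r2,
                 widened = widened, t = tt, trials = trials),
            class = "empirical_diffusion")
}
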