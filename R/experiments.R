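# Scripted experiments: end-to-end reproductions of the model's headline
# computations at "desk" (reduced) or "full" scale. Every stochastic element
# is derived from the `seed` argument; trials are batched as matrix columns
# of one seeded run.

#' Velocity tracking by two coupled 1D modules
#'
#' Drives module 1 with the velocity of a smooth 1D trajectory (module 2
#' receives no external input) and compares the uncoupled control, where
#' module 2 stays put, with the coupled system, where both modules track
#' with phase-velocity ratio close to the spacing ratio.
#'
#' @param scale "desk" (N = 200) or "full" (N = 1000).
#' @param T Trajectory duration, seconds.
#' @param seed Seed for the trajectory.
#' @param dt Integration step.
#' @return List: runs `coupled` and `uncoupled` (phase trajectories), the
#'   fitted velocity `ratio` (theta2-dot / theta1-dot, coupled), its
#'   linear-response prediction `ratio_pred`, and `uncoupled_leak` (module 2
#'   displacement as a fraction of module 1's, uncoupled).
#' @export
experiment_tracking <- function(scale = c("desk", "full"), T = 10, seed = 1,
                                dt = 5e-4) {
  scale <- match.arg(scale)
  N <- if (scale == "desk") 200L else 1000L
  spec <- module_spec(dims = 1, N = N, gamma = 0.06)
  traj <- generate_trajectory(T, dt, dims = 1, arena = 3, speed_mean = 0.2,
                              seed = seed)
  drive <- make_velocity_drive(traj, gamma = c(0.06, 0), eta = 0)
  net <- build_network(spec)
  base <- relax_to_bump(net, phase = 0.5, dt = dt)
  C <- standard_coupling(2)
  sys_c <- coupled_system(spec, 2, C = C, net = net, base_state = base)
  sys_u <- coupled_system(spec, 2, C = matrix(0, 2, 2), net = net,
                          base_state = base)
  run_c <- run_coupled(sys_c, b = drive, dt = dt)
  run_u <- run_coupled(sys_u, b = drive, dt = dt)

  th1 <- run_c$theta[, 1, 1]; th2 <- run_c$theta[, 2, 1]
  ratio <- unname(stats::coef(stats::lm(th2 ~ th1))[2])
  X <- response_tensor(C)$X
  d1 <- run_u$theta[, 1, 1] - run_u$theta[1, 1, 1]
  d2 <- run_u$theta[, 2, 1] - run_u$theta[1, 2, 1]
  leak <- max(abs(d2)) / max(abs(d1))
  list(coupled = run_c, uncoupled = run_u, ratio = ratio,
       ratio_pred = X[2, 1] / X[1, 1], lambda = spacing_ratio(),
       uncoupled_leak = leak, trajectory = traj)
}

#' Drift coordination of three modules under noisy velocity input
#'
#' Simulates the phase-reduction dynamics of three coupled modules (and the
#' uncoupled control) driven by a common 2D trajectory with independent
#' white velocity-input noise per module and direction, over many trials.
#' Reports the pairwise mean-square displacement between the scaled module
#' trajectories and each module's position MSE against the true path, with
#' the uncoupled/coupled MSE slope ratio: coupling averages the m
#' independent noise streams, so the slope drops by a factor close to m.
#'
#' @param trials Noise realisations.
#' @param T Horizon, seconds.
#' @param seed Base seed (trajectory uses `seed`, noise `seed + 1`).
#' @param eta Velocity-noise intensity, m s^-1/2.
#' @param alpha Single-module gain; calibrated on a desk-scale ring network
#'   when NULL.
#' @param dt Reduction time step.
#' @param record_dt Sampling of the recorded phases.
#' @return List: `slope_ratio` (uncoupled/coupled mean MSE slope),
#'   per-variant `metrics` (`drift_metrics` per direction), `spacings`,
#'   `alpha`.
#' @export
experiment_drift <- function(trials = 100, T = 20, seed = 1, eta = 0.02,
                             alpha = NULL, dt = 2e-4, record_dt = 0.1) {
  lam <- spacing_ratio()
  gamma <- 0.06 * lam^(0:2)
  C <- standard_coupling(3)
  if (is.null(alpha)) {
    alpha <- calibrate_gain(module_spec(dims = 1, N = 200))$alpha
  }
  spac_c <- predicted_spacings(gamma, C, alpha)$spacings$spacing_m
  spac_u <- 1 / (alpha * gamma)

  traj <- generate_trajectory(T, dt, dims = 2, seed = seed)
  nstep <- nrow(traj$path) - 1L
  stride <- max(1L, round(record_dt / dt))

  # both variants see the same noise realisations (paired design: the
  # slope ratio is then insensitive to the particular draws)
  run_variant <- function(Cv, spac) {
    set.seed(seed + 1)
    out <- vector("list", 2)
    for (q in 1:2) {
      V <- if (q == 1) traj$path$vx else traj$path$vy
      V <- V[seq_len(nstep)]
      B <- array(0, c(3, trials, nstep))
      for (mu in 1:3) {
        noise <- matrix(stats::rnorm(trials * nstep, 0, eta / sqrt(dt)),
                        trials, nstep)
        B[mu, , ] <- gamma[mu] * sweep(noise, 2, V, "+")
      }
      pr <- phase_reduction_batch(Cv, alpha, B, dt = dt,
                                  record_stride = stride)
      truth <- cumsum(V * dt)[seq_len(nstep) %% stride == 0]
      out[[q]] <- phase_msd_mse(pr$theta, spac, pr$t, truth = truth)
    }
    out
  }
  met_c <- run_variant(C, spac_c)
  met_u <- run_variant(matrix(0, 3, 3), spac_u)
  slope_c <- rowSums(cbind(met_c[[1]]$slopes, met_c[[2]]$slopes))
  slope_u <- rowSums(cbind(met_u[[1]]$slopes, met_u[[2]]$slopes))
  list(slope_ratio = mean(slope_u) / mean(slope_c),
       slopes_coupled = slope_c, slopes_uncoupled = slope_u,
       metrics_coupled = met_c, metrics_uncoupled = met_u,
       spacings_coupled = spac_c, spacings_uncoupled = spac_u,
       alpha = alpha, trials = trials)
}

#' Position decoding from spikes: catastrophic-error statistics
#'
#' The full readout pipeline on a three-module 2D system: simulate the
#' network along a synthetic foraging trajectory, generate Poisson spikes
#' (from the instantaneous rates in the input-noise condition, or as the
#' network's own stochastic dynamics in the intrinsic condition), decode
#' position with the exponential-kernel maximum-likelihood decoder, flag
#' readout discontinuities, and accumulate success and MSE curves over
#' trials.
#'
#' @param variant "coupled", "uncoupled", or both.
#' @param noise "input" (rate dynamics, noisy velocity drive, spikes only
#'   in the readout) or "intrinsic" (Poisson network dynamics, noiseless
#'   drive).
#' @param trials Trials (batched).
#' @param T Horizon, seconds.
#' @param seed Base seed (trajectory `seed`, noise/spikes `seed + 1`,
#'   uncoupled twin `seed + 2`).
#' @param eta Velocity-noise intensity (input-noise condition).
#' @param N Neurons per sub-population (perfect square).
#' @param dt Integration step (desk default 0.5 ms).
#' @param grid_n Decoding grid points per dimension.
#' @param record_dt Decoding stride, seconds.
#' @param tau_d Decoder kernel time constant.
#' @param arena Arena side lengths, meters.
#' @param margin Decoding-grid margin beyond the arena, meters; covers
#'   positions the drifting path integrator can represent just outside the
#'   walls.
#' @return List of class `decoding_experiment`: per-variant `metrics`
#'   ([success_and_error_curves()] output), decoded `paths`, `spacings`,
#'   the shared `trajectory`, and settings.
#' @export
experiment_decoding <- function(variant = c("coupled", "uncoupled"),
                                noise = c("input", "intrinsic"),
                                trials = 10, T = 12, seed = 1,
                                eta = 0.02, N = 24L^2, dt = 5e-4,
                                grid_n = 64L, record_dt = 0.01,
                                tau_d = 0.01, arena = c(1.5, 1.5),
                                margin = 0.15) {
  noise <- match.arg(noise)
  variant <- match.arg(variant, several.ok = TRUE)
  lam <- spacing_ratio()
  gamma <- 0.06 * lam^(0:2)
  m <- 3L
  spec <- module_spec(dims = 2, N = N)
  net <- build_network(spec)
  base <- relax_to_bump(net, phase = c(0.5, 0.5), dt = spec$tau / 20)
  traj <- generate_trajectory(T, dt, dims = 2, arena = arena, seed = seed)
  nstep <- nrow(traj$path) - 1L
  stride <- max(1L, round(record_dt / dt))
  n_rec <- nstep %/% stride
  rec_rows <- 1L + seq_len(n_rec) * stride
  truth <- cbind(traj$path$x[rec_rows], traj$path$y[rec_rows])
  if (noise == "intrinsic") eta <- 0

  out <- list()
  for (vi in seq_along(variant)) {
    vn <- variant[vi]
    C <- if (vn == "coupled") standard_coupling(m) else matrix(0, m, m)
    sys <- coupled_system(spec, m, C = C, net = net, base_state = base)
    cal <- calibrate_spacings(sys, gamma, V = 0.2, T = 0.8)
    spac <- cal$spacing_m
    gains <- cbind(cal$gain_x, cal$gain_y)
    rf <- measure_receptive_fields(sys, spac, arena, grid_n = grid_n,
                                   gains = gains, margin = margin)

    # initial bumps represent the start position
    x0 <- c(traj$path$x[1], traj$path$y[1])
    p0 <- attr(base, "phase")
    S0 <- matrix(NA_real_, spec$n_neurons, m * trials)
    for (mu in seq_len(m)) {
      ph <- position_to_phase(x0, spac[mu], dims = 2, gain = gains[mu, ])
      st <- translate_state(net, base$s, as.vector(ph) - p0)
      S0[, (seq_len(trials) - 1) * m + mu] <- st
    }

    set.seed(seed + if (vn == "coupled") 1L else 2L)
    Bx <- array(0, c(m, trials, nstep))
    By <- array(0, c(m, trials, nstep))
    for (mu in seq_len(m)) {
      nx <- if (eta > 0)
        matrix(stats::rnorm(trials * nstep, 0, eta / sqrt(dt)), trials, nstep)
      else 0
      ny <- if (eta > 0)
        matrix(stats::rnorm(trials * nstep, 0, eta / sqrt(dt)), trials, nstep)
      else 0
      Bx[mu, , ] <- gamma[mu] * (nx + matrix(traj$path$vx[seq_len(nstep)],
                                             trials, nstep, byrow = TRUE))
      By[mu, , ] <- gamma[mu] * (ny + matrix(traj$path$vy[seq_len(nstep)],
                                             trials, nstep, byrow = TRUE))
    }

    # chunked online decoding
    ntot <- m * spec$n_neurons
    chunk <- 100L
    buf <- matrix(0, ntot, trials * chunk)
    buf_valid <- logical(trials * chunk)
    buf_recs <- integer(chunk)
    buf_n <- 0L
    XH <- array(NA_real_, c(n_rec, trials, 2))
    VAL <- matrix(FALSE, n_rec, trials)
    flush <- function() {
      if (buf_n == 0L) return(invisible())
      cols <- seq_len(buf_n * trials)
      ll <- rf$lnr %*% buf[, cols, drop = FALSE]
      idx <- max.col(t(ll), ties.method = "first")
      for (j in seq_len(buf_n)) {
        jc <- (j - 1) * trials + seq_len(trials)
        XH[buf_recs[j], , 1] <<- rf$grid[idx[jc], 1]
        XH[buf_recs[j], , 2] <<- rf$grid[idx[jc], 2]
        VAL[buf_recs[j], ] <<- buf_valid[jc]
      }
      buf_n <<- 0L
      invisible()
    }
    hook <- function(rec_i, NC) {
      buf_n <<- buf_n + 1L
      cols <- (buf_n - 1) * trials + seq_len(trials)
      stacked <- matrix(NC, ntot, trials)
      buf[, cols] <<- stacked
      buf_valid[cols] <<- colSums(stacked) > 0
      buf_recs[buf_n] <<- rec_i
      if (buf_n == chunk) flush()
      invisible()
    }

    integrate_modules(
      net, m = m, K = trials, C = sys$C, a = sys$a, beta = sys$beta,
      v_scale = sys$v_scale,
      S0 = S0, Bx = Bx, By = By, dt = dt, nstep = nstep,
      mode = if (noise == "intrinsic") "poisson" else "rate",
      record_stride = stride,
      readout = if (noise == "intrinsic") "none" else "poisson",
      tau_d = tau_d, count_hook = hook
    )
    flush()

    paths <- lapply(seq_len(trials), function(k) {
      d <- data.frame(t = seq_len(n_rec) * record_dt,
                      x = XH[, k, 1], y = XH[, k, 2],
                      loglik = NA_real_, valid = VAL[, k])
      structure(list(path = d, dims = 2L, grid_n = grid_n, spacings = spac),
                class = "decoded_path")
    })
    metrics <- success_and_error_curves(paths, truth, arena,
                                        threshold = min(spac) / 2)
    out[[vn]] <- list(metrics = metrics, paths = paths, spacings = spac,
                      final_success = metrics$curves$success[n_rec])
  }
  structure(
    c(out, list(trajectory = traj, truth = truth, noise = noise,
                settings = list(trials = trials, T = T, seed = seed,
                                eta = eta, N = N, dt = dt, grid_n = grid_n,
                                record_dt = record_dt, tau_d = tau_d,
                                arena = arena, margin = margin))),
    class = "decoding_experiment"
  )
}

#' Diffusion anisotropy of two coupled 1D modules
#'
#' Computes the phase diffusion tensor of the Poisson-spiking two-module
#' system from the linearized dynamics, coupled and uncoupled, and reports
#' the coupled anisotropy ratio D+/D- and the uncoupled isotropy.
#'
#' @param N Neurons per sub-population (1000 reproduces the reference
#'   configuration; 200 is a fast desk scale).
#' @param relax_dt Relaxation step.
#' @param tol Near-zero eigenvalue tolerance passed to
#'   [null_left_eigenvectors()]; the default accommodates the
#'   lattice-commensuration fluctuation of the translation mode while
#'   keeping a large gap to the first relaxation mode.
#' @return List: `coupled` and `uncoupled` `diffusion_tensor`s, `ratio`
#'   (coupled D+/D-), `uncoupled_offdiag` (relative off-diagonal magnitude),
#'   `uncoupled_imbalance` (relative D11 vs D22 difference).
#' @export
experiment_diffusion <- function(N = 1000L, relax_dt = 1e-4,
                                 tol = NULL) {
  spec <- module_spec(dims = 1, N = N)
  if (is.null(tol)) tol <- if (N >= 700) 1e-2 / spec$tau else 5e-2 / spec$tau
  net <- build_network(spec)
  base <- relax_to_bump(net, phase = 0.5, dt = relax_dt)
  sys_c <- coupled_system(spec, 2, C = standard_coupling(2), net = net,
                          base_state = base)
  sys_u <- coupled_system(spec, 2, C = matrix(0, 2, 2), net = net,
                          base_state = base)
  D_c <- phase_diffusion(sys_c, tol = tol)
  D_u <- phase_diffusion(sys_u, tol = tol)
  list(coupled = D_c, uncoupled = D_u,
       ratio = D_c$eigenvalues[1] / D_c$eigenvalues[2],
       uncoupled_offdiag = abs(D_u$D[1, 2]) / max(diag(D_u$D)),
       uncoupled_imbalance = abs(D_u$D[1, 1] - D_u$D[2, 2]) /
         max(diag(D_u$D)))
}

#' Run a named experiment from a config list
#'
#' Thin config-driven dispatcher over the `experiment_*` functions. The
#' config must contain `scenario` (one of "tracking", "drift", "decoding",
#' "diffusion"); remaining entries are passed as arguments. When `out_dir`
#' is given, curve outputs are written as tidy CSV alongside a JSON (or R
#' dput) manifest capturing the scenario, arguments, seed and package
#' version, sufficient to re-run the experiment.
#'
#' @param config Named list, or path to a JSON config file (requires
#'   jsonlite).
#' @param out_dir Optional output directory.
#' @return The experiment's result object (invisibly when writing files).
#' @export
run_experiment <- function(config, out_dir = NULL) {
  if (is.character(config)) {
    if (!requireNamespace("jsonlite", quietly = TRUE)) {
      stop("reading JSON configs requires the jsonlite package")
    }
    config <- jsonlite::read_json(config, simplifyVector = TRUE)
  }
  scenario <- config$scenario
  if (is.null(scenario)) stop("config must name a `scenario`")
  args <- config[setdiff(names(config), "scenario")]
  fn <- switch(scenario,
               tracking = experiment_tracking,
               drift = experiment_drift,
               decoding = experiment_decoding,
               diffusion = experiment_diffusion,
               stop("unknown scenario: ", scenario))
  res <- do.call(fn, args)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    manifest <- list(scenario = scenario, args = args,
                     package_version = as.character(
                       utils::packageVersion("gridlock")),
                     r_version = R.version.string,
                     timestamp = format(Sys.time(), tz = "UTC"))
    if (requireNamespace("jsonlite", quietly = TRUE)) {
      jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                           auto_unbox = TRUE, pretty = TRUE)
    } else {
      dput(manifest, file.path(out_dir, "manifest.R"))
    }
    write_experiment_csv(res, scenario, out_dir)
    return(invisible(res))
  }
  res
}

write_experiment_csv <- function(res, scenario, out_dir) {
  wcsv <- function(d, name)
    utils::write.csv(d, file.path(out_dir, name), row.names = FALSE)
  if (scenario == "tracking") {
    d <- data.frame(t = res$coupled$t,
                    theta1_coupled = res$coupled$theta[, 1, 1],
                    theta2_coupled = res$coupled$theta[, 2, 1],
                    theta1_uncoupled = res$uncoupled$theta[, 1, 1],
                    theta2_uncoupled = res$uncoupled$theta[, 2, 1])
    wcsv(d, "tracking.csv")
    wcsv(data.frame(ratio = res$ratio, ratio_pred = res$ratio_pred,
                    uncoupled_leak = res$uncoupled_leak), "tracking_summary.csv")
  } else if (scenario == "drift") {
    wcsv(res$metrics_coupled[[1]]$msd, "msd_coupled_x.csv")
    wcsv(res$metrics_uncoupled[[1]]$msd, "msd_uncoupled_x.csv")
    wcsv(data.frame(module = 1:3, slope_coupled = res$slopes_coupled,
                    slope_uncoupled = res$slopes_uncoupled),
         "mse_slopes.csv")
    wcsv(data.frame(slope_ratio = res$slope_ratio), "drift_summary.csv")
  } else if (scenario == "decoding") {
    for (vn in intersect(c("coupled", "uncoupled"), names(res))) {
      wcsv(res[[vn]]$metrics$curves, paste0("curves_", vn, ".csv"))
    }
  } else if (scenario == "diffusion") {
    wcsv(data.frame(variant = c("coupled", "uncoupled"),
                    D11 = c(res$coupled$D[1, 1], res$uncoupled$D[1, 1]),
                    D12 = c(res$coupled$D[1, 2], res$uncoupled$D[1, 2]),
                    D22 = c(res$coupled$D[2, 2], res$uncoupled$D[2, 2])),
         "diffusion_tensors.csv")
    wcsv(data.frame(ratio = res$ratio,
                    uncoupled_offdiag = res$uncoupled_offdiag),
         "diffusion_summary.csv")
  }
  invisible()
}
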