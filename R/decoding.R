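# --- phase <-> position maps -------------------------------------------

#' Module phase representing a position
#'
#' A module of spacing \eqn{\lambda} represents position modulo its
#' spacing: in 1D \eqn{\theta = (x \bmod \lambda)/\lambda}; in 2D the
#' Cartesian phase vector is \eqn{(x, y)/\lambda} and the returned value is
#' its pair of lattice coordinates (each periodic in \[0,1)) in the
#' [hex_basis()] frame.
#'
#' @param x Position: numeric vector (1D) or matrix with 2 columns /
#'   length-2 vector (2D).
#' @param lambda Grid spacing, meters. Ignored when `gain` is given.
#' @param dims 1 or 2.
#' @param gain Optional measured phase-velocity gain (phase per meter):
#'   scalar in 1D, per-axis pair in 2D. Defaults to `1/lambda` per axis;
#'   supplying the measured per-axis gains makes the map invert a slightly
#'   anisotropic network response exactly.
#' @return Phases: vector (1D) or matrix with columns `a`, `b` (2D).
#' @export
position_to_phase <- function(x, lambda, dims = 1, gain = NULL) {
  if (dims == 1) {
    g <- if (is.null(gain)) 1 / lambda else gain
    (x * g) %% 1
  } else {
    g <- if (is.null(gain)) rep(1 / lambda, 2) else rep_len(gain, 2)
    x <- matrix(x, ncol = 2)
    Minv <- solve(hex_basis())
    cart <- cbind(x[, 1] * g[1], x[, 2] * g[2])
    ab <- cart %*% t(Minv)
    ab <- ab %% 1
    colnames(ab) <- c("a", "b")
    ab
  }
}

# --- receptive fields ---------------------------------------------------

#' Measure receptive-field templates of all neurons
#'
#' For every position on a grid covering the arena, each module's bump is
#' placed at the phase representing that position (by periodic translation
#' of the relaxed steady state) and the steady firing rates are read off.
#' The stored log-rates (floored at a small fraction of each neuron's peak
#' rate, to keep the log-likelihood finite) are the templates of the
#' maximum-likelihood decoder.
#'
#' @param system A [coupled_system()].
#' @param spacings Grid spacing of each module, meters (e.g. from
#'   [calibrate_spacings()]).
#' @param arena Arena extent: c(Lx) or c(Lx, Ly), meters (grid spans
#'   \[0, L\] per dimension).
#' @param grid_n Grid points per dimension. If `NULL`, uses
#'   `lambda_min / 50` capped at 200 per dimension.
#' @param gains Optional measured phase-velocity gains (phase per meter),
#'   an m x dims matrix (see [calibrate_spacings()]); defaults to
#'   `1/spacings` on every axis.
#' @param margin Extra grid margin beyond the arena on every side, meters.
#'   Under pure path integration with noise the represented position can
#'   drift slightly past the walls; hypotheses just outside the arena must
#'   be available to the decoder or a remote alias inside it wins.
#' @param rate_floor_frac Floor on template rates, as a fraction of each
#'   neuron's maximum rate (silent neurons fall back to the population
#'   maximum).
#' @return Object of class `receptive_field_map`: `grid` (n_g x dims matrix
#'   of positions), `lnr` (n_g x (m * n_neurons) matrix of log template
#'   rates, modules stacked), `spacings`, `arena`, `grid_n`.
#' @export
measure_receptive_fields <- function(system, spacings, arena,
                                     grid_n = NULL, gains = NULL,
                                     margin = 0,
                                     rate_floor_frac = 1e-4) {
  spec <- system$net$spec
  dims <- spec$dims
  m <- system$m
  if (length(spacings) != m) stop("`spacings` must have length m")
  if (length(arena) != dims) stop("`arena` must have length dims")
  lam_min <- min(spacings)
  if (is.null(grid_n)) {
    grid_n <- pmin(200L, ceiling(arena / (lam_min / 50)))
  }
  grid_n <- rep_len(as.integer(grid_n), dims)
  extent <- arena + 2 * margin
  step <- extent / grid_n
  if (any(step > lam_min / 10)) {
    warning("decoding grid coarser than lambda_min/10: ",
            "decoder resolution is limited")
  }
  ax <- lapply(seq_len(dims), function(d)
    (seq_len(grid_n[d]) - 0.5) * step[d] - margin)
  grid <- if (dims == 1) matrix(ax[[1]], ncol = 1) else
    cbind(rep(ax[[1]], times = grid_n[2]), rep(ax[[2]], each = grid_n[1]))
  n_g <- nrow(grid)

  # base steady rates of one module, and its bump phase
  base <- system$base_state
  r0 <- if (!is.null(base$r)) base$r else base$s / spec$tau
  p0 <- attr(base, "phase")

  if (is.null(gains)) gains <- matrix(1 / spacings, m, dims)
  gains <- matrix(gains, m, dims)

  n_neur <- spec$n_neurons
  lnr <- matrix(NA_real_, n_g, m * n_neur)
  for (mu in seq_len(m)) {
    ph <- position_to_phase(grid, spacings[mu], dims, gain = gains[mu, ])
    cols <- (mu - 1) * n_neur + seq_len(n_neur)
    RF <- matrix(NA_real_, n_g, n_neur)
    for (g in seq_len(n_g)) {
      dp <- if (dims == 1) ph[g] - p0 else ph[g, ] - p0
      RF[g, ] <- translate_state(system$net, r0, dp)
    }
    rmax <- apply(RF, 2, max)
    floor_i <- rate_floor_frac * ifelse(rmax > 0, rmax, max(rmax))
    RF <- pmax(RF, rep(floor_i, each = n_g))
    lnr[, cols] <- log(RF)
  }
  structure(list(grid = grid, lnr = lnr, spacings = spacings,
                 gains = gains, arena = arena, grid_n = grid_n,
                 margin = margin, dims = dims,
                 m = m, n_neurons = n_neur,
                 rate_floor_frac = rate_floor_frac),
            class = "receptive_field_map")
}

# --- effective spike counts --------------------------------------------

#' Exponentially weighted effective spike counts
#'
#' The decoder's evidence at time t is, per neuron, the sum of
#' \eqn{\exp(-(t - t_s)/\tau_d)} over all spikes before t. `method
#' = "running"` uses the recursive update between sample times; `"direct"`
#' evaluates the kernel sum explicitly (reference implementation; the two
#' agree to machine precision).
#'
#' @param spikes Spike raster: either a list of per-neuron spike-time
#'   vectors, or a data frame with columns `neuron` and `time`.
#' @param n_neurons Number of neurons (required for data-frame input).
#' @param times Sample times, increasing.
#' @param tau_d Decoder kernel time constant, seconds.
#' @param method "running" or "direct".
#' @return Matrix `[n_neurons, length(times)]` of effective counts.
#' @export
effective_counts <- function(spikes, times, tau_d = 0.01,
                             n_neurons = NULL,
                             method = c("running", "direct")) {
  method <- match.arg(method)
  if (is.data.frame(spikes)) {
    if (is.null(n_neurons)) n_neurons <- max(spikes$neuron)
    lst <- split(spikes$time, factor(spikes$neuron, levels = seq_len(n_neurons)))
  } else {
    lst <- spikes
    n_neurons <- length(lst)
  }
  nt <- length(times)
  out <- matrix(0, n_neurons, nt)
  if (method == "direct") {
    for (i in seq_len(n_neurons)) {
      ts <- lst[[i]]
      if (!length(ts)) next
      for (k in seq_len(nt)) {
        sel <- ts <= times[k]
        out[i, k] <- sum(exp(-(times[k] - ts[sel]) / tau_d))
      }
    }
    return(out)
  }
  for (i in seq_len(n_neurons)) {
    ts <- sort(lst[[i]])
    if (!length(ts)) next
    n <- 0
    t_prev <- -Inf
    j <- 1L
    for (k in seq_len(nt)) {
      tk <- times[k]
      while (j <= length(ts) && ts[j] <= tk) {
        if (is.finite(t_prev)) n <- n * exp(-(ts[j] - t_prev) / tau_d)
        else n <- 0
        n <- n + 1
        t_prev <- ts[j]
        j <- j + 1L
      }
      if (is.finite(t_prev)) out[i, k] <- n * exp(-(tk - t_prev) / tau_d)
    }
  }
  out
}

# --- decoding -----------------------------------------------------------

#' Maximum-likelihood position decode from spikes
#'
#' At each sample time the decoded position maximises
#' \eqn{\sum_i n_i(t) \ln \bar r_i(x)} over the template grid, where
#' \eqn{n_i(t)} are the exponential-kernel effective counts. Ties are
#' broken toward the lowest grid index. Samples before the first spike
#' carry no evidence and are marked invalid.
#'
#' @param spikes Effective-count matrix `[n_neurons_total, n_times]`
#'   (modules stacked as in the receptive-field map), or a spike raster as
#'   accepted by [effective_counts()] (then `times` and `tau_d` are used to
#'   build the counts).
#' @param rf A [measure_receptive_fields()] map.
#' @param times Sample times (required with raster input; otherwise
#'   optional, for labelling).
#' @param tau_d Decoder kernel time constant.
#' @return Object of class `decoded_path`: data frame with `t`, decoded
#'   coordinates, `loglik`, `valid`.
#' @export
decode_position <- function(spikes, rf, times = NULL, tau_d = 0.01) {
  ntot <- rf$m * rf$n_neurons
  if (is.matrix(spikes) && nrow(spikes) == ntot && !is.data.frame(spikes)) {
    counts <- spikes
  } else {
    if (is.null(times)) stop("supply `times` with raster input")
    counts <- effective_counts(spikes, times, tau_d, n_neurons = ntot)
  }
  nt <- ncol(counts)
  if (is.null(times)) times <- seq_len(nt)
  ll <- rf$lnr %*% counts # n_g x n_times
  idx <- max.col(t(ll), ties.method = "first")
  valid <- colSums(counts) > 0
  xhat <- rf$grid[idx, , drop = FALSE]
  xhat[!valid, ] <- NA_real_
  out <- data.frame(t = times)
  out$x <- xhat[, 1]
  if (rf$dims == 2) out$y <- xhat[, 2]
  out$loglik <- ll[cbind(idx, seq_len(nt))]
  out$loglik[!valid] <- NA_real_
  out$valid <- valid
  structure(list(path = out, dims = rf$dims, grid_n = rf$grid_n,
                 spacings = rf$spacings),
            class = "decoded_path")
}

#' Flag discontinuities in a decoded path
#'
#' A readout discontinuity (catastrophic error candidate) is a jump between
#' consecutive decoded samples larger than `threshold`; the default
#' threshold of half the smallest grid spacing is larger than decoder
#' jitter yet smaller than any legitimate move at plausible running speeds
#' for decoding strides up to ~100 ms.
#'
#' @param path A `decoded_path` (or its data frame).
#' @param threshold Jump threshold, meters; default `min(spacings)/2` when
#'   available.
#' @return Numeric vector of event times (possibly empty), with the logical
#'   flag vector in `attr(, "flags")`.
#' @export
detect_discontinuities <- function(path, threshold = NULL) {
  d <- if (inherits(path, "decoded_path")) path$path else path
  if (is.null(threshold)) {
    if (inherits(path, "decoded_path") && !is.null(path$spacings)) {
      threshold <- min(path$spacings) / 2
    } else stop("supply `threshold`")
  }
  n <- nrow(d)
  flags <- rep(FALSE, n)
  if (n >= 2) {
    dx <- diff(d$x)
    jump2 <- dx^2
    if ("y" %in% names(d)) jump2 <- jump2 + diff(d$y)^2
    ok <- d$valid[-n] & d$valid[-1]
    flags[-1] <- ok & sqrt(jump2) > threshold
  }
  structure(d$t[flags], flags = flags, threshold = threshold)
}

#' Success and error curves over decoding trials
#'
#' A trial counts as a success at time t if its decoded path contains no
#' discontinuity in (0, t\]. Also returns the mean squared error of the
#' decoded position against the true trajectory and the random-guess
#' baseline (expected squared distance between the true position and a
#' uniformly drawn arena point).
#'
#' @param paths List of `decoded_path` objects on a common time grid.
#' @param truth Matrix (or data frame) of true positions at the same times.
#' @param arena Arena side lengths (for the baseline).
#' @param threshold Discontinuity threshold (default from the paths).
#' @return Object of class `drift_metrics`: data frame `curves` with `t`,
#'   `success` (fraction), `mse`, `mse_guess`; `events` (list of event
#'   times); `n_trials`.
#' @export
success_and_error_curves <- function(paths, truth, arena, threshold = NULL) {
  if (length(paths) < 2) stop("need at least 2 trials")
  tgrid <- paths[[1]]$path$t
  for (p in paths) {
    if (!isTRUE(all.equal(p$path$t, tgrid))) {
      stop("trials must share a common time grid")
    }
  }
  truth <- as.matrix(truth)
  n <- length(tgrid)
  K <- length(paths)
  events <- lapply(paths, detect_discontinuities, threshold = threshold)
  first_event <- vapply(events, function(e)
    if (length(e)) min(e) else Inf, numeric(1))
  success <- vapply(tgrid, function(tt)
    mean(first_event > tt), numeric(1))
  se <- matrix(NA_real_, n, K)
  for (k in seq_len(K)) {
    d <- paths[[k]]$path
    err2 <- (d$x - truth[, 1])^2
    if ("y" %in% names(d)) err2 <- err2 + (d$y - truth[, 2])^2
    se[, k] <- err2
  }
  mse <- rowMeans(se)
  guess <- rowSums(vapply(seq_along(arena), function(dd) {
    (truth[, dd] - arena[dd] / 2)^2 + arena[dd]^2 / 12
  }, numeric(n)))
  structure(
    list(curves = data.frame(t = tgrid, success = success, mse = mse,
                             mse_guess = guess),
         events = events, n_trials = K),
    class = "drift_metrics"
  )
}

#' Drift metrics of phase trajectories
#'
#' Converts unwrapped module phases into represented displacements
#' (phase x spacing) and quantifies coordination: the mean square
#' displacement (MSD) between the scaled trajectories of every module pair,
#' and each module's mean square error (MSE) against the true displacement,
#' with fitted linear slopes.
#'
#' @param theta Unwrapped phase trajectories, array `[n_t, m, K]` (single
#'   trial matrices `[n_t, m]` are accepted).
#' @param spacings Module spacings, meters.
#' @param t Time grid, length n_t.
#' @param truth True displacement at `t` (meters, relative to start);
#'   vector, or NULL to skip MSE.
#' @return Object of class `drift_metrics`: data frames `msd` (t, pair,
#'   msd), `mse` (t, module, mse), and `slopes` (per module, m^2/s).
#' @export
phase_msd_mse <- function(theta, spacings, t, truth = NULL) {
  if (length(dim(theta)) == 2) theta <- array(theta, c(dim(theta), 1))
  n_t <- dim(theta)[1]; m <- dim(theta)[2]; K <- dim(theta)[3]
  if (length(t) != n_t) stop("`t` length mismatch")
  # wrapped input detection: phases confined to [0, 1) that jump by more
  # than half a cycle between samples were almost surely not unwrapped
  # (a genuinely continuous trajectory leaves the unit interval)
  if (all(theta >= 0 & theta < 1)) {
    for (mu in seq_len(m)) {
      jumps <- abs(diff(matrix(theta[, mu, ], n_t, K)))
      if (any(jumps > 0.5)) {
        stop("phase trajectories look wrapped (jumps > 0.5); ",
             "unwrap before calling (see unwrap_phase)")
      }
    }
  }
  # displacement in meters relative to the first sample
  X <- array(NA_real_, dim(theta))
  for (mu in seq_len(m)) {
    X[, mu, ] <- (theta[, mu, ] - rep(theta[1, mu, ], each = n_t)) *
      spacings[mu]
  }
  pairs <- utils::combn(m, 2)
  msd <- do.call(rbind, lapply(seq_len(ncol(pairs)), function(pi) {
    i <- pairs[1, pi]; j <- pairs[2, pi]
    d2 <- (X[, i, , drop = FALSE] - X[, j, , drop = FALSE])^2
    data.frame(t = t, pair = paste0(i, "-", j),
               msd = rowMeans(matrix(d2, n_t, K)))
  }))
  mse <- NULL
  slopes <- NULL
  if (!is.null(truth)) {
    truth <- as.numeric(truth)
    if (length(truth) != n_t) stop("`truth` length mismatch")
    rel <- truth - truth[1]
    mse <- do.call(rbind, lapply(seq_len(m), function(mu) {
      e2 <- (X[, mu, ] - rel)^2
      data.frame(t = t, module = mu, mse = rowMeans(matrix(e2, n_t, K)))
    }))
    slopes <- vapply(seq_len(m), function(mu) {
      d <- mse[mse$module == mu, ]
      unname(stats::coef(stats::lm(d$mse ~ d$t))[2])
    }, numeric(1))
  }
  structure(list(msd = msd, mse = mse, slopes = slopes,
                 n_trials = K),
            class = "drift_metrics")
}
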