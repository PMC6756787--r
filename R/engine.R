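# Batched integrator for m identically built modules and K parallel trials.
#
# The synaptic state of all modules and trials is one matrix S with
# n_neurons rows and m*K columns (column mu + (k-1)*m holds module mu of
# trial k), so every step is a handful of BLAS calls. This exactness-neutral
# batching is what keeps the desk-scale 2D experiments tractable.
#
# Bx/By: external velocity inputs, arrays [m, K, nstep] (drive units), or
# NULL for zero input. mode "rate" integrates the deterministic rate
# dynamics; "poisson" replaces rates by Poisson spike counts (each spike
# increments s by 1). readout "poisson" additionally draws spikes from the
# instantaneous rates for decoding only (exponential-kernel effective counts
# with time constant tau_d, delivered to count_hook at each record).
integrate_modules <- function(net, m, K, C, a, beta, S0, Bx = NULL, By = NULL,
                              dt, nstep, mode = c("rate", "poisson"),
                              record_stride = 100L,
                              readout = c("none", "poisson"),
                              tau_d = 0.01, count_hook = NULL,
                              collect_spikes = FALSE,
                              spike_gain = 1,
                              v_scale = NULL,
                              s_ceiling = 1e3) {
  mode <- match.arg(mode)
  readout <- match.arg(readout)
  spec <- net$spec
  dims <- spec$dims
  N <- spec$N
  n_neur <- spec$n_neurons
  mK <- m * K
  stopifnot(nrow(S0) == n_neur, ncol(S0) == mK)
  check_dt(dt, spec$tau)
  tau <- spec$tau
  I0 <- spec$I0

  iR <- subpop_index(net, "R"); iL <- subpop_index(net, "L")
  if (dims == 2) { iU <- subpop_index(net, "U"); iD <- subpop_index(net, "D") }
  pa_coord <- if (dims == 1) net$phases else net$lattice[, 1]
  Ca <- cos(2 * pi * pa_coord); Sa <- sin(2 * pi * pa_coord)
  if (dims == 2) {
    Cb <- cos(2 * pi * net$lattice[, 2])
    Sb <- sin(2 * pi * net$lattice[, 2])
  }

  n_rec <- nstep %/% record_stride
  PA <- matrix(NA_real_, n_rec, mK)
  PB <- if (dims == 2) matrix(NA_real_, n_rec, mK) else NULL
  OX <- matrix(NA_real_, n_rec, mK)
  OY <- if (dims == 2) matrix(NA_real_, n_rec, mK) else NULL
  t_rec <- seq_len(n_rec) * record_stride * dt

  use_counts <- (readout == "poisson") || (mode == "poisson" && !is.null(count_hook))
  NC <- if (use_counts) matrix(0, n_neur, mK) else NULL
  kd <- exp(-dt / tau_d)
  spike_log <- if (collect_spikes) vector("list", 2000L) else NULL
  spike_n <- 0L

  S <- S0
  fbeta <- beta / tau
  # coupling drive scale a * beta / tau: computed once (and supplied
  # directly by coupled systems as 1/n_act, making the dynamics exactly
  # independent of beta)
  if (is.null(v_scale)) v_scale <- a * beta / tau
  decay <- 1 - dt / tau
  rec_i <- 0L

  for (step in seq_len(nstep)) {
    U <- net$W_red %*% S # N x mK
    omx <- .colSums(S[iR, , drop = FALSE], N, mK) -
      .colSums(S[iL, , drop = FALSE], N, mK)
    vx <- v_scale * (C %*% matrix(omx, m, K))
    if (!is.null(Bx)) vx <- vx + Bx[, , step]
    vxv <- rep(as.vector(vx), each = N)
    base <- U + I0
    if (dims == 1) {
      ARG <- rbind(base + vxv, base - vxv)
    } else {
      omy <- .colSums(S[iU, , drop = FALSE], N, mK) -
        .colSums(S[iD, , drop = FALSE], N, mK)
      vy <- v_scale * (C %*% matrix(omy, m, K))
      if (!is.null(By)) vy <- vy + By[, , step]
      vyv <- rep(as.vector(vy), each = N)
      ARG <- rbind(base + vxv, base - vxv, base + vyv, base - vyv)
    }
    ARG[ARG < 0] <- 0
    R <- ARG / tau # rates, Hz

    if (mode == "rate") {
      S <- decay * S + dt * R
      if (use_counts) {
        cnt <- draw_counts(R, dt)
        NC <- kd * NC + cnt
      }
    } else {
      # spike_gain g scales rates by g and increments by 1/g (quantal-size
      # scaling); g = 1 is the physical model
      cnt <- draw_counts(R, dt * spike_gain)
      if (spike_gain != 1) cnt <- cnt / spike_gain
      S <- decay * S + cnt
      if (use_counts) NC <- kd * NC + cnt
    }
    if (collect_spikes && (mode == "poisson" || use_counts)) {
      nz <- which(cnt > 0)
      if (length(nz)) {
        spike_n <- spike_n + 1L
        if (spike_n > length(spike_log)) {
          spike_log <- c(spike_log, vector("list", length(spike_log)))
        }
        spike_log[[spike_n]] <- cbind(idx = nz, n = cnt[nz], step = step)
      }
    }

    if (step %% record_stride == 0L) {
      rec_i <- rec_i + 1L
      if (!all(is.finite(S))) {
        bad <- which(!is.finite(S))[1]
        stop("non-finite synaptic activation at neuron ",
             ((bad - 1) %% n_neur) + 1, " (column ",
             ((bad - 1) %/% n_neur) + 1, ")")
      }
      if (max(abs(S)) > s_ceiling) {
        stop("synaptic activation exceeded the ceiling (", s_ceiling,
             "); the coupled dynamics look unstable - run check_stability() ",
             "on the coupling matrix")
      }
      stot <- S[iR, , drop = FALSE] + S[iL, , drop = FALSE]
      if (dims == 2) {
        stot <- stot + S[iU, , drop = FALSE] + S[iD, , drop = FALSE]
      }
      PA[rec_i, ] <- (atan2(.colSums(stot * Sa, N, mK),
                            .colSums(stot * Ca, N, mK)) / (2 * pi)) %% 1
      OX[rec_i, ] <- fbeta * omx
      if (dims == 2) {
        PB[rec_i, ] <- (atan2(.colSums(stot * Sb, N, mK),
                              .colSums(stot * Cb, N, mK)) / (2 * pi)) %% 1
        OY[rec_i, ] <- fbeta * omy
      }
      if (use_counts && !is.null(count_hook)) count_hook(rec_i, NC)
    }
  }

  spikes <- NULL
  if (collect_spikes && spike_n > 0L) {
    tab <- do.call(rbind, spike_log[seq_len(spike_n)])
    tab <- tab[rep(seq_len(nrow(tab)), tab[, "n"]), , drop = FALSE]
    col <- ((tab[, "idx"] - 1) %/% n_neur) + 1
    neuron <- ((tab[, "idx"] - 1) %% n_neur) + 1
    spikes <- data.frame(
      module = ((col - 1) %% m) + 1,
      trial = ((col - 1) %/% m) + 1,
      neuron = neuron,
      time = tab[, "step"] * dt
    )
    spikes <- spikes[order(spikes$trial, spikes$module,
                           spikes$neuron, spikes$time), ]
    rownames(spikes) <- NULL
  }

  list(t = t_rec, phase_a = PA, phase_b = PB,
       omega_x = OX, omega_y = OY,
       S = S, counts = NC, spikes = spikes,
       m = m, K = K, dims = dims)
}

# Poisson spike counts with mean R * dt, drawing only where the rate is
# positive (the silent majority of neurons contributes exact zeros).
draw_counts <- function(R, dt) {
  cnt <- R * 0
  pos <- which(R > 0)
  cnt[pos] <- stats::rpois(length(pos), R[pos] * dt)
  cnt
}

# Reshape an engine record matrix [n_rec, m*K] into [n_rec, m, K].
split_columns <- function(M, m, K) {
  array(M, dim = c(nrow(M), m, K))
}
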