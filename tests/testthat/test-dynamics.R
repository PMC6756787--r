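zero_weight_net <- function(N = 4) {
  net <- build_network(module_spec(dims = 1, N = N))
  net$W[] <- 0
  net$W_red[] <- 0
  net
}

test_that("the origin is a fixed point and constant drive has the closed-form fixed point", {
  net <- net64()
  st <- synaptic_state(rep(0, 128))
  st2 <- step_rate_dynamics(net, st, rep(0, 128), dt = 1e-3)
  expect_identical(st2$s, rep(0, 128))
  # W = 0, feedforward I0 = 3: s* = tau * phi(3) = 3
  net0 <- zero_weight_net()
  st <- synaptic_state(rep(0, 8))
  for (k in 1:8000) st <- step_rate_dynamics(net0, st, rep(3, 8), 1e-3)
  expect_equal(st$s, rep(3, 8), tolerance = 1e-6)
})

test_that("relaxation forms a stationary bump at the requested phase", {
  st <- base64()
  expect_equal(unname(attr(st, "phase")), 0.5, tolerance = 1e-3)
  # fixed-point identity r = s/tau
  expect_lt(max(abs(st$r - st$s / 0.01)), 1e-8)
  # one further step barely changes the state
  st2 <- step_rate_dynamics(net64(), st, rep(3, 128), 1e-3)
  expect_lt(max(abs(st2$s - st$s)), 1e-3 * 1e-6)
})

test_that("the bump shape is unique up to translation", {
  net <- net64()
  set.seed(21)
  # long relaxation: from random activity the bump settles into a
  # lattice-pinned position on a ~1 s time scale at this size
  r1 <- relax_to_bump(net, init = synaptic_state(runif(128)), dt = 1e-3,
                      T_relax = 6)
  set.seed(99)
  r2 <- relax_to_bump(net, init = synaptic_state(runif(128)), dt = 1e-3,
                      T_relax = 6)
  expect_equal(sort(r1$r), sort(r2$r), tolerance = 1e-6)
})

test_that("no bump forms when the connectivity is too weak", {
  spec <- module_spec(dims = 1, N = 64, A = 2)
  net <- build_network(spec)
  expect_error(relax_to_bump(net, dt = 1e-3), "no bump formed")
})

test_that("phase estimation is exact for symmetric bumps and equivariant to lattice shifts", {
  net <- net64()
  st <- bump_state(net, phase = 0.25, width = 0.1)
  expect_equal(unname(estimate_phase(st, net)), 0.25, tolerance = 1e-12)
  st2 <- translate_state(net, base64(), 1 / 64) # one lattice site
  p1 <- estimate_phase(base64(), net)
  p2 <- estimate_phase(st2, net)
  expect_equal(ring_distance(p2 - p1), 1 / 64, tolerance = 1e-10)
  expect_error(estimate_phase(synaptic_state(rep(1, 128)), net), "flat")
})

test_that("2D relaxation settles a bump with exact lattice-phase estimation", {
  st <- base2d()
  expect_equal(unname(attr(st, "phase")), c(0.5, 0.5), tolerance = 2e-3)
  st2 <- translate_state(net2d(), st, c(1 / 12, 0))
  p <- estimate_phase(st2, net2d())
  expect_equal(unname(ring_distance(p - attr(st, "phase"))),
               c(1 / 12, 0), tolerance = 1e-10)
})

test_that("silent Poisson neurons decay exponentially and spike counts follow the rate", {
  net0 <- zero_weight_net()
  st <- synaptic_state(rep(2, 8))
  set.seed(5)
  nstep <- 500L
  for (k in seq_len(nstep)) {
    out <- step_poisson_dynamics(net0, st, rep(-1, 8), 1e-3)
    st <- out$state
    expect_identical(out$spikes, rep(0L, 8))
  }
  expect_equal(st$s, rep(2 * (1 - 1e-3 / 0.01)^nstep, 8), tolerance = 1e-12)
  # steady rate 300 Hz: total count over 10 s within 3 standard errors
  set.seed(6)
  st <- synaptic_state(rep(0, 8))
  total <- 0
  for (k in 1:10000) {
    out <- step_poisson_dynamics(net0, st, rep(3, 8), 1e-3)
    st <- out$state
    total <- total + sum(out$spikes)
  }
  expected <- 8 * 300 * 10
  expect_lt(abs(total - expected), 3 * sqrt(expected))
})

test_that("the spiking network tracks the rate-model mean field", {
  net <- net200()
  base <- base200()
  trials <- 50L
  set.seed(31)
  res <- gridlock:::integrate_modules(
    net, m = 1L, K = trials, C = matrix(0, 1, 1), a = 1, beta = 1,
    S0 = matrix(base$s, length(base$s), trials), dt = 1e-3, nstep = 500L,
    mode = "poisson", record_stride = 500L)
  mean_mass <- mean(colSums(res$S))
  rate_mass <- sum(base$s)
  expect_lt(abs(mean_mass - rate_mass) / rate_mass, 0.1)
})

test_that("velocity integration is steady and odd in the input", {
  net <- net200()
  base <- base200()
  dI <- 0.02
  Bx <- array(rep(c(dI, -dI), times = 600), c(1, 2, 600))
  res <- gridlock:::integrate_modules(
    net, m = 1L, K = 2L, C = matrix(0, 1, 1), a = 1, beta = 1,
    S0 = matrix(base$s, length(base$s), 2), Bx = Bx, dt = 5e-4,
    nstep = 600L, record_stride = 10L)
  th_p <- unwrap_phase(res$phase_a[, 1])
  th_m <- unwrap_phase(res$phase_a[, 2])
  n <- length(th_p)
  i0 <- ceiling(n / 3) # transient: a few synaptic time constants
  v_p <- diff(th_p[i0:n]) / diff(res$t[i0:n])
  # constant phase velocity: coefficient of variation below 2%
  expect_lt(stats::sd(v_p) / abs(mean(v_p)), 0.02)
  # odd symmetry
  disp_p <- th_p[n] - th_p[i0]
  disp_m <- th_m[n] - th_m[i0]
  expect_lt(abs(disp_p + disp_m) / abs(disp_p), 1e-3)
})

test_that("phase diffusion falls monotonically with the spike rate scale", {
  net <- net64()
  base <- base64()
  trials <- 150L
  vars <- vapply(c(1, 2, 4, 8), function(g) {
    set.seed(41)
    res <- gridlock:::integrate_modules(
      net, m = 1L, K = trials, C = matrix(0, 1, 1), a = 1, beta = 1,
      S0 = matrix(base$s, length(base$s), trials), dt = 1e-3,
      nstep = 1000L, mode = "poisson", record_stride = 1000L,
      spike_gain = g)
    # phases stay near 0.5 at these scales: no wrap correction needed
    stats::var(res$phase_a[1, ])
  }, numeric(1))
  expect_true(all(diff(vars) < 0))
})
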