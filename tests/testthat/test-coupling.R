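test_that("velocity readout vanishes on the symmetric bump and tracks the phase velocity", {
  net <- net200()
  base <- base200()
  expect_lt(abs(velocity_readout(base, net)["x"]), 1e-10)
  # constant drive: the input-scaled readout a*omega recovers the velocity
  # input, hence the phase velocity, within 5% (the raw omega is
  # proportional to theta-dot with the beta-dependent scale absorbed by a)
  dI <- 0.015
  Bx <- array(dI, c(1, 1, 1200))
  res <- gridlock:::integrate_modules(
    net, m = 1L, K = 1L, C = matrix(0, 1, 1), a = 1, beta = 1,
    S0 = matrix(base$s, ncol = 1), Bx = Bx, dt = 5e-4, nstep = 1200L,
    record_stride = 10L)
  th <- unwrap_phase(res$phase_a[, 1])
  n <- length(th)
  i0 <- ceiling(n / 3)
  thdot <- (th[n] - th[i0]) / (res$t[n] - res$t[i0])
  om_avg <- mean(res$omega_x[i0:n, 1])
  expect_gt(om_avg, 0) # positive input moves the bump in +theta
  expect_gt(thdot, 0)
  a_net <- compute_input_scaling(net, base)
  expect_lt(abs(a_net * om_avg - dI) / dI, 0.05)
})

test_that("the input-scaling factor counts active neurons and cancels beta", {
  net <- net64()
  base <- base64()
  a1 <- compute_input_scaling(net, base, beta = 1)
  # independent count oracle
  u <- as.vector(net$W %*% base$s) + 3
  expect_equal(a1, 0.01 / sum(u > 0))
  expect_gt(a1, 0)
  a2 <- compute_input_scaling(net, base, beta = 2)
  expect_equal(a2, a1 / 2)
})

test_that("dynamics are invariant to the readout scale beta", {
  sys1 <- sys64(standard_coupling(2), beta = 1)
  sys2 <- sys64(standard_coupling(2), beta = 7.3)
  b <- function(t) c(0.02 * sin(2 * pi * t), 0)
  r1 <- run_coupled(sys1, b = b, T = 0.5, dt = 1e-3)
  r2 <- run_coupled(sys2, b = b, T = 0.5, dt = 1e-3)
  expect_equal(r1$theta, r2$theta, tolerance = 1e-10)
})

test_that("assembled drives reduce to I0 without coupling or input", {
  sys <- sys64(matrix(0, 2, 2))
  ff <- assemble_coupled_drive(sys, b = c(0, 0))
  for (mu in 1:2) expect_identical(ff[[mu]], rep(3, 128))
})

test_that("readout coupling equals the explicit synaptic coupling matrix", {
  sys <- sys64(standard_coupling(2))
  # put the system in an asymmetric transient so omega is nonzero
  states <- list(
    translate_state(net64(), base64(), 0.13),
    synaptic_state(base64()$s * seq(0.5, 1.5, length.out = 128))
  )
  b <- c(0.01, -0.02)
  ff <- assemble_coupled_drive(sys, b = b, states = states)
  Wc <- coupling_weight_matrix(sys$beta, 0.01, net64()$subpop, net64()$subpop)
  for (mu in 1:2) {
    coup <- rowSums(vapply(1:2, function(rho)
      sys$a * sys$C[mu, rho] * as.vector(Wc %*% states[[rho]]$s),
      numeric(128)))
    sgn <- rep(c(1, -1), each = 64)
    expect_equal(ff[[mu]], 3 + sgn * b[mu] + coup, tolerance = 1e-12)
  }
})

test_that("the coupling weight matrix is uniform, all-to-all and rank one", {
  sp <- factor(rep(c("R", "L"), each = 8), levels = c("R", "L"))
  Wc <- coupling_weight_matrix(2, 0.01, sp, sp)
  expect_true(all(abs(Wc) == 2 / 0.01)) # no zero entries within the channel
  sv <- svd(Wc)$d
  expect_lt(sv[2] / sv[1], 1e-12)
  # swapping the presynaptic R/L labels negates the matrix
  swapped <- factor(rep(c("L", "R"), each = 8), levels = c("R", "L"))
  expect_equal(coupling_weight_matrix(2, 0.01, sp, swapped), -Wc)
  # 2D: horizontal and vertical channels do not mix
  sp2 <- factor(c("R", "L", "U", "D"), levels = c("R", "L", "U", "D"))
  Wc2 <- coupling_weight_matrix(1, 0.01, sp2, sp2)
  expect_identical(Wc2[1:2, 3:4], matrix(0, 2, 2))
  expect_identical(Wc2[3:4, 1:2], matrix(0, 2, 2))
})

test_that("reference coupling matrices match the published values and are stable", {
  C2 <- standard_coupling(2)
  expect_equal(diag(C2), rep(-20, 2))
  expect_equal(C2[1, 2], 14.142, tolerance = 1e-4)
  expect_equal(C2[2, 1], 28.284, tolerance = 1e-4)
  C3 <- standard_coupling(3)
  expect_identical(C3[1, 3], 0)
  expect_identical(C3[3, 1], 0)
  expect_error(standard_coupling(4), "m = 2 or 3")
  # eigenvalue oracle: direct characteristic roots of the 2x2 case
  Cs <- -20; disc <- sqrt(C2[1, 2] * C2[2, 1])
  expect_equal(sort(Re(eigen(C2)$values)), sort(c(Cs - disc, Cs + disc)),
               tolerance = 1e-10)
  expect_true(check_stability(C2)$stable)
  expect_true(check_stability(C3)$stable)
})

test_that("zero-input phases are steady and uncoupled modules do not leak", {
  sys <- sys64(standard_coupling(2))
  run <- run_coupled(sys, T = 10, dt = 1e-3)
  drift <- abs(run$theta[nrow(run$theta), , 1] - run$theta[1, , 1])
  expect_lt(max(drift), 1e-4)
  # uncoupled, input only to module 1
  sysu <- sys64(matrix(0, 2, 2))
  b <- function(t) c(0.02, 0)
  runu <- run_coupled(sysu, b = b, T = 1, dt = 1e-3)
  d1 <- abs(runu$theta[nrow(runu$theta), 1, 1] - runu$theta[1, 1, 1])
  d2 <- max(abs(runu$theta[, 2, 1] - runu$theta[1, 2, 1]))
  expect_gt(d1, 0.5) # module 1 integrates the velocity input
  expect_lt(d2, 1e-3) # module 2 is unresponsive
})

test_that("every combination of relative phases is a steady state of the coupled system", {
  # capacity preservation: the coupling acts on velocities, never on phases
  sys <- sys64(standard_coupling(2))
  # lattice-commensurate offsets: exact steady states of the discrete ring
  deltas <- round(seq(0, 0.9, by = 0.1) * 64) / 64
  net <- net64()
  S0 <- matrix(NA_real_, 128, 2 * length(deltas))
  for (k in seq_along(deltas)) {
    S0[, 2 * k - 1] <- base64()$s
    S0[, 2 * k] <- translate_state(net, base64()$s, deltas[k])
  }
  res <- gridlock:::integrate_modules(
    net, m = 2L, K = length(deltas), C = sys$C, a = sys$a, beta = 1,
    S0 = S0, dt = 1e-3, nstep = 5000L, record_stride = 5000L)
  final_delta <- (res$phase_a[1, seq(2, 20, 2)] -
                    res$phase_a[1, seq(1, 19, 2)]) %% 1
  expect_equal(ring_distance(final_delta - deltas), rep(0, 10),
               tolerance = 1e-3)
})

test_that("instability is reported with a pointer to the stability screen", {
  # strong positive self-coupling; a brief input pulse seeds the runaway
  # (the symmetric resting state has omega exactly 0 and never destabilises
  # on its own)
  Cbad <- matrix(c(30, 0, 0, 30), 2)
  expect_false(check_stability(Cbad)$stable)
  sys <- sys64(Cbad)
  b <- function(t) c(if (t < 0.1) 0.01 else 0, 0)
  expect_error(run_coupled(sys, b = b, T = 1, dt = 1e-3), "check_stability")
})
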