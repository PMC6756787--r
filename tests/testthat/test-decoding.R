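rf_fixture <- function() gl_memo("rf_fixture", {
  sys <- sys64(matrix(0, 2, 2))
  measure_receptive_fields(sys, spacings = c(0.5, 0.5 / sqrt(2)),
                           arena = 1.6, grid_n = 200L)
})

test_that("receptive fields are periodic with the module spacing", {
  rf <- rf_fixture()
  step <- 1.6 / 200
  for (mu in 1:2) {
    lam <- rf$spacings[mu]
    f <- exp(rf$lnr[, (mu - 1) * 128 + 10]) # one neuron's field
    n <- length(f)
    lags <- 10:(n / 2)
    cc <- vapply(lags, function(l)
      stats::cor(f[1:(n - l)], f[(1 + l):n]), numeric(1))
    best <- lags[which.max(cc)] * step
    expect_lt(abs(best - lam), step + 1e-12)
  }
})

test_that("translating a state by a full period is the identity", {
  net <- net64()
  s <- base64()$s
  expect_equal(translate_state(net, s, 1), s, tolerance = 1e-10)
  # 2D: full period along either lattice vector
  s2 <- base2d()$s
  expect_equal(translate_state(net2d(), s2, c(1, 0)), s2, tolerance = 1e-10)
  expect_equal(translate_state(net2d(), s2, c(0, 1)), s2, tolerance = 1e-10)
})

test_that("noise-free effective counts decode back to the encoded position", {
  rf <- rf_fixture()
  tau_d <- 0.01
  for (g0 in c(13L, 57L, 101L, 180L)) {
    counts <- matrix(exp(rf$lnr[g0, ]) * tau_d, ncol = 1)
    dec <- decode_position(counts, rf, times = 0.5)
    expect_equal(dec$path$x, rf$grid[g0, 1], tolerance = 1.6 / 200 + 1e-12)
  }
})

test_that("running and direct kernel evaluations agree to machine precision", {
  set.seed(81)
  spikes <- lapply(1:5, function(i) sort(runif(rpois(1, 20), 0, 2)))
  times <- seq(0.1, 2, by = 0.05)
  a <- effective_counts(spikes, times, tau_d = 0.01, method = "running")
  b <- effective_counts(spikes, times, tau_d = 0.01, method = "direct")
  expect_equal(a, b, tolerance = 1e-12)
})

test_that("a single module is ambiguous across periods and ties resolve to the first grid point", {
  sys1 <- gl_memo("sys1d_single",
                  coupled_system(spec64(), 1, C = matrix(0, 1, 1),
                                 net = net64(), base_state = base64()))
  lam <- 0.5
  rf1 <- measure_receptive_fields(sys1, spacings = lam, arena = 1.5,
                                  grid_n = 150L)
  # encode a position in the *second* period
  x0 <- 0.8
  g0 <- which.min(abs(rf1$grid[, 1] - x0))
  counts <- matrix(exp(rf1$lnr[g0, ]) * 0.01, ncol = 1)
  dec <- decode_position(counts, rf1, times = 0)
  # the likelihood is lambda-periodic: the argmax lands one period earlier
  expect_equal(dec$path$x, x0 - lam, tolerance = 2 * 1.5 / 150)
})

test_that("samples before the first spike are invalid, not zero", {
  rf <- rf_fixture()
  counts <- matrix(0, 256, 3)
  counts[10, 3] <- 1
  dec <- decode_position(counts, rf, times = c(0.1, 0.2, 0.3))
  expect_identical(dec$path$valid, c(FALSE, FALSE, TRUE))
  expect_true(all(is.na(dec$path$x[1:2])))
})

test_that("discontinuity detection flags teleports and respects the kinematic bound", {
  tgrid <- seq(0, 1, by = 0.01)
  d <- data.frame(t = tgrid, x = 0.5 + 0 * tgrid, valid = TRUE)
  expect_length(detect_discontinuities(d, threshold = 0.1), 0)
  d2 <- d
  d2$x[51:101] <- d2$x[51:101] + 3 * 0.2 # one teleport of 3 lambda_min
  ev <- detect_discontinuities(d2, threshold = 0.1)
  expect_equal(as.numeric(ev), tgrid[51])
  # smooth motion below threshold speed never triggers
  vmax <- 0.5
  d3 <- data.frame(t = tgrid, x = 0.2 + vmax * tgrid, valid = TRUE)
  expect_length(detect_discontinuities(d3, threshold = vmax * 0.01 * 1.5), 0)
})

test_that("success curves are exact for constructed trials", {
  tgrid <- seq(0.01, 1, by = 0.01)
  mkpath <- function(x) {
    structure(list(path = data.frame(t = tgrid, x = x, valid = TRUE),
                   dims = 1L, spacings = 0.2),
              class = "decoded_path")
  }
  clean <- mkpath(rep(0.5, 100))
  jumpy <- mkpath(c(rep(0.5, 49), rep(1.4, 51)))
  truth <- matrix(0.5, 100, 1)
  met <- success_and_error_curves(list(clean, clean), truth, arena = 2,
                                  threshold = 0.1)
  expect_true(all(met$curves$success == 1))
  met2 <- success_and_error_curves(list(clean, jumpy), truth, arena = 2,
                                   threshold = 0.1)
  expect_true(all(diff(met2$curves$success) <= 0)) # nonincreasing
  expect_equal(met2$curves$success[100], 0.5)
  expect_equal(met2$curves$success[40], 1)
  # random-guess baseline: uniform-point oracle
  set.seed(9)
  guess_mc <- mean((0.5 - runif(2e5, 0, 2))^2)
  expect_equal(met$curves$mse_guess[1], guess_mc, tolerance = 0.01)
})

test_that("phase MSD/MSE reproduce Brownian statistics and reject wrapped input", {
  set.seed(91)
  K <- 300; n_t <- 200; D <- 0.005; dt <- 0.02
  spac <- c(0.4, 0.3)
  theta <- array(0, c(n_t, 2, K))
  for (mu in 1:2) {
    inc <- matrix(rnorm((n_t - 1) * K, 0, sqrt(2 * D * dt)), n_t - 1, K)
    theta[, mu, ] <- rbind(0, apply(inc, 2, cumsum))
  }
  tgrid <- (0:(n_t - 1)) * dt
  met <- phase_msd_mse(theta, spac, tgrid, truth = rep(0, n_t))
  # pairwise MSD slope: (s1^2 + s2^2) * 2D
  fit <- stats::coef(stats::lm(msd ~ t, data = met$msd))[2]
  expect_equal(unname(fit), sum(spac^2) * 2 * D, tolerance = 0.15)
  # per-module MSE slope: s_mu^2 * 2D
  expect_equal(met$slopes, spac^2 * 2 * D, tolerance = 0.15)
  expect_identical(phase_msd_mse(theta * 0, spac, tgrid)$msd$msd,
                   rep(0, n_t))
  # a wrapped ramp: confined to [0,1) with near-unit jumps at each wrap
  ramp <- (seq(0, 3, length.out = n_t)) %% 1
  wrapped <- array(rep(ramp, 2 * K), c(n_t, 2, K))
  expect_error(phase_msd_mse(wrapped, spac, tgrid), "unwrap")
})

test_that("2D receptive fields lie on the hexagonal lattice of the module", {
  sys2 <- gl_memo("sys2d_single",
                  coupled_system(module_spec(dims = 2, N = 144), 1,
                                 C = matrix(0, 1, 1), net = net2d(),
                                 base_state = base2d()))
  lam <- 0.4
  rf <- measure_receptive_fields(sys2, spacings = lam, arena = c(1.4, 1.4),
                                 grid_n = 70L)
  n_g <- nrow(rf$grid)
  f <- exp(rf$lnr[, 40]) # one neuron's 2D field
  # its peak repeats at the six hexagonal neighbours x0 + lam * (u1, u2, u2 - u1)
  g0 <- which.max(f * (rf$grid[, 1] > 0.3) * (rf$grid[, 1] < 0.7) *
                    (rf$grid[, 2] > 0.3) * (rf$grid[, 2] < 0.7))
  x0 <- rf$grid[g0, ]
  B <- hex_basis()
  offs <- list(B[, 1], B[, 2], B[, 2] - B[, 1])
  fval <- function(x) {
    gi <- which.min((rf$grid[, 1] - x[1])^2 + (rf$grid[, 2] - x[2])^2)
    f[gi]
  }
  for (o in offs) {
    for (sgn in c(-1, 1)) {
      x1 <- x0 + sgn * lam * o
      if (all(x1 > 0.05) && all(x1 < 1.35)) {
        expect_gt(fval(x1), 0.85 * f[g0])
        # midpoint between peaks is far below the peak
        expect_lt(fval(x0 + sgn * lam * o / 2), 0.7 * f[g0])
      }
    }
  }
})
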