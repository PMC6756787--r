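alpha200 <- function() gl_memo(
  "alpha200", calibrate_gain(net200(), T = 0.25))

test_that("the velocity gain is linear, odd and predictive", {
  fit <- alpha200()
  expect_gt(fit$r2, 0.999)
  # origin crossing, relative to the largest probed phase velocity
  expect_lt(abs(fit$intercept), 1e-3 * fit$alpha * 0.03)
  expect_gt(fit$alpha, 0)
  # odd symmetry of the underlying velocities
  d <- fit$data
  expect_equal(d$theta_dot[d$b == -0.015], -d$theta_dot[d$b == 0.015],
               tolerance = 1e-3)
  # an independent run at a new input level is predicted within 2%
  net <- net200(); base <- base200()
  bnew <- 0.022
  res <- gridlock:::integrate_modules(
    net, m = 1L, K = 1L, C = matrix(0, 1, 1), a = 1, beta = 1,
    S0 = matrix(base$s, ncol = 1), Bx = array(bnew, c(1, 1, 2000)),
    dt = 5e-4, nstep = 2000L, record_stride = 10L)
  th <- unwrap_phase(res$phase_a[, 1])
  n <- length(th); i0 <- ceiling(n / 4)
  disp <- th[n] - th[i0]
  pred <- fit$alpha * bnew * (res$t[n] - res$t[i0])
  expect_lt(abs(disp - pred) / pred, 0.02)
})

test_that("nonlinear input ranges are rejected by the linearity guard", {
  expect_error(calibrate_gain(net200(), b_levels = c(-3, -1.5, 0.75, 1.5, 3),
                              T = 0.15),
               "not linear")
})

test_that("the response tensor has the closed form and its two-module eigenvalues", {
  expect_equal(response_tensor(matrix(0, 3, 3), alpha = 2.5)$X,
               2.5 * diag(3))
  C <- standard_coupling(2)
  rt <- response_tensor(C, alpha = 1)
  expect_equal(rt$X_plus, 1, tolerance = 1e-12) # Cs + sqrt(C1 C2) = 0
  expect_equal(rt$X_plus / rt$X_minus, 41, tolerance = 1e-12)
  # X depends on the couplings only through Cs +/- sqrt(C12 C21)
  C2 <- rbind(c(-20, 20 / 2), c(20 * 2, -20)) # same product C12*C21
  rt2 <- response_tensor(C2, alpha = 1)
  expect_equal(rt2$X_plus, rt$X_plus, tolerance = 1e-12)
  expect_equal(rt2$X_minus, rt$X_minus, tolerance = 1e-12)
  # singular I - C
  expect_error(response_tensor(matrix(c(1, 0, 0, 0), 2)), "stability")
})

test_that("the stability screen follows the unit-eigenvalue criterion", {
  expect_true(check_stability(matrix(0, 2, 2))$stable)
  expect_false(check_stability(matrix(c(2, 0, 0, 0), 2))$stable)
  ev <- check_stability(standard_coupling(2))$values
  expect_equal(sort(Re(ev)), c(-40, 0), tolerance = 1e-10)
})

test_that("phase reduction integrates exactly without coupling and reaches X b when slow", {
  # C = 0: Euler reduction equals the cumulative sum of alpha * b
  alpha <- 3
  bfun <- function(t) c(0.05 * sin(2 * pi * t), -0.02)
  pr <- phase_reduction(matrix(0, 2, 2), alpha, bfun, dt = 1e-3, T = 1)
  B <- vapply((0:999) * 1e-3, bfun, numeric(2))
  oracle <- apply(alpha * t(B) * 1e-3, 2, cumsum)
  expect_equal(pr$theta[-1, ], oracle, tolerance = 1e-12)
  # slowly varying input: theta-dot converges to X b within 1% after 10 tau
  C <- standard_coupling(2)
  bconst <- c(0.01, 0.004)
  pr2 <- phase_reduction(C, alpha, function(t) bconst, dt = 2e-4, T = 0.3)
  n <- nrow(pr2$theta)
  thdot <- (pr2$theta[n, ] - pr2$theta[n - 200, ]) / (200 * 2e-4)
  pred <- as.vector(response_tensor(C, alpha)$X %*% bconst)
  expect_equal(thdot, pred, tolerance = 0.01)
})

test_that("reduction matches the closed-form response for random stable couplings", {
  set.seed(61)
  alpha <- 2
  for (rep in 1:5) {
    M <- matrix(rnorm(9, sd = 5), 3)
    C <- M - (max(Re(eigen(M)$values)) + 2) * diag(3)
    expect_true(check_stability(C)$stable)
    b <- rnorm(3, sd = 0.02)
    pr <- phase_reduction(C, alpha, function(t) b, dt = 2e-4, T = 0.4)
    n <- nrow(pr$theta)
    thdot <- (pr$theta[n, ] - pr$theta[n - 100, ]) / (100 * 2e-4)
    pred <- as.vector(response_tensor(C, alpha)$X %*% b)
    expect_equal(thdot, pred, tolerance = 5e-3)
  }
})

test_that("the full network follows the phase reduction under a smooth input", {
  sys <- sys200(standard_coupling(2))
  alpha <- alpha200()$alpha
  bfun <- function(t) c(0.015 * sin(pi * t), 0)
  T <- 2
  run <- run_coupled(sys, b = bfun, T = T, dt = 5e-4)
  pr <- phase_reduction(standard_coupling(2), alpha, bfun, dt = 2e-4, T = T)
  disp_net <- run$theta[nrow(run$theta), , 1] - run$theta[1, , 1]
  disp_red <- pr$theta[nrow(pr$theta), ] - pr$theta[1, ]
  expect_equal(disp_net, disp_red, tolerance = 0.03)
})

test_that("spacings follow the gains and the joint-motion vector is an eigenvector", {
  lam <- spacing_ratio()
  # uncoupled: gamma ratios (1, lam, lam^2) give spacing ratios lam each
  ps <- predicted_spacings(0.06 * lam^(0:2), matrix(0, 3, 3), alpha = 20)
  sp <- ps$spacings$spacing_m
  expect_equal(sp[1] / sp[2], lam, tolerance = 1e-12)
  expect_equal(sp[2] / sp[3], lam, tolerance = 1e-12)
  # coupled, input gains all equal: ratios still close to lam
  ps2 <- predicted_spacings(rep(0.06, 3), standard_coupling(3), alpha = 20)
  sp2 <- ps2$spacings$spacing_m
  expect_equal(sp2[1] / sp2[2], lam, tolerance = 0.05)
  expect_equal(sp2[2] / sp2[3], lam, tolerance = 0.05)
  expect_gt(ps2$u_alignment, 0.999)
  # coupled two modules, input to module 1 only: velocity ratio from X
  C <- standard_coupling(2)
  X <- response_tensor(C, 1)$X
  expect_equal(X[2, 1] / X[1, 1], 28.284 / 21, tolerance = 1e-3)
})

test_that("disconnecting a module increases its spacing and its neighbours'", {
  lam <- spacing_ratio()
  gamma <- 0.06 * lam^(0:2)
  C <- standard_coupling(3)
  for (rm in 1:3) {
    pred <- module_removal_prediction(C, gamma, alpha = 20, removed = rm)
    expect_gt(pred$delta[rm], 0)
    neigh <- intersect(c(rm - 1, rm + 1), 1:3)
    expect_true(all(pred$delta[neigh] > 0))
  }
  # matrix-inverse oracle: removing module 3 changes module 1 exactly as the
  # recomputed tensor dictates
  pred <- module_removal_prediction(C, gamma, alpha = 20, removed = 3)
  C2 <- C; C2[3, -3] <- 0; C2[-3, 3] <- 0
  X2 <- 20 * solve(diag(3) - C2)
  expect_equal(pred$after$spacing_m, as.vector(1 / (X2 %*% gamma)),
               tolerance = 1e-12)
})

test_that("suppression is anisotropic: relative input moves the system far less", {
  C <- standard_coupling(2)
  X <- response_tensor(C, 1)$X
  lam <- spacing_ratio()
  u <- c(1, lam) / sqrt(1 + lam^2)       # joint-motion eigenvector
  uperp <- c(1, -lam) / sqrt(1 + lam^2)  # relative-motion eigenvector
  gain_joint <- sqrt(sum((X %*% u)^2))
  gain_rel <- sqrt(sum((X %*% uperp)^2))
  expect_gt(gain_joint / gain_rel, 30)
})
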