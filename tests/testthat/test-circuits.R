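test_that("builtin models carry the reference parameters and shapes", {
  m <- builtin_model("iffl_ideal")
  expect_equal(m$parameters$rho1, 641.4)
  expect_equal(m$parameters$rho2, 585.1)
  expect_equal(m$parameters$rho3, 652.8)
  expect_equal(m$parameters$alpha1, 7.8)
  expect_equal(m$parameters$k1d, 200)
  expect_equal(m$parameters$kMu1, 4000)
  expect_equal(m$parameters$dm, 10)
  expect_equal(m$n, 6)
  expect_equal(m$p, 3)
  expect_equal(m$m, 3)

  m2 <- builtin_model("iffl_ideal", overrides = list(rho1 = 100))
  x <- c(1, 1, 1, 2, 1, 1); u <- c(1, 1, 1)
  f1 <- eval_field(m, x, u); f2 <- eval_field(m2, x, u)
  expect_equal(f2[1] - f1[1], (100 - 641.4) * 2)

  expect_error(builtin_model("nope"), "arg")
  expect_error(builtin_model("iffl_ideal", overrides = list(rho1 = -1)),
               "non-positive")
  expect_error(builtin_model("iffl_ideal", overrides = list(bogus = 1)),
               "unknown")
})

test_that("equilibrium finding: closed forms and residual/Hurwitz checks", {
  # linear system: x_e = -A^-1 B u
  lin <- dsfnet:::circuit_model(
    name = "lin", state_names = c("x1", "x2"), measured_indices = 1:2,
    input_names = "u1", parameters = list(k = 1),
    field_exprs = list(quote(-2 * x1 + x2 + u1), quote(x1 - 3 * x2)))
  op <- find_equilibrium(lin, 2, c(1, 1))
  A <- matrix(c(-2, 1, 1, -3), 2, 2, byrow = TRUE)
  expect_equal(op$x_e, as.numeric(solve(-A, c(2, 0))), tolerance = 1e-8)

  # zero input: the origin propagates down the cascade
  m <- builtin_model("iffl_ideal")
  op0 <- find_equilibrium(m, c(0, 0, 0), rep(0.01, 6))
  expect_lt(max(abs(op0$x_e)), 1e-6)

  # feasible positive input: small residual and Hurwitz Jacobian
  op1 <- find_equilibrium(m, c(1, 0.1, 1))
  expect_lt(op1$residual_norm, 1e-9 * max(1, max(abs(op1$x_e))))
  J <- dsfnet:::model_jacobian(m, op1$x_e, op1$u_e)$A
  expect_true(all(Re(eigen(J)$values) < 0))
})

test_that("linearization: exact on linear models, matches finite differences", {
  lin <- dsfnet:::circuit_model(
    name = "lin", state_names = c("x1", "x2"), measured_indices = 1L,
    input_names = "u1", parameters = list(k = 1),
    field_exprs = list(quote(-2 * x1 + 0.5 * x2 + u1), quote(x1 - 3 * x2)))
  sys <- suppressWarnings(linearize(lin, list(x_e = c(1, 1), u_e = 0)))
  expect_equal(sys$A11, matrix(-2))
  expect_equal(as.numeric(sys$A12), 0.5)
  expect_equal(as.numeric(sys$A22), -3)

  mc <- builtin_model("iffl_crosstalk")
  set.seed(2)
  x <- abs(rnorm(6, 10)); u <- c(1, 0.05, 1)
  Je <- dsfnet:::model_jacobian(mc, x, u, "exact")
  Jf <- dsfnet:::model_jacobian(mc, x, u, "fd")
  expect_equal(Je$A, Jf$A, tolerance = 1e-6)
  expect_equal(Je$B, Jf$B, tolerance = 1e-6)
})

test_that("event detector: derived Q12/Q21 match the symmetric closed forms", {
  set.seed(19)
  for (rep in 1:4) {
    kM <- runif(1, 100, 2000); k <- runif(1, 1, 10); rho <- runif(1, 1, 8)
    kl <- runif(1, 0.005, 0.05); dp <- runif(1, 0.05, 0.5); dm <- runif(1, 0.5, 3)
    m <- builtin_model("event_detector", overrides = list(
      hill = 1, kM2 = kM, kM3 = kM, kMu1 = kM, kMu2 = kM,
      k1 = k, k2 = k, k3 = k, k4 = k,
      rho1 = rho, rho2 = rho, rho3 = rho, rho4 = rho,
      kl = kl, dp = dp, dm = dm))
    x0 <- abs(rnorm(8, 2)); u0 <- runif(2, 1, 20)
    d <- suppressWarnings(dsf_from_lti(linearize(m, list(x_e = x0, u_e = u0))))
    den2 <- dsfnet:::poly_mul(c(1, dm), c(1, dp))
    # Q12: effect of x3 on x2 through the hidden m2, with the squared
    # promoter-occupancy denominator
    q12_ref <- rf(-k * rho * (kl + u0[1] / kM),
                  den2 * (kM * (u0[1] / kM + x0[3] / kM + 1)^2))
    q12 <- tm_entry(d$Q, 1, 2)
    expect_equal(q12$num, q12_ref$num, tolerance = 1e-8)
    expect_equal(q12$den, q12_ref$den, tolerance = 1e-8)
    q21_ref <- rf(-k * rho * (kl + u0[2] / kM),
                  den2 * (kM * (u0[2] / kM + x0[2] / kM + 1)^2))
    q21 <- tm_entry(d$Q, 2, 1)
    expect_equal(q21$num, q21_ref$num, tolerance = 1e-8)
    expect_equal(q21$den, q21_ref$den, tolerance = 1e-8)
    # P diagonal has denominator (dm + s)(dp + s)
    for (i in 1:2)
      expect_equal(tm_entry(d$P, i, i)$den, den2, tolerance = 1e-8)
  }
})

test_that("event detector defaults give two stable latched states", {
  m <- builtin_model("event_detector")
  # drive into each latched state, then relax at zero input
  u0 <- c(0, 0)
  opA <- find_equilibrium(m, u0, x_guess = c(1, 5, 0.1, 1, 1, 1, 0.1, 1))
  opB <- find_equilibrium(m, u0, x_guess = c(1, 0.1, 5, 1, 1, 0.1, 1, 1))
  expect_gt(abs(opA$x_e[2] - opB$x_e[2]), 1)
  for (op in list(opA, opB)) {
    J <- dsfnet:::model_jacobian(m, op$x_e, op$u_e)$A
    expect_true(all(Re(eigen(J)$values) < 0))
  }
  # the two states mirror each other: x2-dominant vs x3-dominant
  expect_gt(opA$x_e[2], opA$x_e[3])
  expect_gt(opB$x_e[3], opB$x_e[2])
})

test_that("simulation matches analytic and matrix-exponential solutions", {
  # equilibrium start with zero perturbation stays constant
  m <- builtin_model("iffl_ideal")
  op <- find_equilibrium(m, c(1, 0.1, 1), tol = 1e-12)
  tg <- seq(0, 200, by = 10)
  tr <- simulate_circuit(m, constant_schedule(op$u_e), op$x_e, tg)
  expect_lt(max(abs(sweep(tr$Y, 2, tr$Y[1, ]))), 1e-6)

  # scalar decay
  dec <- dsfnet:::circuit_model(
    name = "dec", state_names = "x1", measured_indices = 1L,
    input_names = "u1", parameters = list(k = 1),
    field_exprs = list(quote(-x1 + 0 * u1)))
  tg2 <- seq(0, 5, by = 0.1)
  tr2 <- simulate_circuit(dec, constant_schedule(0), 1, tg2)
  expect_equal(as.numeric(tr2$Y), exp(-tg2), tolerance = 1e-7)

  # 3-state linear step response vs matrix exponential
  A <- matrix(c(-1, 0.5, 0, 0, -2, 1, 0.3, 0, -1.5), 3, 3, byrow = TRUE)
  lin3 <- dsfnet:::circuit_model(
    name = "lin3", state_names = c("x1", "x2", "x3"), measured_indices = 1:3,
    input_names = "u1", parameters = list(k = 1),
    field_exprs = list(
      quote(-x1 + 0.5 * x2 + u1), quote(-2 * x2 + x3), quote(0.3 * x1 - 1.5 * x3)))
  tg3 <- seq(0, 4, by = 0.2)
  tr3 <- simulate_circuit(lin3, constant_schedule(1), c(0, 0, 0), tg3)
  B <- c(1, 0, 0)
  ref <- t(vapply(tg3, function(t) {
    as.numeric(solve(A, (as.matrix(Matrix::expm(A * t)) - diag(3)) %*% B))
  }, numeric(3)))
  expect_equal(unname(tr3$Y), ref, tolerance = 1e-6)
})

test_that("experiment generation: determinism, baselines, and noise calibration", {
  m <- builtin_model("iffl_ideal")
  design <- iffl_study_design()
  design$t_end <- 600

  # zero noise, zero amplitude: flat at baseline
  d0 <- design; d0$amplitudes <- c(0, 0, 0)
  s0 <- generate_experiments(m, d0, noise_sd = 0, seed = 1)
  for (tr in s0$trajectories)
    expect_lt(max(abs(sweep(tr$Y, 2, tr$Y[1, ]))), 1e-6)

  # same seed: bit-identical
  s1 <- generate_experiments(m, design, noise_sd = 0.01, seed = 42)
  s2 <- generate_experiments(m, design, noise_sd = 0.01, seed = 42)
  expect_identical(s1$trajectories[[1]]$Y, s2$trajectories[[1]]$Y)

  # 1% relative noise: pooled standardized residual SD within 10% of 1
  s3 <- generate_experiments(m, design, noise_sd = 0.01, seed = 7)
  z <- unlist(lapply(s3$trajectories, function(tr) {
    resid <- tr$Y - tr$Y_clean
    unlist(lapply(1:3, function(j) {
      if (tr$meta$noise_sd[j] > 0) resid[, j] / tr$meta$noise_sd[j]
    }))
  }))
  expect_lt(abs(stats::sd(z) - 1), 0.1)

  # ground truth is attached and has the designed support
  expect_s3_class(s1$truth, "dsf")
  expect_equal(unname(structure_report(s1$truth)$support), ideal_iffl_support())
})

test_that("crosstalk coupling makes every Q entry active at positive operating points", {
  mc <- builtin_model("iffl_crosstalk")
  grid <- list(c(0.3, 0.02, 1), c(0.5, 0.02, 1), c(0.8, 0.015, 1),
               c(1, 0.01, 1), c(1.5, 0.008, 1))
  for (u in grid) {
    op <- find_equilibrium(mc, u)
    expect_true(all(op$x_e > 0))
    d <- dsf_from_lti(linearize(mc, op))
    # all six off-diagonal entries are nonzero (threshold well below the
    # weakest loading-induced edge, which can sit ~1e-3 of the largest)
    expect_equal(sum(structure_report(d, tol = 1e-4)$support), 6)
  }
})
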