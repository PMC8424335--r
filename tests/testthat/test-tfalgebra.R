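test_that("transfer-function evaluation matches direct polynomial arithmetic", {
  expect_equal(tf_eval_rf(rf(5), 0.37 + 2i), 5)
  expect_equal(tf_eval_rf(rf(1, c(1, 2)), 0), 0.5)

  # independent power-sum oracle (not Horner)
  powsum <- function(p, s) sum(p * s^((length(p) - 1):0))
  set.seed(101)
  ent <- replicate(9, rf(rnorm(4), c(1, rnorm(3))), simplify = FALSE)
  M <- tfm(ent, 3, 3)
  for (k in 1:10) {
    s0 <- complex(real = rnorm(1), imaginary = rnorm(1))
    ref <- matrix(0 + 0i, 3, 3)
    for (i in 1:3) for (j in 1:3) {
      e <- tm_entry(M, i, j)
      ref[i, j] <- powsum(e$num, s0) / powsum(e$den, s0)
    }
    expect_equal(unname(tf_eval(M, s0)), ref, tolerance = 1e-12)
  }
})

test_that("evaluation at a pole is rejected with the offending entry named", {
  M <- tfm(list(rf(1, c(1, 2)), rf(1), rf(1), rf(1, c(1, 3))), 2, 2)
  expect_error(tf_eval(M, -2), "pole.*\\(1,1\\)")
})

test_that("evaluation distributes over rational sums and products", {
  set.seed(7)
  for (rep in 1:10) {
    a <- rf(rnorm(3), c(1, rnorm(2)))
    b <- rf(rnorm(2), c(1, rnorm(3)))
    s0 <- complex(real = runif(1, 0.5, 2), imaginary = rnorm(1))
    ea <- tf_eval_rf(a, s0); eb <- tf_eval_rf(b, s0)
    expect_equal(tf_eval_rf(a + b, s0), ea + eb, tolerance = 1e-10)
    expect_equal(tf_eval_rf(a * b, s0), ea * eb, tolerance = 1e-10)
  }
})

test_that("matrix inversion: identity, diagonal, and adjugate oracle", {
  I2 <- tm_identity(2)
  Ii <- tm_inverse(I2)
  expect_equal(unname(Mod(tf_eval(Ii, 1.3))), diag(2))

  D <- tfm(list(rf(1, c(1, 1)), rf(0), rf(0), rf(1, c(1, 4))), 2, 2)
  Di <- tm_inverse(D)
  expect_equal(tm_entry(Di, 1, 1)$num, c(1, 1))
  expect_equal(tm_entry(Di, 2, 2)$num, c(1, 4))

  # [[1, a/(s+1)], [b/(s+2), 1]]: inverse from the symbolic adjugate
  a <- 0.7; b <- -1.3
  M <- tfm(list(rf(1), rf(a, c(1, 1)), rf(b, c(1, 2)), rf(1)), 2, 2)
  Mi <- tm_inverse(M)
  set.seed(3)
  for (k in 1:10) {
    s0 <- complex(real = runif(1, 0.5, 3), imaginary = rnorm(1))
    det0 <- 1 - a * b / ((s0 + 1) * (s0 + 2))
    adj <- matrix(c(1, -a / (s0 + 1), -b / (s0 + 2), 1), 2, 2, byrow = TRUE)
    expect_equal(unname(tf_eval(Mi, s0)), adj / det0, tolerance = 1e-10)
  }
})

test_that("random transfer matrices invert to identity at sampled points", {
  set.seed(12)
  for (p in c(2, 3)) for (rep in 1:5) {
    ent <- replicate(p * p, rf(rnorm(2), c(1, abs(rnorm(1)) + 0.5, abs(rnorm(1)))),
                     simplify = FALSE)
    M <- tfm(ent, p, p)
    Mi <- tryCatch(tm_inverse(M), error = function(e) NULL)
    if (is.null(Mi)) next
    for (k in 1:10) {
      s0 <- complex(real = runif(1, 0.5, 2.5), imaginary = runif(1, 0.3, 2))
      E <- tf_eval(M, s0) %*% tf_eval(Mi, s0) - diag(p)
      expect_lt(max(Mod(E)), 1e-8)
    }
  }
})

test_that("singular transfer matrices are rejected", {
  M <- tfm(list(rf(1, c(1, 1)), rf(2, c(1, 1)),
                rf(2, c(1, 1)), rf(4, c(1, 1))), 2, 2)
  expect_error(tm_inverse(M), "singular")
})

test_that("impulse kernels reproduce closed forms for all pole types", {
  tg <- seq(0, 8, by = 0.01)
  # distinct real poles: K (e^{-at} - e^{-bt})/(b - a), i.e. the sinh form
  K <- 2.4; a <- 0.8; b <- 2.9
  k1 <- impulse_kernel(rf(K, dsfnet:::poly_mul(c(1, a), c(1, b))), tg)
  sinh_form <- (2 * K / (b - a)) * exp(-(a + b) * tg / 2) * sinh((b - a) * tg / 2)
  expect_lt(max(abs(k1 - sinh_form)), 1e-9)

  # repeated pole: t e^{-at}
  k2 <- impulse_kernel(rf(1, dsfnet:::poly_mul(c(1, 1.7), c(1, 1.7))), tg)
  expect_lt(max(abs(k2 - tg * exp(-1.7 * tg))), 1e-9)

  # complex pair: e^{-st} sin(wt) vs a state-space simulation oracle
  sg <- 0.5; w <- 3
  r3 <- rf(w, c(1, 2 * sg, sg^2 + w^2))
  k3 <- impulse_kernel(r3, tg)
  expect_lt(max(abs(k3 - exp(-sg * tg) * sin(w * tg))), 1e-9)
  A <- matrix(c(-2 * sg, -(sg^2 + w^2), 1, 0), 2, 2, byrow = TRUE)
  ode_oracle <- t(vapply(tg, function(t)
    (as.matrix(Matrix::expm(A * t)) %*% c(1, 0))[, 1], numeric(2)))[, 2] * w
  expect_lt(max(abs(k3 - ode_oracle)), 1e-6)
})

test_that("non-strictly-proper kernels are rejected", {
  expect_error(impulse_kernel(rf(c(1, 1), c(1, 2)), 0:5), "strictly proper")
})

test_that("kernels Laplace-transform back to the transfer function", {
  set.seed(21)
  for (rep in 1:5) {
    poles <- -runif(3, 0.3, 2)
    den <- dsfnet:::poly_mul(dsfnet:::poly_mul(c(1, -poles[1]), c(1, -poles[2])),
                             c(1, -poles[3]))
    x <- rf(rnorm(3), den)
    T_end <- 10 / min(abs(poles))
    tg <- seq(0, T_end, length.out = 4000)
    k <- impulse_kernel(x, tg)
    for (s in c(0.5, 1, 2, 3.5, 5)) {
      expect_equal(laplace_of_kernel(tg, k, s), tf_eval_rf(x, s),
                   tolerance = 1e-3)
    }
  }
})

test_that("H-infinity norm: closed forms and dense-sweep oracle", {
  expect_equal(hinf_norm(rf(3, c(1, 1.5))), 2, tolerance = 1e-9)
  expect_equal(hinf_norm(rf_zero()), 0)
  # resonant second-order: oracle is a brute-force 1e6-point sweep
  zeta <- 0.1
  x <- rf(1, c(1, 2 * zeta, 1))
  w <- 10^seq(-4, 4, length.out = 1e6)
  sweep_max <- max(Mod(dsfnet:::tf_eval_rf_raw(x, 1i * w)))
  expect_equal(hinf_norm(x), sweep_max, tolerance = 1e-4)
})

test_that("H-infinity norm bounds the DC gain and rejects unstable entries", {
  set.seed(5)
  for (rep in 1:10) {
    x <- rf(rnorm(2), c(1, abs(rnorm(1)) + 0.3, abs(rnorm(1)) + 0.05))
    if (!rf_stable(x)) next
    expect_gte(hinf_norm(x) + 1e-12, abs(tf_eval_rf(x, 0)))
  }
  expect_error(hinf_norm(rf(1, c(1, -1))), "unstable")
})

test_that("H2 norm: closed form, zero, and quadrature oracle", {
  a <- 1.7
  expect_equal(h2_norm(rf(1, c(1, a))), 1 / sqrt(2 * a), tolerance = 1e-12)
  expect_equal(h2_norm(rf_zero()), 0)
  set.seed(8)
  den <- Reduce(dsfnet:::poly_mul,
                list(c(1, 0.9), c(1, 2.2), c(1, 1.1, 2), 1))
  x <- rf(rnorm(3), den)
  quad <- sqrt(stats::integrate(function(w)
    Mod(dsfnet:::tf_eval_rf_raw(x, 1i * w))^2 / pi,
    0, Inf, rel.tol = 1e-10)$value)
  expect_equal(h2_norm(x), quad, tolerance = 1e-6)
  expect_error(h2_norm(rf(c(1, 0), c(1, 1))), "strictly proper")
})

test_that("minimal realization cancels common factors without altering values", {
  x <- rf(dsfnet:::poly_mul(c(1, 1), c(1, 3)),
          Reduce(dsfnet:::poly_mul, list(c(1, 1), c(1, 2), c(1, 3))))
  xs <- rf_simplify(x)
  expect_equal(xs$den, c(1, 2))
  # repeated factors
  y <- rf(dsfnet:::poly_mul(c(1, 1), c(1, 1)),
          Reduce(dsfnet:::poly_mul, list(c(1, 1), c(1, 1), c(1, 1), c(1, 2))))
  ys <- rf_simplify(y)
  expect_equal(ys$den, dsfnet:::poly_mul(c(1, 1), c(1, 2)))
  # values preserved for a non-cancelling function
  set.seed(9)
  z <- rf(rnorm(3), c(1, 2.5, 1.7, 0.4))
  zs <- rf_simplify(z)
  for (s in c(0.3 + 1i, 2 - 0.4i))
    expect_equal(tf_eval_rf(zs, s), tf_eval_rf(z, s), tolerance = 1e-9)
})

test_that("discretization round-trips and maps poles correctly", {
  # zoh round trip at dt well under the fastest time constant
  x <- rf(c(1, 0.3), dsfnet:::poly_mul(c(1, 1), c(1, 4)))
  for (dt in c(0.01, 0.02)) {
    rc <- rf_undiscretize(rf_discretize(x, dt, "zoh"), dt, "zoh")
    expect_equal(sort(Re(rf_poles(rc))), c(-4, -1), tolerance = 1e-6)
  }
  # discrete pole e^{-a dt} maps near s = -a under tustin as dt -> 0
  a <- 1; dt <- 1e-3
  zd <- rf(1 - exp(-a * dt), c(1, -exp(-a * dt)), var = "z")
  zc <- rf_undiscretize(zd, dt, "tustin")
  expect_equal(Re(rf_poles(zc)), -a, tolerance = 1e-3)
  # tustin singularity at z = -1
  bad <- rf(1, c(1, 1), var = "z")
  expect_error(rf_undiscretize(bad, 0.1, "tustin"), "z = -1")
})
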