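test_that("hybrid constants satisfy their defining identities", {
  p <- structural_params(ka = 1.5, v_f = 8, cl_f = 4, v2_f = 6, cl2_f = 2)
  h <- hybrid_constants(p)
  expect_equal(h$k10, 0.5)
  expect_equal(h$k12, 0.25)
  expect_equal(h$k21, 1 / 3)
  expect_equal(h$alpha + h$beta, 0.5 + 0.25 + 1 / 3, tolerance = 1e-12)
  expect_equal(h$alpha * h$beta, 0.5 * (1 / 3), tolerance = 1e-12)

  # polynomial-reconstruction property on random draws
  set.seed(41)
  for (i in 1:50) {
    pp <- random_params()
    hh <- hybrid_constants(pp)
    expect_gte(hh$alpha, hh$beta)
    expect_gt(hh$beta, 0)
    expect_equal(hh$alpha + hh$beta, hh$k10 + hh$k12 + hh$k21,
                 tolerance = 1e-10)
    expect_equal(hh$alpha * hh$beta, hh$k10 * hh$k21, tolerance = 1e-10)
  }
})

test_that("concentration: zero at dose time, superposition, dose linearity", {
  p <- structural_params(ka = 1.5, v_f = 8, cl_f = 4, v2_f = 6, cl2_f = 2)
  expect_equal(concentration(p, data.frame(time = 0, amt = 80), 0), 0)

  # superposition / time-shift invariance
  two <- concentration(p, data.frame(time = c(0, 12), amt = c(80, 80)), 15)
  one <- concentration(p, data.frame(time = 0, amt = 80), c(15, 3))
  expect_equal(two, sum(one), tolerance = 1e-12)

  # dose linearity and nonnegativity on random draws
  set.seed(42)
  for (i in 1:20) {
    pp <- random_params()
    t <- sort(stats::runif(8, 0, 72))
    c1 <- concentration(pp, data.frame(time = 0, amt = 80), t)
    c2 <- concentration(pp, data.frame(time = 0, amt = 160), t)
    expect_true(all(c1 >= 0))
    expect_equal(c2, 2 * c1, tolerance = 1e-12)
  }
})

test_that("closed form matches the matrix-exponential ODE oracle", {
  skip_if_not_installed("Matrix")
  # spot check at the worked-example parameters plus a handful of random sets
  # (the full 100-set sweep lives in test-acceptance.R)
  p <- structural_params(ka = 1.5, v_f = 8, cl_f = 4, v2_f = 6, cl2_f = 2)
  t <- c(0.25, 0.5, 1, 2, 4, 8, 16, 32)
  expect_equal(concentration(p, data.frame(time = 0, amt = 80), t),
               expm_conc_oracle(p, 80, t), tolerance = 1e-8)
  # and the oracle itself against RK4 integration at one point
  expect_equal(expm_conc_oracle(p, 80, 2), rk4_conc_oracle(p, 80, 2),
               tolerance = 1e-8)
  set.seed(43)
  for (i in 1:10) {
    pp <- random_params()
    tt <- sort(stats::runif(4, 0.25, 36))
    a <- concentration(pp, data.frame(time = 0, amt = 80), tt)
    b <- expm_conc_oracle(pp, 80, tt)
    expect_lt(max(abs(a - b) / pmax(abs(b), 1e-12)), 1e-6)
  }
})

test_that("near-zero inter-compartmental clearance degenerates to one compartment", {
  # with CL2/F -> 0 the model collapses to one-compartment first-order oral:
  # C(t) = D ka / (V (ka - k10)) (e^{-k10 t} - e^{-ka t})
  ka <- 1.2; v <- 10; cl <- 3
  p <- structural_params(ka = ka, v_f = v, cl_f = cl, v2_f = 6, cl2_f = 1e-10)
  k10 <- cl / v
  t <- c(0.5, 1, 2, 4, 8, 24)
  one_cmt <- 80 * ka / (v * (ka - k10)) * (exp(-k10 * t) - exp(-ka * t))
  expect_equal(concentration(p, data.frame(time = 0, amt = 80), t), one_cmt,
               tolerance = 1e-6)
})

test_that("ka degeneracy guard keeps the solution finite and accurate", {
  skip_if_not_installed("Matrix")
  p0 <- structural_params(ka = 1, v_f = 8, cl_f = 4, v2_f = 6, cl2_f = 2)
  h <- hybrid_constants(p0)
  p <- structural_params(ka = h$alpha, v_f = 8, cl_f = 4, v2_f = 6, cl2_f = 2)
  t <- c(0.5, 2, 8)
  got <- concentration(p, data.frame(time = 0, amt = 80), t)
  expect_true(all(is.finite(got)))
  expect_equal(got, expm_conc_oracle(p, 80, t), tolerance = 1e-4)
})

test_that("auc_infinity equals dose / CL/F and quadrature agrees", {
  p <- structural_params(ka = 1.5, v_f = 8, cl_f = 4, v2_f = 6, cl2_f = 2)
  expect_identical(auc_infinity(p, 80), 20)
  expect_identical(auc_infinity(p, 0), 0)
  q <- stats::integrate(function(t) concentration(p, data.frame(time = 0, amt = 80), t),
                        0, 2000, rel.tol = 1e-10, subdivisions = 2000L)
  expect_equal(q$value, 20, tolerance = 1e-4)
})

test_that("steady state: average identity, long-superposition oracle, proportionality", {
  p <- structural_params(ka = 1.5, v_f = 8, cl_f = 4, v2_f = 6, cl2_f = 2)
  grid <- seq(0, 24, by = 1)
  ss <- steady_state_profile(p, dose = 80, tau = 24, grid = grid)
  expect_equal(ss$c_avg_ss, 80 / (4 * 24))

  # brute-force superposition of 60 consecutive doses
  bf <- concentration(p, data.frame(time = seq(0, 59 * 24, by = 24), amt = 80),
                      59 * 24 + grid)
  expect_lt(max(abs(bf - ss$conc)), 1e-6)

  # doubling CL/F halves the average exactly
  p2 <- structural_params(ka = 1.5, v_f = 8, cl_f = 8, v2_f = 6, cl2_f = 2)
  expect_equal(steady_state_profile(p2, 80, 24, grid)$c_avg_ss, ss$c_avg_ss / 2)
})

test_that("invalid structural parameters are rejected", {
  expect_error(structural_params(ka = -1, v_f = 8, cl_f = 4, v2_f = 6, cl2_f = 2),
               "positive")
  expect_error(structural_params(ka = 1, v_f = 8, cl_f = Inf, v2_f = 6, cl2_f = 2))
})
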