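ref_model <- function(...) zaltoprofen_model(...)

test_that("individual parameters reduce to typical values at the medians", {
  m <- ref_model()
  p <- individual_params(m, crcl = 104.38, albumin = 4.90,
                         genotype = "*1/*1", eta = c(0, 0, 0))
  expect_equal(p$ka, m$typical$tv_ka)
  expect_equal(p$v_f, m$typical$tv_v_f)
  expect_equal(p$cl_f, m$typical$tv_cl_f)
  expect_equal(p$v2_f, m$typical$tv_v2_f)
  expect_equal(p$cl2_f, m$typical$tv_cl2_f)
})

test_that("covariate power laws and the genotype shift act multiplicatively", {
  m <- ref_model(d_cl_crcl = 1, d_cl_albumin = NULL)
  p <- individual_params(m, crcl = 2 * 104.38, albumin = 4.90)
  expect_equal(p$cl_f, 2 * m$typical$tv_cl_f, tolerance = 1e-12)

  # a -0.08 fractional shift multiplies CL/F by 0.92 for *1/*3 carriers
  mg <- ref_model(d_cl_crcl = NULL, d_cl_albumin = NULL,
                  d_cl_cyp2c9_13 = -0.08)
  p13 <- individual_params(mg, 104.38, 4.90, genotype = "*1/*3")
  expect_equal(p13$cl_f / mg$typical$tv_cl_f, 0.92, tolerance = 1e-12)
  p11 <- individual_params(mg, 104.38, 4.90, genotype = "*1/*1")
  expect_equal(p11$cl_f, mg$typical$tv_cl_f)
  # *3/*3 accepted but inert unless extrapolation is switched on
  p33 <- individual_params(mg, 104.38, 4.90, genotype = "*3/*3")
  expect_equal(p33$cl_f, mg$typical$tv_cl_f)
})

test_that("CL/F is monotone in CrCL (+) and albumin (-); exp(eta) keeps positivity", {
  m <- ref_model()  # d_crcl > 0, d_albumin < 0
  cr <- seq(60, 160, by = 10)
  cl_cr <- vapply(cr, function(x) individual_params(m, x, 4.9)$cl_f, 0)
  expect_true(all(diff(cl_cr) > 0))
  al <- seq(3.5, 5.5, by = 0.25)
  cl_al <- vapply(al, function(x) individual_params(m, 104.38, x)$cl_f, 0)
  expect_true(all(diff(cl_al) < 0))
  set.seed(5)
  for (i in 1:20) {
    p <- individual_params(m, 104.38, 4.9, eta = stats::rnorm(3, 0, 3))
    expect_true(all(unlist(p) > 0))
  }
  expect_error(individual_params(m, -10, 4.9), "positive")
})

test_that("residual_sd follows the variance model with a zero-prediction floor", {
  prop <- list(model = "proportional", sigma_prop = 0.1, sigma_add = 0)
  expect_equal(residual_sd(prop, 5), 0.5)
  expect_equal(residual_sd(prop, 0), 1e-10)  # floored, never exactly 0
  comb <- list(model = "combined", sigma_prop = 0.1, sigma_add = 0.05)
  expect_equal(residual_sd(comb, 2), sqrt(0.04 + 0.0025))
  expect_equal(residual_sd(comb, 2), 0.2061553, tolerance = 1e-6)
})

test_that("simulate_observations: noise-free limit, determinism, moments", {
  design <- tiny_dataset(dv = rep(0, 6))
  # sigma -> 0 and omega = 0 gives the deterministic profile
  m0 <- pop_model(typical = list(tv_ka = 1, tv_v_f = 15, tv_cl_f = 7.75,
                                 tv_v2_f = 30, tv_cl2_f = 5),
                  error = list(model = "proportional", sigma_prop = 1e-12))
  sim <- simulate_observations(m0, design, seed = 1)
  p <- individual_params(m0, 104.38, 4.9)
  expected <- concentration(p, data.frame(time = 0, amt = 80), c(1, 2, 4, 8, 12, 24))
  expect_equal(sim$dataset$dv[design$evid == 0], expected, tolerance = 1e-9)

  m <- ref_model()
  big <- do.call(rbind, lapply(1:4, function(k) {
    d <- tiny_dataset(times = 2, dv = 0, id = paste0("S", k)); d
  }))
  class(big) <- c("pk_dataset", "data.frame")
  s1 <- simulate_observations(m, big, seed = 7)
  s2 <- simulate_observations(m, big, seed = 7)
  expect_identical(s1$dataset, s2$dataset)
  s3 <- simulate_observations(m, big, seed = 8)
  expect_false(identical(s1$dataset$dv, s3$dataset$dv))

  # law of large numbers: 10,000 subjects, one timepoint, y/f centered on 1
  n <- 10000
  dd <- pk_dataset(id = rep(sprintf("S%05d", 1:n), each = 2),
                   time = rep(c(0, 2), n), evid = rep(c(1L, 0L), n),
                   amt = rep(c(80, NA), n), dv = rep(c(NA, 0), n),
                   crcl = 104.38, alb = 4.9, cyp2c9 = "*1/*1")
  mprop <- small_model(omega2_cl = 0, sigma_prop = 0.1)
  sim <- simulate_observations(mprop, dd, seed = 99)
  y <- sim$dataset$dv[dd$evid == 0]
  f <- concentration(individual_params(mprop, 104.38, 4.9),
                     data.frame(time = 0, amt = 80), 2)
  ratio <- y / f
  se <- 0.1 / sqrt(n)
  expect_lt(abs(mean(ratio) - 1), 3 * se)
  expect_equal(stats::sd(ratio), 0.1, tolerance = 0.03)
})

test_that("model JSON serialization round-trips", {
  m <- ref_model(d_cl_cyp2c9_13 = -0.08)
  f <- withr::local_tempfile(fileext = ".json")
  model_to_json(m, f)
  back <- model_from_json(f)
  expect_equal(unclass(back)[c("typical", "iiv", "error")],
               unclass(m)[c("typical", "iiv", "error")])
  expect_equal(back$covariates$d_cl_albumin, m$covariates$d_cl_albumin)
  expect_equal(back$covariates$d_cl_cyp2c9_13, -0.08)
})

test_that("percent CV conversions invert each other", {
  expect_equal(omega2_to_cv(cv_to_omega2(40.63)), 40.63, tolerance = 1e-10)
  expect_equal(cv_to_omega2(20), log(1.04), tolerance = 1e-12)
})

test_that("degenerate model specifications are rejected", {
  tv <- list(tv_ka = 1, tv_v_f = 15, tv_cl_f = 7.75, tv_v2_f = 30, tv_cl2_f = 5)
  expect_error(pop_model(typical = tv,
                         error = list(model = "proportional", sigma_prop = 0)),
               "sigma")
  expect_error(pop_model(typical = tv, iiv = list(omega2_cl = -0.1)), ">= 0")
  expect_error(pop_model(typical = tv,
                         covariates = list(d_cl_cyp2c9_13 = -1.5)), "cyp2c9")
})
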