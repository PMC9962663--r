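# The FOCE engine and fit/LRT/stepwise machinery.

test_that("FOCE objective is exact for the linear mixed model", {
  # y_ij = theta + eta_i + eps_ij is linear in eta with additive error, so
  # the Laplace/FOCE approximation must equal the closed-form Gaussian
  # marginal -2LL (normalization constants included)
  set.seed(11)
  for (rep in 1:5) {
    n <- 6; ni <- sample(2:5, n, replace = TRUE)
    theta <- stats::runif(1, 1, 10)
    om2 <- stats::runif(1, 0.1, 2)
    sig <- stats::runif(1, 0.2, 1)
    subj <- rep(seq_len(n), ni)
    y <- theta + rep(stats::rnorm(n, 0, sqrt(om2)), ni) +
      stats::rnorm(length(subj), 0, sig)
    pred_fun <- function(eta) theta + eta[subj, 1]
    err <- list(model = "additive", sigma_prop = 0, sigma_add = sig)
    for (interaction in c(TRUE, FALSE)) {
      got <- zaltopk:::.foce_core(y, subj, pred_fun, err,
                                  omega2 = c(om2, 0, 0),
                                  interaction = interaction)
      want <- gaussian_lmm_neg2ll(split(y, subj), theta, om2, sig^2)
      expect_equal(got$nll, want, tolerance = 1e-6)
    }
  }
})

test_that("Omega -> 0 reduces to extended least squares at eta = 0", {
  set.seed(12)
  coh <- generate_cohort(cohort_config(n_subjects = 8, seed = 21))
  m <- coh$config$true_model
  m$iiv <- list(omega2_cl = 0, omega2_v2 = 0, omega2_ka = 0)
  got <- foce_objective(m, coh$dataset)
  # direct computation at eta = 0
  pre <- zaltopk:::.precompute_design(coh$dataset)
  f0 <- zaltopk:::.pred_from_pre(m, pre, matrix(0, pre$n_subj, 3), full = FALSE)
  g0 <- residual_sd(m$error, f0)
  want <- sum((pre$y - f0)^2 / g0^2 + log(g0^2) + log(2 * pi))
  expect_equal(got$neg2ll, want, tolerance = 1e-10)
  expect_true(all(got$eta_hat == 0))
})

test_that("compiled and reference FOCE engines agree", {
  coh <- generate_cohort(cohort_config(n_subjects = 12, seed = 31))
  m <- coh$config$true_model
  pre <- zaltopk:::.precompute_design(coh$dataset)
  for (interaction in c(TRUE, FALSE)) {
    a <- zaltopk:::.foce_pre(m, pre, interaction = interaction, engine = "cpp")
    b <- zaltopk:::.foce_pre(m, pre, interaction = interaction, engine = "r")
    expect_equal(a$nll, b$nll, tolerance = 1e-6)
    expect_lt(max(abs(a$eta - b$eta)), 1e-5)
  }
})

test_that("analytic prediction gradients match finite differences", {
  coh <- generate_cohort(cohort_config(n_subjects = 10, seed = 32))
  m <- coh$config$true_model
  pre <- zaltopk:::.precompute_design(coh$dataset)
  set.seed(1)
  eta <- matrix(stats::rnorm(10 * 3, 0, 0.3), 10, 3)
  p <- zaltopk:::.individual_params_vec(m, pre$crcl, pre$alb, pre$geno, eta)
  fg <- zaltopk:::.conc_pairs_grad_cpp(pre$pair_u, pre$pair_amt, pre$pair_subj0,
                                       pre$pair_obs0, pre$n_obs,
                                       p$ka, p$v_f, p$cl_f, p$v2_f, p$cl2_f)
  pf <- function(e) zaltopk:::.pred_from_pre(m, pre, e, full = FALSE)
  expect_equal(fg$f, pf(eta), tolerance = 1e-12)
  h <- 1e-6
  for (k in 1:3) {
    ep <- eta; ep[, k] <- ep[, k] + h
    em <- eta; em[, k] <- em[, k] - h
    fd <- (pf(ep) - pf(em)) / (2 * h)
    expect_lt(max(abs(fg$G[, k] - fd) / pmax(abs(fd), 1e-6)), 1e-4)
  }
})

test_that("a covariate exponent fixed at 0 leaves the objective unchanged", {
  coh <- generate_cohort(cohort_config(n_subjects = 8, seed = 22))
  m0 <- zaltoprofen_model(d_cl_crcl = NULL, d_cl_albumin = NULL)
  m1 <- zaltoprofen_model(d_cl_crcl = 0, d_cl_albumin = NULL)
  expect_equal(foce_objective(m0, coh$dataset)$neg2ll,
               foce_objective(m1, coh$dataset)$neg2ll, tolerance = 1e-10)
})

test_that("objective is invariant to a time-unit rescale with matching parameters", {
  coh <- generate_cohort(cohort_config(n_subjects = 10, seed = 23))
  m <- coh$config$true_model
  d2 <- coh$dataset
  d2$time <- d2$time / 24  # hours -> days
  m2 <- m
  m2$typical$tv_ka <- m$typical$tv_ka * 24
  m2$typical$tv_cl_f <- m$typical$tv_cl_f * 24
  m2$typical$tv_cl2_f <- m$typical$tv_cl2_f * 24
  expect_equal(foce_objective(m2, d2)$neg2ll, foce_objective(m, coh$dataset)$neg2ll,
               tolerance = 1e-6)
})

test_that("likelihood ratio test matches the chi-square reference points", {
  mk <- function(nll) list(neg2ll = nll)
  expect_equal(likelihood_ratio_test(mk(10), mk(10))$p_value, 1)
  lrt <- likelihood_ratio_test(mk(10), mk(13.841), df = 1)
  expect_equal(round(lrt$p_value, 4), 0.05)
  lrt <- likelihood_ratio_test(mk(10), mk(16.635), df = 1)
  expect_equal(round(lrt$p_value, 4), 0.01)
  neg <- likelihood_ratio_test(mk(12), mk(10), df = 1)
  expect_true(neg$warning)
  expect_equal(neg$p_value, 1)
})

test_that("fit recovers structural parameters from near-noiseless data", {
  # omega = 0 (no IIV), tiny residual error: fixed effects only
  # sigma -> tiny: the MLE sits on a shallow ka-V/F ridge whose displacement
  # from truth scales with sigma, so 1e-4 keeps all parameters within 0.1%
  truth <- pop_model(typical = list(tv_ka = 1.2, tv_v_f = 14, tv_cl_f = 7,
                                    tv_v2_f = 28, tv_cl2_f = 4.5),
                     error = list(model = "proportional", sigma_prop = 1e-4))
  cfg <- cohort_config(n_subjects = 26, true_model = truth, seed = 77)
  coh <- generate_cohort(cfg)
  start <- truth
  start$typical <- lapply(truth$typical, function(x) x * 1.25)
  f <- fit(start, coh$dataset, fixed = "sigma_prop",
           options = list(compute_se = FALSE))
  expect_true(f$convergence)
  for (nm in names(truth$typical)) {
    expect_equal(f$model_hat$typical[[nm]], truth$typical[[nm]],
                 tolerance = 1e-3)
  }
  expect_equal(f$aic, f$neg2ll + 2 * f$n_param)
})

test_that("fit reports RSEs from the observed information", {
  coh <- generate_cohort(cohort_config(n_subjects = 26, seed = 41))
  f <- fit(coh$config$true_model, coh$dataset)
  expect_true(f$convergence)
  expect_true(all(is.finite(f$rse[c("tv_cl_f", "sigma_prop")])))
  expect_lt(f$rse[["tv_cl_f"]], 30)  # precision comparable to the study's
  expect_equal(f$aic, f$neg2ll + 2 * f$n_param)
  # eta_hat shrinks toward zero relative to the simulated etas
  expect_equal(dim(f$eta_hat), c(26L, 3L))
})

test_that("stepwise: empty candidate set returns the base model untouched", {
  coh <- generate_cohort(cohort_config(n_subjects = 8, seed = 51))
  base <- small_model()
  sw <- stepwise_covariate_search(base, coh$dataset, character(),
                                  options = list(compute_se = FALSE))
  expect_equal(sw$final, base)
  expect_equal(nrow(sw$trace), 0L)
})

test_that("stepwise with alpha_forward = 0 admits nothing", {
  coh <- generate_cohort(cohort_config(n_subjects = 10, seed = 52))
  base <- zaltoprofen_model(d_cl_crcl = NULL, d_cl_albumin = NULL)
  sw <- stepwise_covariate_search(base, coh$dataset, c("crcl", "albumin"),
                                  alpha_forward = 0,
                                  options = list(compute_se = FALSE,
                                                 rel_tol = 1e-3))
  expect_false(zaltopk:::.has_covariate(sw$final, "crcl"))
  expect_false(zaltopk:::.has_covariate(sw$final, "albumin"))
  expect_true(all(sw$trace$decision == "not added"))
})
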