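test_that("NCA on an exact mono-exponential recovers lambda_z and half-life", {
  t <- seq(2, 48, by = 2)
  conc <- 10 * exp(-0.1 * t)
  r <- nca_parameters(c(0, t), c(0, conc), dose = 80)
  expect_equal(r$lambda_z, 0.100, tolerance = 1e-8)
  expect_equal(r$t_half, log(2) / 0.1, tolerance = 1e-8)
  expect_equal(r$t_half, 6.931, tolerance = 1e-3)
  # identities to machine precision
  expect_equal(r$cl_f_nca, 80 / r$auc_inf, tolerance = 1e-12)
  expect_equal(r$vz_f_nca, r$cl_f_nca / r$lambda_z, tolerance = 1e-12)
  expect_gte(r$auc_inf, r$auc_last)
})

test_that("linear trapezoid arithmetic and collinear-point invariance", {
  r <- nca_parameters(c(0, 1, 2), c(0, 2, 1), dose = 10)
  expect_equal(r$auc_last, 2.5)
  expect_true(is.na(r$lambda_z))  # too few terminal points: extrapolation NA
  expect_equal(r$cmax, 2)
  expect_equal(r$tmax, 1)

  # inserting a collinear midpoint leaves AUC_last unchanged
  t <- c(0, 1, 2, 4, 8, 12)
  cc <- c(0, 4, 3, 2.2, 1.1, 0.4)
  a1 <- nca_parameters(t, cc, 80)$auc_last
  t2 <- sort(c(t, 3)); c2 <- approx(t, cc, xout = t2)$y
  a2 <- nca_parameters(t2, c2, 80)$auc_last
  expect_equal(a1, a2, tolerance = 1e-12)
})

test_that("terminal-phase regression maximizes adjusted R^2 and handles flat tails", {
  # bi-exponential: the last points are dominated by the slow phase
  t <- c(0.5, 1, 2, 3, 4, 6, 8, 12, 16, 24, 36, 48)
  cc <- 5 * exp(-0.5 * t) + 2 * exp(-0.08 * t)
  r <- nca_parameters(c(0, t), c(0, cc), 80)
  expect_gt(r$lambda_z, 0.07)
  expect_lt(r$lambda_z, 0.12)
  # rising profile: no negative slope estimable
  r2 <- nca_parameters(c(0, 1, 2, 4, 8), c(0, 1, 2, 3, 4), 80)
  expect_true(is.na(r2$lambda_z))
  expect_true(is.na(r2$auc_inf))
})

test_that("NCA clearance approximates model clearance with long sampling", {
  p <- structural_params(ka = 1.2, v_f = 15, cl_f = 7.75, v2_f = 30, cl2_f = 5)
  h <- hybrid_constants(p)
  t_half_term <- log(2) / h$beta
  t <- sort(unique(c(0.25, 0.5, 1, 2, 4, 8, seq(12, ceiling(8 * t_half_term), by = 6))))
  cc <- concentration(p, data.frame(time = 0, amt = 80), t)
  r <- nca_parameters(c(0, t), c(0, cc), 80)
  expect_equal(r$cl_f_nca, p$cl_f, tolerance = 0.05)
  expect_equal(r$auc_inf, auc_infinity(p, 80), tolerance = 0.05)
})

test_that("covariate screening flags exact and null relationships correctly", {
  set.seed(71)
  n <- 500
  cl <- exp(stats::rnorm(n, 2, 0.3))
  tab <- data.frame(cmax = stats::runif(n), tmax = stats::runif(n),
                    auc_inf = 80 / cl, t_half = stats::runif(n),
                    cl_f_nca = cl, vz_f_nca = stats::runif(n))
  covs <- data.frame(exact = cl, noise = stats::rnorm(n), const = rep(1, n))
  sc <- screen_covariates(tab, covs, threshold = 0.30)
  expect_equal(sc$r[sc$covariate == "exact" & sc$parameter == "cl_f_nca"], 1)
  expect_true(sc$selected[sc$covariate == "exact" & sc$parameter == "cl_f_nca"])
  expect_true(all(abs(sc$r[sc$covariate == "noise"]) < 0.15))
  expect_false(any(sc$selected[sc$covariate == "noise"]))
  expect_false("const" %in% sc$covariate)
  expect_match(attr(sc, "notes"), "const")
  # r2 scale: r = 1 still selected, |r| = 0.4 not selected at 0.30 r2
  sc2 <- screen_covariates(tab, covs["exact"], threshold = 0.30, scale = "r2")
  expect_true(sc2$selected[sc2$parameter == "cl_f_nca"])
})

test_that("screening recovers the signs of the generating covariate effects", {
  coh <- generate_cohort(cohort_config(n_subjects = 100, seed = 72))
  tab <- nca_dataset(coh$dataset)
  sc <- screen_covariates(tab)
  r_crcl <- sc$r[sc$covariate == "crcl" & sc$parameter == "cl_f_nca"]
  r_alb <- sc$r[sc$covariate == "alb" & sc$parameter == "cl_f_nca"]
  expect_gt(r_crcl, 0)   # positive CrCL-CL/F correlation
  expect_lt(r_alb, 0)    # negative albumin-CL/F correlation
  expect_true(sc$selected[sc$covariate == "crcl" & sc$parameter == "cl_f_nca"])
})

test_that("genotype group comparison: identical, separated, and null cases", {
  tab <- data.frame(t_half = rep(6, 8), tmax = rep(1, 8), cmax = rep(2, 8),
                    auc_inf = rep(10, 8), vz_f_nca = rep(50, 8),
                    cl_f_nca = rep(8, 8))
  g <- rep(c("*1/*1", "*1/*3"), each = 4)
  cmp <- compare_genotype_groups(tab, g)
  expect_true(all(cmp$p_wilcox >= 0.99 | is.na(cmp$p_wilcox)))
  expect_false(any(cmp$flag))

  # Tmax shifted +1 h in the small group, nothing else differs
  set.seed(73)
  n1 <- 22; n2 <- 4
  mk <- function(n, shift = 0) data.frame(
    t_half = stats::rnorm(n, 6, 0.5), tmax = stats::rnorm(n, 1 + shift, 0.1),
    cmax = stats::rnorm(n, 2, 0.2), auc_inf = stats::rnorm(n, 10, 1),
    vz_f_nca = stats::rnorm(n, 50, 5), cl_f_nca = stats::rnorm(n, 8, 0.8))
  tab2 <- rbind(mk(n1), mk(n2, shift = 1))
  g2 <- c(rep("*1/*1", n1), rep("*1/*3", n2))
  cmp2 <- compare_genotype_groups(tab2, g2)
  expect_true(cmp2$flag[cmp2$parameter == "tmax"])
  expect_false(any(cmp2$flag[cmp2$parameter != "tmax"]))

  # type-I error calibration under the null across 100 draws
  flags <- vapply(1:100, function(s) {
    set.seed(200 + s)
    tabn <- rbind(mk(n1), mk(n2))
    any(compare_genotype_groups(tabn, g2, parameters = "cl_f_nca")$flag)
  }, TRUE)
  expect_lt(mean(flags), 0.12)  # ~ alpha = 0.05 within binomial error

  # descriptive-only when a group has n < 2
  cmp3 <- compare_genotype_groups(tab2[c(1:22, 23), ], g2[c(1:22, 23)])
  expect_true(all(is.na(cmp3$p_wilcox)))
})
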