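# Residual diagnostics, bootstrap, VPC, NPDE.

test_that("without IIV, CWRES degenerates to simple weighted residuals", {
  truth <- pop_model(typical = list(tv_ka = 1, tv_v_f = 15, tv_cl_f = 7.75,
                                    tv_v2_f = 30, tv_cl2_f = 5),
                     error = list(model = "additive", sigma_add = 0.05))
  coh <- generate_cohort(cohort_config(n_subjects = 6, true_model = truth,
                                       seed = 61))
  o <- foce_objective(truth, coh$dataset)
  fake_fit <- list(eta_hat = o$eta_hat, model_hat = truth)
  rd <- residual_diagnostics(fake_fit, coh$dataset, model = truth)
  obs <- coh$dataset[coh$dataset$evid == 0, ]
  expect_equal(rd$cwres, (obs$dv - rd$pred) / 0.05, tolerance = 1e-10)
  expect_equal(rd$ipred, rd$pred)  # no etas
})

test_that("IWRES vanish on an exactly noise-free dataset at the true etas", {
  m <- zaltoprofen_model()
  coh <- generate_cohort(cohort_config(n_subjects = 6, seed = 62))
  d <- coh$dataset
  eta <- as.matrix(coh$truth[, c("eta_cl", "eta_v2", "eta_ka")])
  rownames(eta) <- coh$truth$id
  d$dv[d$evid == 0] <- zaltopk:::.population_pred(m, d, eta = eta)[d$evid == 0]
  fake_fit <- list(eta_hat = eta, model_hat = m)
  rd <- residual_diagnostics(fake_fit, d, model = m)
  expect_lt(max(abs(rd$iwres)), 1e-8)
  expect_false(any(rd$flag))
})

test_that("CWRES are calibrated under the true model", {
  m <- zaltoprofen_model()
  coh <- generate_cohort(cohort_config(n_subjects = 100, seed = 63))
  o <- foce_objective(m, coh$dataset)
  rd <- residual_diagnostics(list(eta_hat = o$eta_hat, model_hat = m),
                             coh$dataset, model = m)
  expect_gt(mean(rd$cwres), -0.1)
  expect_lt(mean(rd$cwres), 0.1)
  expect_gt(stats::var(rd$cwres), 0.8)
  expect_lt(stats::var(rd$cwres), 1.2)
  expect_lt(mean(abs(rd$cwres) > 4), 0.001)
})

test_that("bootstrap of a single-subject dataset is degenerate", {
  truth <- small_model()
  coh <- generate_cohort(cohort_config(n_subjects = 1,
                                       genotype_counts = c("*1/*1" = 1L),
                                       true_model = truth, seed = 64))
  bs <- bootstrap(truth, coh$dataset, B = 3, seed = 1,
                  fixed = c("tv_ka", "tv_v_f", "tv_v2_f", "tv_cl2_f"),
                  options = list(rel_tol = 1e-3))
  expect_equal(unname(bs$ci_upper - bs$ci_lower),
               rep(0, ncol(bs$replicates)), tolerance = 1e-6)
  expect_equal(bs$median, bs$estimate[colnames(bs$replicates)],
               tolerance = 1e-6)
})

test_that("VPC: percentile ordering, dose equivariance, empty-bin merge", {
  m <- zaltoprofen_model()
  coh <- generate_cohort(cohort_config(n_subjects = 20, seed = 65))
  v <- vpc(m, coh$dataset, M = 50, seed = 9)
  expect_true(all(v$bins$sim_p5_med <= v$bins$sim_p50_med + 1e-12))
  expect_true(all(v$bins$sim_p50_med <= v$bins$sim_p95_med + 1e-12))

  # doubling every dose scales all bands exactly x2 (same seeds)
  d2 <- coh$dataset
  d2$amt[d2$evid == 1] <- 2 * d2$amt[d2$evid == 1]
  v2 <- vpc(m, d2, M = 50, seed = 9)
  for (col in grep("^sim_", names(v$bins), value = TRUE)) {
    expect_equal(v2$bins[[col]], 2 * v$bins[[col]], tolerance = 1e-10)
  }

  # a bin grid with an empty interior bin merges with a warning
  expect_warning(vpc(m, coh$dataset, M = 10, seed = 9,
                     bins = c(0, 10, 15, 20, 50)), "merged")
})

test_that("VPC external overlay mode reports band coverage of a mean profile", {
  m <- zaltoprofen_model()
  design <- generate_cohort(cohort_config(n_subjects = 20, seed = 66))$dataset
  # an external 'digitized' profile: the model-typical curve, well inside bands
  p <- individual_params(m, 104.38, 4.9)
  tt <- c(0.5, 1, 2, 4, 8, 12, 24)
  overlay <- data.frame(time = tt,
                        dv = concentration(p, data.frame(time = 0, amt = 80), tt))
  v <- vpc(m, design, observations = overlay, M = 100, seed = 10)
  expect_true(v$overlay)
  expect_gt(v$coverage, 0.9)
})

test_that("NPDE: exact pd at the simulated median and at the clamp boundary", {
  m <- small_model()
  d <- tiny_dataset(times = 4, dv = 1)
  K <- 40
  sims <- vapply(seq_len(K), function(r)
    simulate_observations(m, d, seed = 100 + r)$dataset$dv[2], 0)
  # observation just above the K/2-th order statistic -> pd = 1/2 -> npde = 0
  d$dv[2] <- sort(sims)[K / 2] + 1e-9
  r <- npde(m, d, K = K, seed = 100)
  expect_equal(r$table$pd, 0.5)
  expect_equal(r$table$npde, 0)
  # observation above every simulation -> clamped at 1 - 1/(2K)
  d$dv[2] <- max(sims) + 1
  r2 <- npde(m, d, K = K, seed = 100)
  expect_equal(r2$table$pd, 1 - 1 / (2 * K))
})
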