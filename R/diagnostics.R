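# Model qualification tools: residual tables, nonparametric bootstrap,
# visual predictive check, normalized prediction distribution errors.

#' Goodness-of-fit residual table (PRED/IPRED/IWRES/CWRES)
#'
#' Population predictions (`pred`, at eta = 0), individual predictions
#' (`ipred`, at the conditional modes), individual weighted residuals
#' `iwres = (y - ipred) / residual_sd(ipred)`, and conditional weighted
#' residuals from the FOCE linearization at eta_hat:
#' `E_i = f_i(eta_hat) - G_i eta_hat`,
#' `Cov_i = G_i Omega G_i' + diag(residual_sd(ipred)^2)`,
#' `cwres_i = L_i^-1 (y_i - E_i)` with `L_i` the lower Cholesky factor of
#' `Cov_i` and `G_i = df/deta` at `eta_hat` (central finite differences).
#' Values with `|cwres| > 4` are flagged.
#'
#' @param fit a `pk_fit` (its `eta_hat` is used).
#' @param dataset the dataset that was fitted.
#' @param model the model at which to evaluate; defaults to `fit$model_hat`.
#' @return A data frame with one row per observation: `id`, `time`, `dv`,
#'   `pred`, `ipred`, `iwres`, `cwres`, `flag`; the eta matrix is attached as
#'   attribute `"eta_hat"`.
#' @export
residual_diagnostics <- function(fit, dataset, model = fit$model_hat) {
  pre <- .precompute_design(dataset)
  eta <- fit$eta_hat[pre$ids, , drop = FALSE]
  omega2 <- c(model$iiv$omega2_cl, model$iiv$omega2_v2, model$iiv$omega2_ka)
  act <- which(omega2 > 0)
  pred_fun <- function(e) .pred_from_pre(model, pre, e, full = FALSE)

  f0 <- pred_fun(matrix(0, pre$n_subj, 3))
  fhat <- pred_fun(eta)
  g_ind <- residual_sd(model$error, fhat)
  iwres <- (pre$y - fhat) / g_ind

  cwres <- numeric(pre$n_obs)
  if (length(act) == 0) {
    cwres <- (pre$y - f0) / residual_sd(model$error, f0)
  } else {
    h <- 1e-4
    G <- matrix(0, pre$n_obs, length(act))
    for (k in seq_along(act)) {
      ep <- eta; ep[, act[k]] <- ep[, act[k]] + h * pmax(abs(ep[, act[k]]), 1)
      em <- eta; em[, act[k]] <- em[, act[k]] - h * pmax(abs(em[, act[k]]), 1)
      step <- ep[, act[k]] - em[, act[k]]
      G[, k] <- (pred_fun(ep) - pred_fun(em)) / step[pre$obs_subj]
    }
    for (i in seq_len(pre$n_subj)) {
      rows <- which(pre$obs_subj == i)
      Gi <- G[rows, , drop = FALSE]
      Ei <- fhat[rows] - as.numeric(Gi %*% eta[i, act])
      Cov <- Gi %*% (omega2[act] * t(Gi)) + diag(g_ind[rows]^2, length(rows))
      L <- tryCatch(chol(Cov), error = function(e) NULL)
      if (is.null(L)) {
        L <- tryCatch(chol(Cov + diag(1e-10, nrow(Cov))), error = function(e)
          stop("CWRES covariance not positive definite for subject ", pre$ids[i]))
      }
      cwres[rows] <- backsolve(L, pre$y[rows] - Ei, transpose = TRUE)
    }
  }
  out <- data.frame(id = pre$ids[pre$obs_subj],
                    time = dataset$time[pre$obs_rows],
                    dv = pre$y, pred = f0, ipred = fhat,
                    iwres = iwres, cwres = cwres,
                    flag = abs(cwres) > 4,
                    stringsAsFactors = FALSE)
  attr(out, "eta_hat") <- eta
  out
}

#' Nonparametric bootstrap of a population-PK fit
#'
#' `B` replicates of subject-level resampling with replacement (original
#' cohort size), each refit by [fit()]; non-converged replicates are dropped
#' and counted. Deterministic given `seed`.
#'
#' @param model a [pop_model()] with the starting/structure values; each
#'   replicate is warm-started at `start` (default: a fit of the original
#'   dataset).
#' @param dataset a validated `pk_dataset`.
#' @param B number of replicates (the reference analysis used 1000; tests
#'   use a scaled-down 200).
#' @param seed integer seed.
#' @param start optional `pk_fit` providing the warm start and the point
#'   estimates reported alongside.
#' @param fixed parameter names held at their `model` values (passed to
#'   [fit()]).
#' @param options passed to [fit()] (`compute_se` is forced off for speed).
#' @return An object of class `pk_bootstrap`: `replicates` (matrix B_conv x
#'   parameters), `median`, `ci_lower`, `ci_upper` (2.5/97.5 percentiles),
#'   `estimate` (point estimates), `n_converged`, `B`.
#' @export
bootstrap <- function(model, dataset, B = 200L, seed = 1L, start = NULL,
                      fixed = character(), options = list()) {
  stopifnot(B >= 1)
  options$compute_se <- FALSE
  if (is.null(start)) start <- fit(model, dataset, fixed = fixed,
                                   options = options)
  start_model <- .set_model_values(model, start)
  ids <- unique(dataset$id)
  rows_by_id <- split(seq_len(nrow(dataset)), factor(dataset$id, levels = ids))
  set.seed(seed)
  reps <- vector("list", B)
  n_conv <- 0L
  for (b in seq_len(B)) {
    take <- sample(length(ids), length(ids), replace = TRUE)
    pieces <- lapply(seq_along(take), function(k) {
      d <- dataset[rows_by_id[[take[k]]], , drop = FALSE]
      d$id <- sprintf("B%03d", k)
      d
    })
    dd <- do.call(rbind, pieces)
    class(dd) <- c("pk_dataset", "data.frame")
    fb <- tryCatch(fit(start_model, dd, fixed = fixed, options = options),
                   error = function(e) NULL)
    if (!is.null(fb) && fb$convergence) {
      n_conv <- n_conv + 1L
      reps[[b]] <- fb$estimates
    }
  }
  reps <- do.call(rbind, reps[!vapply(reps, is.null, TRUE)])
  if (is.null(reps)) stop("no bootstrap replicate converged")
  structure(list(
    replicates = reps,
    median = apply(reps, 2, stats::median),
    ci_lower = apply(reps, 2, stats::quantile, probs = 0.025),
    ci_upper = apply(reps, 2, stats::quantile, probs = 0.975),
    estimate = start$estimates,
    n_converged = n_conv, B = B), class = "pk_bootstrap")
}

#' @export
print.pk_bootstrap <- function(x, ...) {
  cat(sprintf("Nonparametric bootstrap: %d/%d replicates converged\n",
              x$n_converged, x$B))
  print(data.frame(estimate = signif(x$estimate[colnames(x$replicates)], 4),
                   median = signif(x$median, 4),
                   ci2.5 = signif(x$ci_lower, 4),
                   ci97.5 = signif(x$ci_upper, 4)))
  invisible(x)
}

#' Visual predictive check
#'
#' Simulates `M` replicate datasets on the design (same subjects, dose events
#' and sampling times; covariates as observed), computes the 5th/50th/95th
#' percentile of the simulated concentrations per time bin in each replicate,
#' and reports the 95% confidence band of each percentile across replicates
#' together with the observed percentiles. Coverage is the fraction of
#' observations inside the pointwise simulated 90% prediction interval at
#' their own design point. An external digitized mean profile (data frame
#' with `time`, `dv`) can be supplied as `observations` for overlay
#' validation after changing dose/interval in the design.
#'
#' @param model a [pop_model()].
#' @param design a `pk_dataset` giving subjects, doses and sampling times.
#' @param observations observed data: a `pk_dataset` (default: the design
#'   itself, if it carries `dv`) or an external overlay data frame with
#'   columns `time` and `dv`.
#' @param M number of simulation replicates (>= 100 recommended).
#' @param bins numeric vector of bin edges; default: the design's unique
#'   nominal observation times (one bin per time).
#' @param seed integer seed; replicate r uses stream `seed + r`.
#' @param probs percentiles to track.
#' @return An object of class `pk_vpc`: `bins` (data frame with per-bin
#'   observed percentiles and simulated bands), `coverage`, `M`, `overlay`
#'   (logical), `n_obs`.
#' @export
vpc <- function(model, design, observations = NULL, M = 200L, bins = NULL,
                seed = 1L, probs = c(0.05, 0.5, 0.95)) {
  stopifnot(M >= 1)
  overlay <- !is.null(observations) && !inherits(observations, "pk_dataset")
  obs_rows <- design$evid == 0L
  t_obs <- design$time[obs_rows]
  if (is.null(bins)) {
    edges <- sort(unique(t_obs))
    bin_of <- match(t_obs, edges)
    bin_mid <- edges
  } else {
    bin_of <- findInterval(t_obs, bins, rightmost.closed = TRUE)
    keep <- bin_of >= 1 & bin_of <= length(bins) - 1
    # merge out-of-range points into edge bins rather than dropping
    bin_of[t_obs < bins[1]] <- 1L
    bin_of[t_obs > bins[length(bins)]] <- length(bins) - 1L
    bin_mid <- (bins[-1] + bins[-length(bins)]) / 2
    # merge empty bins with their left neighbour
    counts <- tabulate(bin_of, length(bin_mid))
    if (any(counts == 0)) {
      warning("empty VPC bin(s) merged with neighbour")
      nonempty <- which(counts > 0)
      # merge each empty bin into the nearest non-empty bin to its left
      # (leading empty bins merge right)
      bin_of <- pmax(findInterval(bin_of, nonempty), 1L)
      bin_mid <- bin_mid[nonempty]
    }
  }
  nb <- length(bin_mid)
  qs <- array(NA_real_, c(M, nb, length(probs)))
  simvals <- matrix(NA_real_, M, length(t_obs))
  for (r in seq_len(M)) {
    s <- simulate_observations(model, design, seed = seed + r)
    yv <- s$dataset$dv[obs_rows]
    simvals[r, ] <- yv
    for (b in seq_len(nb)) {
      qs[r, b, ] <- stats::quantile(yv[bin_of == b], probs = probs, names = FALSE)
    }
  }
  band <- function(p_idx, q) apply(qs[, , p_idx, drop = FALSE], 2, stats::quantile,
                                   probs = q, names = FALSE)
  bins_df <- data.frame(time = bin_mid)
  for (k in seq_along(probs)) {
    nm <- paste0("p", round(100 * probs[k]))
    bins_df[[paste0("sim_", nm, "_lo")]] <- band(k, 0.025)
    bins_df[[paste0("sim_", nm, "_med")]] <- band(k, 0.5)
    bins_df[[paste0("sim_", nm, "_hi")]] <- band(k, 0.975)
  }
  coverage <- NA_real_
  n_obs_used <- 0L
  if (overlay) {
    # external mean profile: fraction of overlay points inside the simulated
    # 5th-95th percentile band of their (nearest) bin
    ob <- observations
    bidx <- vapply(ob$time, function(tt) which.min(abs(bin_mid - tt)), 1L)
    lo <- bins_df[[paste0("sim_p", round(100 * probs[1]), "_lo")]][bidx]
    hi <- bins_df[[paste0("sim_p", round(100 * probs[length(probs)]), "_hi")]][bidx]
    coverage <- mean(ob$dv >= lo & ob$dv <= hi)
    n_obs_used <- nrow(ob)
    for (k in seq_along(probs)) {
      nm <- paste0("obs_p", round(100 * probs[k]))
      bins_df[[nm]] <- NA_real_
    }
  } else {
    y <- if (!is.null(observations)) observations$dv[observations$evid == 0L]
         else design$dv[obs_rows]
    if (!all(is.na(y))) {
      for (k in seq_along(probs)) {
        nm <- paste0("obs_p", round(100 * probs[k]))
        bins_df[[nm]] <- vapply(seq_len(nb), function(b)
          stats::quantile(y[bin_of == b], probs = probs[k], names = FALSE), 0)
      }
      # pointwise 90% simulated interval at each design point
      lo <- apply(simvals, 2, stats::quantile, probs = 0.05)
      hi <- apply(simvals, 2, stats::quantile, probs = 0.95)
      coverage <- mean(y >= lo & y <= hi)
      n_obs_used <- length(y)
    }
  }
  structure(list(bins = bins_df, coverage = coverage, M = M,
                 probs = probs, overlay = overlay, n_obs = n_obs_used),
            class = "pk_vpc")
}

#' @export
print.pk_vpc <- function(x, ...) {
  cat(sprintf("VPC: %d replicates, %d bins, %s observations; coverage of the 90%% interval: %s\n",
              x$M, nrow(x$bins), x$n_obs,
              if (is.na(x$coverage)) "n/a" else sprintf("%.3f", x$coverage)))
  invisible(x)
}

#' Normalized prediction distribution errors
#'
#' Simulates `K` replicates of every subject's observation vector, decorrelates
#' both the observed and the simulated vectors with the empirical mean and
#' lower-triangular Cholesky factor of the empirical covariance across
#' replicates, and computes `pd = P(sim* < obs*)` (clamped to
#' `[1/(2K), 1 - 1/(2K)]`) and `npde = qnorm(pd)`. Global adequacy tests:
#' t test for mean zero, chi-square test for unit variance, Shapiro-Wilk for
#' normality.
#'
#' @param model a [pop_model()].
#' @param dataset observed `pk_dataset`.
#' @param K number of simulation replicates (>= 1000 recommended).
#' @param seed integer seed.
#' @return An object of class `pk_npde`: data frame `table` (id, time, pd,
#'   npde), `mean`, `var`, `p_mean` (t test), `p_var` (chi-square), `p_normal`
#'   (Shapiro-Wilk on at most 5000 values).
#' @export
npde <- function(model, dataset, K = 1000L, seed = 1L) {
  stopifnot(K >= 1)
  pre <- .precompute_design(dataset)
  sims <- matrix(NA_real_, K, pre$n_obs)
  for (r in seq_len(K)) {
    s <- simulate_observations(model, dataset, seed = seed + r)
    sims[r, ] <- s$dataset$dv[dataset$evid == 0L]
  }
  pd <- numeric(pre$n_obs)
  for (i in seq_len(pre$n_subj)) {
    rows <- which(pre$obs_subj == i)
    Si <- sims[, rows, drop = FALSE]
    mu <- colMeans(Si)
    V <- stats::cov(Si)
    L <- tryCatch(chol(V), error = function(e) {
      warning("singular empirical covariance; ridged by 1e-8")
      chol(V + diag(1e-8 * mean(diag(V)) + 1e-12, nrow(V)))
    })
    ystar <- backsolve(L, pre$y[rows] - mu, transpose = TRUE)
    sstar <- backsolve(L, t(Si) - mu, transpose = TRUE)
    pd[rows] <- rowMeans(sstar < ystar)
  }
  pd <- pmin(pmax(pd, 1 / (2 * K)), 1 - 1 / (2 * K))
  z <- stats::qnorm(pd)
  nz <- length(z)
  p_mean <- if (nz >= 2) stats::t.test(z, mu = 0)$p.value else NA_real_
  v <- if (nz >= 2) stats::var(z) else NA_real_
  chi <- (nz - 1) * v
  p_var <- if (nz >= 2) {
    2 * min(stats::pchisq(chi, nz - 1), stats::pchisq(chi, nz - 1, lower.tail = FALSE))
  } else NA_real_
  p_normal <- if (nz >= 3) {
    stats::shapiro.test(if (nz > 5000) sample(z, 5000) else z)$p.value
  } else NA_real_
  structure(list(table = data.frame(id = pre$ids[pre$obs_subj],
                                    time = dataset$time[pre$obs_rows],
                                    pd = pd, npde = z,
                                    stringsAsFactors = FALSE),
                 mean = mean(z), var = v,
                 p_mean = p_mean, p_var = p_var, p_normal = p_normal,
                 K = K), class = "pk_npde")
}

#' @export
print.pk_npde <- function(x, ...) {
  cat(sprintf("NPDE (K = %d): mean %.3f (p = %.3f), variance %.3f (p = %.3f), normality p = %.3f\n",
              x$K, x$mean, x$p_mean, x$var, x$p_var, x$p_normal))
  invisible(x)
}
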