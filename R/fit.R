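# Parameter packing: typical values and variance parameters are estimated on
# the log scale (positivity), covariate effects on the identity scale.

.par_table <- function(model) {
  co <- model$covariates
  err <- model$error
  rows <- list(
    list(name = "tv_ka", value = model$typical$tv_ka, log = TRUE),
    list(name = "tv_v_f", value = model$typical$tv_v_f, log = TRUE),
    list(name = "tv_cl_f", value = model$typical$tv_cl_f, log = TRUE),
    list(name = "tv_v2_f", value = model$typical$tv_v2_f, log = TRUE),
    list(name = "tv_cl2_f", value = model$typical$tv_cl2_f, log = TRUE))
  if (!is.null(co$d_cl_crcl)) {
    rows <- c(rows, list(list(name = "d_cl_crcl", value = co$d_cl_crcl, log = FALSE)))
  }
  if (!is.null(co$d_cl_albumin)) {
    rows <- c(rows, list(list(name = "d_cl_albumin", value = co$d_cl_albumin, log = FALSE)))
  }
  if (!is.null(co$d_cl_cyp2c9_13)) {
    rows <- c(rows, list(list(name = "d_cl_cyp2c9_13", value = co$d_cl_cyp2c9_13, log = FALSE)))
  }
  for (nm in c("omega2_cl", "omega2_v2", "omega2_ka")) {
    if (model$iiv[[nm]] > 0) {
      rows <- c(rows, list(list(name = nm, value = model$iiv[[nm]], log = TRUE)))
    }
  }
  if (err$model %in% c("proportional", "combined") && err$sigma_prop > 0) {
    rows <- c(rows, list(list(name = "sigma_prop", value = err$sigma_prop, log = TRUE)))
  }
  if (err$model %in% c("additive", "combined") && err$sigma_add > 0) {
    rows <- c(rows, list(list(name = "sigma_add", value = err$sigma_add, log = TRUE)))
  }
  data.frame(name = vapply(rows, `[[`, "", "name"),
             value = vapply(rows, `[[`, 0, "value"),
             log = vapply(rows, `[[`, TRUE, "log"),
             stringsAsFactors = FALSE)
}

.pack <- function(tab) {
  out <- tab$value
  out[tab$log] <- log(out[tab$log])
  out
}

.unpack_model <- function(model, tab, par) {
  vals <- ifelse(tab$log, exp(par), par)
  names(vals) <- tab$name
  m <- model
  for (nm in tab$name) {
    v <- unname(vals[[nm]])
    if (nm %in% names(m$typical)) m$typical[[nm]] <- v
    else if (nm %in% c("d_cl_crcl", "d_cl_albumin", "d_cl_cyp2c9_13")) m$covariates[[nm]] <- v
    else if (nm %in% names(m$iiv)) m$iiv[[nm]] <- v
    else m$error[[nm]] <- v
  }
  m
}

# central-difference Hessian of fn at par (relative step)
.fd_hessian <- function(fn, par, rel_step = 1e-4) {
  p <- length(par)
  h <- rel_step * pmax(abs(par), 1)
  H <- matrix(NA_real_, p, p)
  f0 <- fn(par)
  for (i in seq_len(p)) {
    for (j in i:p) {
      if (i == j) {
        pp <- par; pp[i] <- par[i] + h[i]; fp <- fn(pp)
        pm <- par; pm[i] <- par[i] - h[i]; fm <- fn(pm)
        H[i, i] <- (fp - 2 * f0 + fm) / h[i]^2
      } else {
        s <- c(1, 1, -1, -1); t <- c(1, -1, 1, -1); val <- 0
        for (k in 1:4) {
          pp <- par
          pp[i] <- par[i] + s[k] * h[i]
          pp[j] <- par[j] + t[k] * h[j]
          val <- val + s[k] * t[k] * fn(pp)
        }
        H[i, j] <- H[j, i] <- val / (4 * h[i] * h[j])
      }
    }
  }
  H
}

#' Fit a population-PK model by FOCE
#'
#' Minimizes [foce_objective()] over the unmasked parameters (typical values
#' and variance components on the log scale, covariate effects on the
#' identity scale) with `stats::nlminb`. Standard errors come from the
#' inverse of a central-finite-difference observed-information matrix;
#' non-convergence returns the best-so-far fit flagged
#' `convergence = FALSE`, never an error.
#'
#' @param model0 a [pop_model()] holding the initial values; its structure
#'   (which covariate terms, IIV terms and error components are present)
#'   defines what is estimated.
#' @param dataset a validated `pk_dataset`.
#' @param fixed character vector of parameter names to hold at their
#'   `model0` values (e.g. `"d_cl_crcl"`, `"omega2_ka"`, `"sigma_prop"`).
#' @param options list: `interaction` (default `TRUE`), `compute_se`
#'   (default `TRUE`), `iter_max` (default 300), `rel_tol` (outer objective
#'   tolerance, default 1e-6).
#' @return An object of class `pk_fit`: `model_hat`, `estimates` (natural
#'   scale), `neg2ll`, `aic` (`= neg2ll + 2 p`), `n_param`, `se`, `rse` (%),
#'   `eta_hat`, `convergence`, `message`.
#' @export
fit <- function(model0, dataset, fixed = character(), options = list()) {
  opt <- utils::modifyList(list(interaction = TRUE, compute_se = TRUE,
                                iter_max = 300L, rel_tol = 1e-6), options)
  validate_pk_dataset(dataset, strict = FALSE)
  pre <- .precompute_design(dataset)
  tab <- .par_table(model0)
  est_idx <- which(!tab$name %in% fixed)
  if (length(setdiff(fixed, tab$name)) > 0) {
    stop("unknown parameter in `fixed`: ",
         paste(setdiff(fixed, tab$name), collapse = ", "))
  }
  par0 <- .pack(tab)

  state <- new.env(parent = emptyenv())
  state$eta <- NULL
  state$best <- Inf
  state$best_par <- par0[est_idx]

  objective <- function(par_est) {
    par <- par0
    par[est_idx] <- par_est
    m <- tryCatch(.unpack_model(model0, tab, par), error = function(e) NULL)
    if (is.null(m)) return(1e10)
    res <- tryCatch(
      .foce_pre(m, pre, interaction = opt$interaction, eta_start = state$eta),
      error = function(e) NULL)
    if (is.null(res) || !is.finite(res$nll)) return(1e10)
    state$eta <- res$eta
    if (res$nll < state$best) {
      state$best <- res$nll
      state$best_par <- par_est
    }
    res$nll
  }

  conv <- FALSE
  msg <- ""
  if (length(est_idx) > 0) {
    ctrl <- list(iter.max = opt$iter_max, eval.max = 10 * opt$iter_max,
                 rel.tol = opt$rel_tol * 1e-2)
    # explicit central-difference gradient: PORT's internal forward
    # differences stall ("false convergence") when a parameter sits at 0,
    # exactly the warm start of a newly added covariate term
    gradient <- function(p) {
      g <- numeric(length(p))
      for (i in seq_along(p)) {
        h <- 1e-5 * max(abs(p[i]), 1)
        ep <- p; ep[i] <- p[i] + h
        em <- p; em[i] <- p[i] - h
        g[i] <- (objective(ep) - objective(em)) / (2 * h)
      }
      g
    }
    run <- function(p) tryCatch(
      stats::nlminb(p, objective, gradient = gradient, control = ctrl),
      error = function(e) list(par = p, objective = Inf, convergence = 1L,
                               message = conditionMessage(e)))
    ans <- run(par0[est_idx])
    conv <- identical(ans$convergence, 0L)
    msg <- ans$message %||% ""
    if (!conv && is.finite(ans$objective)) {
      # nlminb's "false convergence" is frequently a start at (or next to)
      # the optimum; restart once and accept if no further progress is made
      ans2 <- run(ans$par)
      if (is.finite(ans2$objective)) {
        conv <- identical(ans2$convergence, 0L) ||
          abs(ans2$objective - ans$objective) < 1e-3
        msg <- paste0(ans2$message %||% "", " (after restart)")
        if (ans2$objective <= ans$objective) ans <- ans2
      }
    }
    par_hat <- if (is.finite(state$best) && state$best <= (ans$objective %||% Inf)) {
      state$best_par
    } else ans$par
  } else {
    par_hat <- numeric(0)
    conv <- TRUE
    msg <- "nothing estimated"
  }

  par_full <- par0
  par_full[est_idx] <- par_hat
  model_hat <- .unpack_model(model0, tab, par_full)
  final <- .foce_pre(model_hat, pre, interaction = opt$interaction,
                     eta_start = state$eta)
  eta <- final$eta
  colnames(eta) <- c("eta_cl", "eta_v2", "eta_ka")
  rownames(eta) <- pre$ids

  tab_hat <- .par_table(model_hat)
  estimates <- stats::setNames(tab_hat$value, tab_hat$name)
  p <- length(est_idx)

  se <- rse <- stats::setNames(rep(NA_real_, nrow(tab)), tab$name)
  if (opt$compute_se && p > 0) {
    H <- tryCatch(.fd_hessian(objective, par_hat), error = function(e) NULL)
    if (!is.null(H) && all(is.finite(H))) {
      cov <- tryCatch(2 * solve(H), error = function(e) NULL)
      if (!is.null(cov)) {
        v <- diag(cov)
        v[v <= 0] <- NA_real_  # non-PD information: RSE reported missing
        se_t <- sqrt(v)        # SE on the packed scale
        nm <- tab$name[est_idx]
        is_log <- tab$log[est_idx]
        se[nm] <- ifelse(is_log, estimates[nm] * se_t, se_t)
        rse[nm] <- ifelse(is_log, 100 * se_t,
                          100 * se_t / abs(estimates[nm]))
      }
    }
  }

  structure(list(model_hat = model_hat, estimates = estimates,
                 neg2ll = final$nll, aic = final$nll + 2 * p, n_param = p,
                 se = se, rse = rse, eta_hat = eta,
                 convergence = conv, message = msg,
                 fixed = fixed, interaction = opt$interaction),
            class = "pk_fit")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.pk_fit <- function(x, ...) {
  cat(sprintf("FOCE fit: -2LL = %.3f, AIC = %.3f (%d estimated parameters)%s\n",
              x$neg2ll, x$aic, x$n_param,
              if (x$convergence) "" else "  [NOT CONVERGED]"))
  tab <- data.frame(estimate = signif(x$estimates, 5),
                    `RSE%` = signif(x$rse, 3), check.names = FALSE)
  print(tab)
  invisible(x)
}

#' Likelihood-ratio test between nested fits
#'
#' `delta = neg2ll(reduced) - neg2ll(full)` compared against a chi-square
#' distribution with `df` degrees of freedom. A negative delta (optimizer
#' noise) returns `p = 1` with a warning flag.
#'
#' @param fit_full,fit_reduced `pk_fit` objects (or lists with `neg2ll`),
#'   reduced nested in full.
#' @param df degrees of freedom (>= 1).
#' @return list `delta`, `p_value`, `warning` (TRUE when delta < 0).
#' @export
likelihood_ratio_test <- function(fit_full, fit_reduced, df = 1L) {
  stopifnot(df >= 1)
  delta <- fit_reduced$neg2ll - fit_full$neg2ll
  if (delta < 0) {
    return(list(delta = delta, p_value = 1, warning = TRUE))
  }
  list(delta = delta,
       p_value = stats::pchisq(delta, df = df, lower.tail = FALSE),
       warning = FALSE)
}

# --- stepwise covariate selection --------------------------------------------

.cov_field <- c(crcl = "d_cl_crcl", albumin = "d_cl_albumin",
                cyp2c9 = "d_cl_cyp2c9_13")

.add_covariate <- function(model, term, init = 0) {
  model$covariates[[.cov_field[[term]]]] <- init
  model
}

.drop_covariate <- function(model, term) {
  model$covariates[.cov_field[[term]]] <- list(NULL)
  model
}

.has_covariate <- function(model, term) {
  !is.null(model$covariates[[.cov_field[[term]]]])
}

#' Stepwise covariate search (forward addition, backward elimination)
#'
#' Forward: at each round every remaining candidate is added (one at a time,
#' 1 df) to the current model, refit, and scored by the likelihood-ratio
#' drop; the candidate with the largest significant drop (`p < alpha_forward`,
#' ties broken by declaration order) enters. Backward: starting from the
#' forward model, the least significant included term with
#' `p >= alpha_backward` is removed, iterating to stability. Every decision
#' is recorded in the trace.
#'
#' @param base a [pop_model()] without the candidate terms.
#' @param dataset a validated `pk_dataset`.
#' @param candidates character vector out of `"crcl"`, `"albumin"`,
#'   `"cyp2c9"` (all effects act on CL/F).
#' @param alpha_forward forward inclusion level (default 0.05).
#' @param alpha_backward backward retention level (default 0.01).
#' @param options passed to [fit()].
#' @return list `final` (the selected [pop_model()]), `fit` (its `pk_fit`),
#'   and `trace` (a data frame: candidate, direction, delta_neg2ll, df,
#'   p_value, decision).
#' @export
stepwise_covariate_search <- function(base, dataset, candidates,
                                      alpha_forward = 0.05,
                                      alpha_backward = 0.01,
                                      options = list()) {
  stopifnot(all(candidates %in% names(.cov_field)))
  trace <- list()
  note <- function(cand, dir, delta, p, dec) {
    trace[[length(trace) + 1]] <<- data.frame(
      candidate = cand, direction = dir, delta_neg2ll = delta, df = 1L,
      p_value = p, decision = dec, stringsAsFactors = FALSE)
  }
  current <- base
  current_fit <- fit(current, dataset, options = options)
  if (length(candidates) > 0) {
    # forward addition
    repeat {
      remaining <- candidates[!vapply(candidates, .has_covariate,
                                      TRUE, model = current)]
      if (length(remaining) == 0) break
      fits <- list(); pvals <- numeric(0); deltas <- numeric(0)
      for (cand in remaining) {
        m <- .add_covariate(.set_model_values(current, current_fit), cand)
        f <- fit(m, dataset, options = options)
        lrt <- likelihood_ratio_test(f, current_fit, df = 1L)
        fits[[cand]] <- f
        pvals[cand] <- lrt$p_value
        deltas[cand] <- lrt$delta
      }
      ok <- pvals < alpha_forward
      if (!any(ok)) {
        for (cand in remaining) note(cand, "forward", deltas[cand], pvals[cand],
                                     "not added")
        break
      }
      best <- remaining[ok][which.min(pvals[remaining[ok]])]
      for (cand in remaining) {
        note(cand, "forward", deltas[cand], pvals[cand],
             if (cand == best) "added" else "not added this round")
      }
      current <- fits[[best]]$model_hat
      current_fit <- fits[[best]]
    }
    # backward elimination
    repeat {
      included <- candidates[vapply(candidates, .has_covariate,
                                    TRUE, model = current)]
      if (length(included) == 0) break
      pvals <- numeric(0); deltas <- numeric(0); fits <- list()
      for (term in included) {
        m <- .drop_covariate(.set_model_values(current, current_fit), term)
        f <- fit(m, dataset, options = options)
        lrt <- likelihood_ratio_test(current_fit, f, df = 1L)
        fits[[term]] <- f
        pvals[term] <- lrt$p_value
        deltas[term] <- lrt$delta
      }
      removable <- included[pvals[included] >= alpha_backward]
      if (length(removable) == 0) {
        for (term in included) note(term, "backward", deltas[term],
                                    pvals[term], "retained")
        break
      }
      worst <- removable[which.max(pvals[removable])]
      note(worst, "backward", deltas[worst], pvals[worst], "removed")
      current <- fits[[worst]]$model_hat
      current_fit <- fits[[worst]]
    }
  }
  list(final = current, fit = current_fit,
       trace = if (length(trace)) do.call(rbind, trace)
               else data.frame(candidate = character(), direction = character(),
                               delta_neg2ll = numeric(), df = integer(),
                               p_value = numeric(), decision = character(),
                               stringsAsFactors = FALSE))
}

# warm start: copy a fit's estimates into a model skeleton
.set_model_values <- function(model, fit_obj) {
  tab <- .par_table(fit_obj$model_hat)
  .unpack_model(model, tab[tab$name %in% .par_table(model)$name, , drop = FALSE],
                .pack(tab[tab$name %in% .par_table(model)$name, , drop = FALSE]))
}
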