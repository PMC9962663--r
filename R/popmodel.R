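#' Hierarchical population-PK model
#'
#' Bundles the four components of the hierarchical model:
#'
#' * `typical`: typical values `tv_ka` (1/h), `tv_v_f` (L), `tv_cl_f` (L/h),
#'   `tv_v2_f` (L), `tv_cl2_f` (L/h).
#' * `covariates`: effects on CL/F. Power terms
#'   `(CrCL/m_crcl)^d_cl_crcl` and `(Albumin/m_albumin)^d_cl_albumin`
#'   centered at the medians `m_crcl` (mL/min) and `m_albumin` (g/dL), and an
#'   optional linear fractional shift `1 + d_cl_cyp2c9_13` for carriers of
#'   CYP2C9 *1/*3.  Set an exponent to `NULL` to exclude the term.
#' * `iiv`: diagonal log-normal inter-individual variability variances
#'   `omega2_cl`, `omega2_v2`, `omega2_ka` (variances of eta; a value of 0
#'   removes the random effect).
#' * `error`: residual error spec, `model` one of `"proportional"`,
#'   `"additive"`, `"combined"`, with `sigma_prop` (CV, dimensionless) and
#'   `sigma_add` (ug/mL).
#'
#' @param typical named list of typical values (see above).
#' @param covariates named list of covariate effects; defaults to no effects
#'   with centering medians 104.38 mL/min and 4.90 g/dL.
#' @param iiv named list of eta variances; defaults to all 0.
#' @param error residual error spec; defaults to 10% proportional error.
#' @return An object of class `pop_model`.
#' @examples
#' m <- pop_model(
#'   typical = list(tv_ka = 1, tv_v_f = 15, tv_cl_f = 7.75, tv_v2_f = 30,
#'                  tv_cl2_f = 5),
#'   covariates = list(d_cl_crcl = 0.75, d_cl_albumin = -2.1,
#'                     m_crcl = 104.38, m_albumin = 4.90),
#'   iiv = list(omega2_cl = 0.04, omega2_v2 = 0.2, omega2_ka = 0.15),
#'   error = list(model = "proportional", sigma_prop = 0.1, sigma_add = 0))
#' individual_params(m, crcl = 104.38, albumin = 4.90, genotype = "*1/*1",
#'                   eta = c(0, 0, 0))
#' @export
pop_model <- function(typical,
                      covariates = list(),
                      iiv = list(),
                      error = list(model = "proportional", sigma_prop = 0.1,
                                   sigma_add = 0)) {
  tv <- utils::modifyList(
    list(tv_ka = NULL, tv_v_f = NULL, tv_cl_f = NULL, tv_v2_f = NULL,
         tv_cl2_f = NULL), typical)
  if (any(vapply(tv, is.null, TRUE))) stop("all five typical values must be given")
  if (any(unlist(tv) <= 0)) stop("typical values must be strictly positive")
  cov <- utils::modifyList(
    list(d_cl_crcl = NULL, d_cl_albumin = NULL, d_cl_cyp2c9_13 = NULL,
         m_crcl = 104.38, m_albumin = 4.90, cyp2c9_33_extrapolate = FALSE),
    covariates)
  if (cov$m_crcl <= 0 || cov$m_albumin <= 0) stop("centering medians must be > 0")
  if (!is.null(cov$d_cl_cyp2c9_13) && 1 + cov$d_cl_cyp2c9_13 <= 0) {
    stop("1 + d_cl_cyp2c9_13 must be > 0")
  }
  om <- utils::modifyList(list(omega2_cl = 0, omega2_v2 = 0, omega2_ka = 0), iiv)
  if (any(unlist(om) < 0)) stop("IIV variances must be >= 0")
  err <- utils::modifyList(
    list(model = "proportional", sigma_prop = 0, sigma_add = 0), error)
  err$model <- match.arg(err$model, c("proportional", "additive", "combined"))
  if (err$model == "proportional") err$sigma_add <- 0
  if (err$model == "additive") err$sigma_prop <- 0
  if (err$sigma_prop <= 0 && err$sigma_add <= 0) {
    stop("at least one residual error sigma must be > 0")
  }
  structure(list(typical = tv, covariates = cov, iiv = om, error = err),
            class = "pop_model")
}

#' @export
print.pop_model <- function(x, ...) {
  cat("Population PK model (2-compartment, first-order oral absorption)\n")
  cat(sprintf("  typical: Ka %.4g 1/h, V/F %.4g L, CL/F %.4g L/h, V2/F %.4g L, CL2/F %.4g L/h\n",
              x$typical$tv_ka, x$typical$tv_v_f, x$typical$tv_cl_f,
              x$typical$tv_v2_f, x$typical$tv_cl2_f))
  co <- x$covariates
  terms <- c(
    if (!is.null(co$d_cl_crcl)) sprintf("(CrCL/%.4g)^%.4g", co$m_crcl, co$d_cl_crcl),
    if (!is.null(co$d_cl_albumin)) sprintf("(Alb/%.4g)^%.4g", co$m_albumin, co$d_cl_albumin),
    if (!is.null(co$d_cl_cyp2c9_13)) sprintf("[1%+.4g * (CYP2C9*1/*3)]", co$d_cl_cyp2c9_13))
  cat("  CL/F covariates:", if (length(terms)) paste(terms, collapse = " * ") else "none", "\n")
  cat(sprintf("  IIV (omega^2): CL/F %.4g, V2/F %.4g, Ka %.4g  (%%CV: %s)\n",
              x$iiv$omega2_cl, x$iiv$omega2_v2, x$iiv$omega2_ka,
              paste(sprintf("%.1f", omega2_to_cv(unlist(x$iiv))), collapse = "/")))
  cat(sprintf("  residual error: %s (sigma_prop %.4g, sigma_add %.4g ug/mL)\n",
              x$error$model, x$error$sigma_prop, x$error$sigma_add))
  invisible(x)
}

#' Convert a log-normal variance to percent CV (and back)
#'
#' `%CV = 100 sqrt(exp(omega2) - 1)`, the exact coefficient of variation of a
#' log-normal random effect.
#'
#' @param omega2 variance of eta (log scale).
#' @return percent CV.
#' @export
omega2_to_cv <- function(omega2) 100 * sqrt(exp(omega2) - 1)

#' @rdname omega2_to_cv
#' @param cv percent CV.
#' @export
cv_to_omega2 <- function(cv) log(1 + (cv / 100)^2)

# Vectorized CL/F covariate multiplier. genotype is a character vector.
.cl_multiplier <- function(cov, crcl, albumin, genotype) {
  m <- rep(1, length(crcl))
  if (!is.null(cov$d_cl_crcl)) m <- m * (crcl / cov$m_crcl)^cov$d_cl_crcl
  if (!is.null(cov$d_cl_albumin)) m <- m * (albumin / cov$m_albumin)^cov$d_cl_albumin
  if (!is.null(cov$d_cl_cyp2c9_13)) {
    shift <- ifelse(genotype == "*1/*3", cov$d_cl_cyp2c9_13,
                    ifelse(genotype == "*3/*3" & isTRUE(cov$cyp2c9_33_extrapolate),
                           2 * cov$d_cl_cyp2c9_13, 0))
    m <- m * (1 + shift)
  }
  m
}

# Vectorized per-subject parameters; eta is an n x 3 matrix (cl, v2, ka).
.individual_params_vec <- function(model, crcl, albumin, genotype, eta) {
  tv <- model$typical
  n <- length(crcl)
  if (is.null(dim(eta))) eta <- matrix(eta, nrow = n, ncol = 3, byrow = n == 1)
  list(
    ka = rep(tv$tv_ka, n) * exp(eta[, 3]),
    v_f = rep(tv$tv_v_f, n),
    cl_f = tv$tv_cl_f * .cl_multiplier(model$covariates, crcl, albumin, genotype) *
      exp(eta[, 1]),
    v2_f = rep(tv$tv_v2_f, n) * exp(eta[, 2]),
    cl2_f = rep(tv$tv_cl2_f, n))
}

#' Individual structural parameters from the hierarchical model
#'
#' Applies the covariate multipliers and log-normal random effects:
#' `CL/F = tv_cl_f * (CrCL/m_crcl)^d_cl_crcl * (Albumin/m_albumin)^d_cl_albumin
#' * [1 + d_cl_cyp2c9_13 * 1(genotype = *1/*3)] * exp(eta_cl)`,
#' `V2/F = tv_v2_f * exp(eta_v2)`, `Ka = tv_ka * exp(eta_ka)`; V/F and CL2/F
#' carry no IIV.
#'
#' @param model a [pop_model()].
#' @param crcl creatinine clearance (mL/min, > 0).
#' @param albumin serum albumin (g/dL, > 0).
#' @param genotype CYP2C9 genotype label.
#' @param eta numeric vector `c(eta_cl, eta_v2, eta_ka)`.
#' @return A [structural_params()] object.
#' @export
individual_params <- function(model, crcl, albumin, genotype = "*1/*1",
                              eta = c(0, 0, 0)) {
  if (crcl <= 0 || albumin <= 0) stop("covariates must be strictly positive")
  if (!genotype %in% .genotype_levels) stop("unknown genotype label: ", genotype)
  p <- .individual_params_vec(model, crcl, albumin, genotype,
                              matrix(eta, nrow = 1))
  structural_params(ka = p$ka, v_f = p$v_f, cl_f = p$cl_f,
                    v2_f = p$v2_f, cl2_f = p$cl2_f)
}

#' Residual standard deviation at a prediction
#'
#' `sqrt((sigma_prop * f)^2 + sigma_add^2)`, floored at 1e-10 ug/mL so the
#' likelihood never degenerates at a zero prediction.
#'
#' @param error the `error` component of a [pop_model()].
#' @param prediction predicted concentration(s), >= 0.
#' @return standard deviation(s) (ug/mL).
#' @export
residual_sd <- function(error, prediction) {
  pmax(sqrt((error$sigma_prop * prediction)^2 + error$sigma_add^2), 1e-10)
}

#' Simulate observations onto a study design
#'
#' Draws per-subject random effects `eta ~ N(0, diag(omega2))`, computes each
#' subject's concentration profile from their dose events by superposition,
#' and adds residual error (`y = f (1 + eps1) + eps2` according to the error
#' model). Deterministic given `seed`.
#'
#' @param model a [pop_model()].
#' @param design a `pk_dataset` whose observation rows give the sampling
#'   times (any `dv` present is overwritten).
#' @param seed integer seed.
#' @param eta optional pre-drawn `n x 3` eta matrix (rows in the order
#'   subjects first appear); when supplied no eta is drawn.
#' @return A list with `dataset` (the design with `dv` filled in) and `eta`
#'   (the matrix of random effects used, rownames = subject ids).
#' @export
simulate_observations <- function(model, design, seed = NULL, eta = NULL) {
  if (!is.null(seed)) set.seed(seed)
  ids <- unique(design$id)
  n <- length(ids)
  if (is.null(eta)) {
    sdv <- sqrt(unlist(model$iiv))  # cl, v2, ka
    eta <- cbind(stats::rnorm(n, 0, sdv[1]), stats::rnorm(n, 0, sdv[2]),
                 stats::rnorm(n, 0, sdv[3]))
  }
  rownames(eta) <- ids
  sim <- design
  f <- .population_pred(model, design, eta = eta)
  obs <- design$evid == 0L
  fo <- f[obs]
  err <- model$error
  y <- fo
  if (err$sigma_prop > 0) y <- y * (1 + stats::rnorm(sum(obs), 0, err$sigma_prop))
  if (err$sigma_add > 0) y <- y + stats::rnorm(sum(obs), 0, err$sigma_add)
  sim$dv[obs] <- y
  sim$mdv[obs] <- 0L
  list(dataset = sim, eta = eta)
}

# Model predictions for every row of a dataset (0 on dose rows untouched --
# returns f for all rows; callers subset). eta: n x 3 matrix by subject order
# of first appearance, or NULL for eta = 0.
.population_pred <- function(model, dataset, eta = NULL) {
  pre <- .precompute_design(dataset)
  if (is.null(eta)) eta <- matrix(0, pre$n_subj, 3)
  .pred_from_pre(model, pre, eta)
}

# Precompute the (observation, prior-dose) pair expansion used by every
# prediction/estimation path. Returns subject covariates in order of first
# appearance.
.precompute_design <- function(dataset) {
  ids <- unique(dataset$id)
  subj <- match(dataset$id, ids)
  first <- match(ids, dataset$id)
  obs_rows <- which(dataset$evid == 0L)
  dose_rows <- which(dataset$evid == 1L)
  # pairs: for each observation, all doses of the same subject at time <= t
  po <- list(); pd <- list()
  dose_by_subj <- split(dose_rows, subj[dose_rows])
  for (k in seq_along(obs_rows)) {
    r <- obs_rows[k]
    dr <- dose_by_subj[[as.character(subj[r])]]
    dr <- dr[dataset$time[dr] <= dataset$time[r]]
    if (length(dr) > 0) {
      po[[k]] <- rep.int(k, length(dr))
      pd[[k]] <- dr
    }
  }
  po <- unlist(po); pd <- unlist(pd)
  # pair_obs is non-decreasing by construction; precompute the rowsum target
  # index once (rowsum sorts groups, so rownames == sorted unique groups)
  po_levels <- unique(po)
  obs_subj <- subj[obs_rows]
  y_obs <- dataset$dv[obs_rows]
  # subject-sorted copies for the compiled per-subject inner engine
  ord_obs <- order(obs_subj)
  obs_count <- tabulate(obs_subj, length(ids))
  local_pos <- integer(length(obs_rows))        # 0-based position within subject
  local_pos[ord_obs] <- sequence(obs_count) - 1L
  pair_subj <- obs_subj[po]
  ord_pair <- order(pair_subj)
  list(n_subj = length(ids), ids = ids, n_rows = nrow(dataset),
       pair_obs_levels = po_levels,
       pair_subj0 = subj[obs_rows][po] - 1L, pair_obs0 = po - 1L,
       y_sorted = y_obs[ord_obs], obs_count = obs_count, ord_obs = ord_obs,
       pair_u_sorted = (dataset$time[obs_rows][po] - dataset$time[pd])[ord_pair],
       pair_amt_sorted = dataset$amt[pd][ord_pair],
       pair_local_sorted = local_pos[po][ord_pair],
       pair_count = tabulate(pair_subj, length(ids)),
       crcl = dataset$crcl[first], alb = dataset$alb[first],
       geno = dataset$cyp2c9[first],
       obs_rows = obs_rows, n_obs = length(obs_rows),
       obs_subj = subj[obs_rows],
       y = dataset$dv[obs_rows],
       pair_obs = po,
       pair_u = dataset$time[obs_rows][po] - dataset$time[pd],
       pair_amt = dataset$amt[pd],
       pair_subj = subj[obs_rows][po])
}

# f at the observation rows given an n x 3 eta matrix; returns a vector over
# all dataset rows (0 elsewhere) if full = TRUE, else over observations only.
.pred_from_pre <- function(model, pre, eta, full = TRUE) {
  p <- .individual_params_vec(model, pre$crcl, pre$alb, pre$geno, eta)
  fobs <- .conc_pairs_cpp(pre$pair_u, pre$pair_amt, pre$pair_subj0,
                          pre$pair_obs0, pre$n_obs,
                          p$ka, p$v_f, p$cl_f, p$v2_f, p$cl2_f)
  if (!full) return(fobs)
  full_vec <- numeric(pre$n_rows)
  full_vec[pre$obs_rows] <- fobs
  full_vec
}

#' Serialize a population model to JSON
#'
#' @param model a [pop_model()].
#' @param path optional file path; when `NULL` the JSON string is returned.
#' @return JSON string (invisibly when written to `path`).
#' @export
model_to_json <- function(model, path = NULL) {
  js <- jsonlite::toJSON(unclass(model), auto_unbox = TRUE, digits = NA,
                         null = "null", pretty = TRUE)
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(js)
}

#' Deserialize a population model from JSON (or a parsed list)
#'
#' @param x a JSON string, file path, or list with fields `typical`,
#'   `covariates`, `iiv`, `error`.
#' @return A [pop_model()].
#' @export
model_from_json <- function(x) {
  if (is.character(x) && length(x) == 1) {
    x <- if (file.exists(x)) jsonlite::read_json(x, simplifyVector = TRUE)
         else jsonlite::fromJSON(x, simplifyVector = TRUE)
  }
  drop_null <- function(l) l[!vapply(l, is.null, TRUE)]
  pop_model(typical = drop_null(as.list(x$typical)),
            covariates = drop_null(as.list(x$covariates)),
            iiv = drop_null(as.list(x$iiv)),
            error = drop_null(as.list(x$error)))
}
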