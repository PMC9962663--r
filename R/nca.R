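# Non-compartmental analysis and the pre-modelling covariate screen.

#' Non-compartmental analysis of one concentration-time profile
#'
#' Cmax/Tmax from the observed maximum (first occurrence on ties), terminal
#' slope lambda_z by log-linear least squares over the points after Tmax,
#' choosing among the last 3, 4, ... points the set maximizing the adjusted
#' R^2; AUC_last by the linear trapezoidal rule (a log-down variant is
#' available via `method`); `AUC_inf = AUC_last + C_last / lambda_z`;
#' `t_half = ln 2 / lambda_z`; `CL/F = dose / AUC_inf`;
#' `Vz/F = (CL/F) / lambda_z`. When no negative terminal slope can be
#' estimated the extrapolated fields are `NA`.
#'
#' @param times sampling times (h), sorted ascending.
#' @param concentrations concentrations (ug/mL), same length.
#' @param dose administered dose (mg).
#' @param method trapezoid rule for AUC_last: `"linear"` (default) or
#'   `"linear-up/log-down"`.
#' @return A one-row data frame: `cmax`, `tmax`, `auc_last`, `auc_inf`,
#'   `lambda_z`, `t_half`, `cl_f_nca`, `vz_f_nca`, `n_lambda_z`, `r2_adj`.
#' @export
nca_parameters <- function(times, concentrations, dose,
                           method = c("linear", "linear-up/log-down")) {
  method <- match.arg(method)
  stopifnot(length(times) == length(concentrations), !is.unsorted(times))
  # AUC/Cmax need only two post-dose points; terminal-phase estimation needs
  # >= 3 points after Tmax (a rich design has >= 4 post-dose samples)
  if (sum(times > 0) < 2) stop("need at least 2 post-dose samples")
  t <- times; c <- concentrations
  imax <- which.max(c)
  cmax <- c[imax]; tmax <- t[imax]

  # AUC_last
  dt <- diff(t)
  c1 <- c[-length(c)]; c2 <- c[-1]
  if (method == "linear") {
    seg <- dt * (c1 + c2) / 2
  } else {
    down <- c2 < c1 & c2 > 0 & c1 > 0
    seg <- ifelse(down, dt * (c1 - c2) / log(c1 / c2), dt * (c1 + c2) / 2)
  }
  auc_last <- sum(seg)

  # terminal slope: points strictly after tmax with positive concentration
  idx <- which(t > tmax & c > 0)
  lambda_z <- t_half <- auc_inf <- cl_f <- vz_f <- r2a_best <- NA_real_
  n_lz <- NA_integer_
  if (length(idx) >= 3) {
    for (k in 3:length(idx)) {
      use <- utils::tail(idx, k)
      fit <- stats::lm.fit(cbind(1, t[use]), log(c[use]))
      slope <- fit$coefficients[2]
      if (!is.finite(slope) || slope >= 0) next
      r2 <- 1 - sum(fit$residuals^2) / sum((log(c[use]) - mean(log(c[use])))^2)
      r2a <- 1 - (1 - r2) * (k - 1) / (k - 2)
      if (is.na(r2a_best) || r2a > r2a_best + 1e-12) {
        r2a_best <- r2a
        lambda_z <- -slope
        n_lz <- k
      }
    }
  }
  if (is.finite(lambda_z)) {
    t_half <- log(2) / lambda_z
    c_last <- c[max(which(c > 0))]
    auc_inf <- auc_last + c_last / lambda_z
    cl_f <- dose / auc_inf
    vz_f <- cl_f / lambda_z
  }
  data.frame(cmax = cmax, tmax = tmax, auc_last = auc_last, auc_inf = auc_inf,
             lambda_z = unname(lambda_z), t_half = unname(t_half),
             cl_f_nca = unname(cl_f), vz_f_nca = unname(vz_f),
             n_lambda_z = n_lz, r2_adj = unname(r2a_best))
}

#' Per-subject NCA over a dataset
#'
#' Runs [nca_parameters()] on every subject's observation rows (dose taken
#' from the subject's first dose event).
#'
#' @param dataset a validated `pk_dataset`.
#' @param method passed to [nca_parameters()].
#' @return A data frame, one row per subject, with the NCA fields plus `id`,
#'   `crcl`, `alb`, `cyp2c9` and `dose`.
#' @export
nca_dataset <- function(dataset, method = "linear") {
  out <- lapply(split(seq_len(nrow(dataset)), factor(dataset$id, levels = unique(dataset$id))),
                function(rows) {
    d <- dataset[rows, , drop = FALSE]
    obs <- d[d$evid == 0L, ]
    dose <- d$amt[d$evid == 1L][1]
    res <- nca_parameters(obs$time, obs$dv, dose, method = method)
    cbind(data.frame(id = d$id[1], dose = dose, crcl = d$crcl[1],
                     alb = d$alb[1], cyp2c9 = d$cyp2c9[1],
                     stringsAsFactors = FALSE), res)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Screen covariates against NCA parameters by linear regression
#'
#' Univariate linear regression of each NCA parameter on each numeric
#' covariate; a pair is selected when its correlation exceeds the threshold.
#' The published screen quoted "correlations of about 30% or more"; whether
#' that is on the r or the R^2 scale is ambiguous, so the scale is explicit
#' here (default `|r| >= 0.30`).
#'
#' @param nca_table output of [nca_dataset()] (or any data frame containing
#'   the `parameters` columns).
#' @param covariates data frame of per-subject numeric covariates, same row
#'   order (default: the `crcl` and `alb` columns of `nca_table`).
#' @param threshold selection threshold (default 0.30).
#' @param scale `"r"` (default) or `"r2"`: the scale on which `threshold` is
#'   applied.
#' @param parameters NCA columns to screen.
#' @return A data frame: `covariate`, `parameter`, `n`, `r`, `r2`, `slope`,
#'   `selected`; constant covariates are excluded with a note attribute.
#' @export
screen_covariates <- function(nca_table,
                              covariates = nca_table[, c("crcl", "alb")],
                              threshold = 0.30, scale = c("r", "r2"),
                              parameters = c("cmax", "tmax", "auc_inf",
                                             "t_half", "cl_f_nca", "vz_f_nca")) {
  scale <- match.arg(scale)
  stopifnot(nrow(covariates) == nrow(nca_table))
  rows <- list(); notes <- character()
  for (cv in names(covariates)) {
    x <- covariates[[cv]]
    if (stats::sd(x, na.rm = TRUE) == 0 || all(is.na(x))) {
      notes <- c(notes, paste0("covariate ", cv, " is constant; r undefined, excluded"))
      next
    }
    for (pm in parameters) {
      y <- nca_table[[pm]]
      ok <- is.finite(x) & is.finite(y)
      if (sum(ok) < 3) next
      r <- stats::cor(x[ok], y[ok])
      slope <- r * stats::sd(y[ok]) / stats::sd(x[ok])
      sel <- if (scale == "r") abs(r) >= threshold else r^2 >= threshold
      rows[[length(rows) + 1]] <- data.frame(
        covariate = cv, parameter = pm, n = sum(ok), r = r, r2 = r^2,
        slope = slope, selected = sel, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "notes") <- notes
  out
}

#' Compare NCA parameters between CYP2C9 genotype groups
#'
#' Two-sided Mann-Whitney (Wilcoxon rank-sum) test per parameter between the
#' two genotype groups, with a Welch t test alongside when both groups have
#' n >= 2; groups with n < 2 yield descriptive output only.
#'
#' @param nca_table output of [nca_dataset()].
#' @param genotypes per-subject genotype labels (default: the `cyp2c9`
#'   column).
#' @param parameters NCA columns to compare.
#' @param alpha significance level for flagging (default 0.05).
#' @return A data frame per parameter: group means/medians, `p_wilcox`,
#'   `p_ttest`, `flag`.
#' @export
compare_genotype_groups <- function(nca_table, genotypes = nca_table$cyp2c9,
                                    parameters = c("t_half", "tmax", "cmax",
                                                   "auc_inf", "vz_f_nca",
                                                   "cl_f_nca"),
                                    alpha = 0.05) {
  g <- factor(genotypes)
  lv <- levels(g)
  if (length(lv) != 2) stop("exactly two genotype groups required, got: ",
                            paste(lv, collapse = ", "))
  rows <- lapply(parameters, function(pm) {
    y <- nca_table[[pm]]
    y1 <- y[g == lv[1] & is.finite(y)]
    y2 <- y[g == lv[2] & is.finite(y)]
    base <- data.frame(parameter = pm,
                       n1 = length(y1), n2 = length(y2),
                       mean1 = mean(y1), mean2 = mean(y2),
                       median1 = stats::median(y1), median2 = stats::median(y2),
                       p_wilcox = NA_real_, p_ttest = NA_real_, flag = FALSE,
                       stringsAsFactors = FALSE)
    if (length(y1) >= 2 && length(y2) >= 2) {
      base$p_wilcox <- suppressWarnings(
        stats::wilcox.test(y1, y2, exact = FALSE)$p.value)
      base$p_ttest <- tryCatch(stats::t.test(y1, y2)$p.value,
                               error = function(e) NA_real_)
      base$flag <- is.finite(base$p_wilcox) && base$p_wilcox < alpha
    }
    base
  })
  out <- do.call(rbind, rows)
  attr(out, "groups") <- lv
  out
}
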