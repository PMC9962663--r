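# FOCE-type marginal likelihood engine.
#
# The -2 log marginal likelihood of subject i is approximated by a Laplace
# expansion at the conditional mode eta_hat_i of
#   l_i(eta) = sum_j [ (y_ij - f_ij(eta))^2 / g_ij^2 + log g_ij^2 ]
#              + eta' Omega^-1 eta
# with g evaluated at eta (eta-eps interaction) or at eta = 0 (no
# interaction), and a Gauss-Newton Hessian G' W G + Omega^-1 (G = df/deta at
# eta_hat, W = 1/g^2):
#   -2LL_i = l_i(eta_hat) + n_i log 2pi + log|Omega| + log|G'WG + Omega^-1|.
# All ln(2pi) normalization constants are kept so the approximation is exact
# (not merely exact up to a constant) for models linear in eta with additive
# error.
#
# The inner optimization is a damped (Levenberg) Gauss-Newton iteration run
# simultaneously for all subjects on vectorized predictions; per-subject
# q x q systems (q <= 3) are solved in closed form.

# --- small vectorized symmetric solvers -------------------------------------

# H: n x q(q+1)/2 matrix of upper-triangle entries (row-major: 11,12,13,22,23,33)
# b: n x q right-hand sides. Returns n x q solutions.
.solve_sym_vec <- function(H, b, q) {
  if (q == 1) return(b / H)
  if (q == 2) {
    det <- H[, 1] * H[, 3] - H[, 2]^2
    cbind((H[, 3] * b[, 1] - H[, 2] * b[, 2]) / det,
          (H[, 1] * b[, 2] - H[, 2] * b[, 1]) / det)
  } else {
    a11 <- H[, 1]; a12 <- H[, 2]; a13 <- H[, 3]
    a22 <- H[, 4]; a23 <- H[, 5]; a33 <- H[, 6]
    c11 <- a22 * a33 - a23^2
    c12 <- a13 * a23 - a12 * a33
    c13 <- a12 * a23 - a13 * a22
    c22 <- a11 * a33 - a13^2
    c23 <- a12 * a13 - a11 * a23
    c33 <- a11 * a22 - a12^2
    det <- a11 * c11 + a12 * c12 + a13 * c13
    cbind((c11 * b[, 1] + c12 * b[, 2] + c13 * b[, 3]) / det,
          (c12 * b[, 1] + c22 * b[, 2] + c23 * b[, 3]) / det,
          (c13 * b[, 1] + c23 * b[, 2] + c33 * b[, 3]) / det)
  }
}

.logdet_sym_vec <- function(H, q) {
  if (q == 1) return(log(H[, 1]))
  if (q == 2) return(log(H[, 1] * H[, 3] - H[, 2]^2))
  a11 <- H[, 1]; a12 <- H[, 2]; a13 <- H[, 3]
  a22 <- H[, 4]; a23 <- H[, 5]; a33 <- H[, 6]
  log(a11 * (a22 * a33 - a23^2) - a12 * (a12 * a33 - a13 * a23) +
      a13 * (a12 * a23 - a13 * a22))
}

# Upper-triangle column index pairs for q dims
.ut_pairs <- function(q) {
  idx <- which(upper.tri(matrix(0, q, q), diag = TRUE), arr.ind = TRUE)
  idx[order(idx[, 1], idx[, 2]), , drop = FALSE]
}

# --- engine ------------------------------------------------------------------

# y: observations (length m); subj: integer subject index (1..n) per obs;
# pred_fun(eta): n x q_total eta matrix -> length-m predictions;
# error: residual error spec (list model/sigma_prop/sigma_add);
# omega2: length q_total vector of eta variances (0 = eta absent);
# interaction: evaluate g at the conditional eta (TRUE) or at eta = 0;
# eta_start: optional n x q_total warm start.
# Returns list(nll, eta (n x q_total), per_subject nll contributions).
.foce_core <- function(y, subj, pred_fun, error, omega2,
                       interaction = TRUE, eta_start = NULL,
                       inner_tol = 1e-12, max_iter = 150L,
                       grad_fun = NULL) {
  n <- max(subj)
  m <- length(y)
  q_total <- length(omega2)
  if (any(omega2 < 0) || any(!is.finite(omega2))) {
    stop("Omega is invalid: fix or drop the offending eta (variances must be finite and >= 0)")
  }
  act <- which(omega2 > 0)
  q <- length(act)
  n_i <- tabulate(subj, n)

  g_of <- function(f) residual_sd(error, f)
  f0 <- pred_fun(matrix(0, n, q_total))
  g0 <- g_of(f0)

  if (q == 0L) {
    r <- y - f0
    nll_i <- rowsum(r^2 / g0^2 + log(g0^2), subj)[, 1] + n_i * log(2 * pi)
    return(list(nll = sum(nll_i), eta = matrix(0, n, q_total),
                nll_subject = nll_i))
  }

  omega2a <- omega2[act]
  eta <- if (is.null(eta_start)) matrix(0, n, q_total) else eta_start
  h_fd <- 1e-4  # central-difference step on eta (exact for f linear in eta)

  # per-subject objective at a given eta matrix
  l_of <- function(eta) {
    f <- pred_fun(eta)
    g <- if (interaction) g_of(f) else g0
    prior <- as.numeric(eta[, act, drop = FALSE]^2 %*% (1 / omega2a))
    rowsum((y - f)^2 / g^2 + log(g^2), subj)[, 1] + prior
  }

  pairs <- .ut_pairs(q)
  diag_idx <- which(pairs[, 1] == pairs[, 2])
  l_cur <- l_of(eta)
  lam <- rep(0, n)
  f <- g <- G <- NULL
  have_state <- FALSE  # f/g/G valid at the current eta

  refresh <- function(eta) {
    if (!is.null(grad_fun)) {
      fg <- grad_fun(eta)
      f <<- fg$f
      G <<- fg$G[, act, drop = FALSE]
      g <<- if (interaction) g_of(f) else g0
    } else {
      f <<- pred_fun(eta)
      g <<- if (interaction) g_of(f) else g0
      G <<- matrix(0, m, q)
      for (k in seq_len(q)) {
        ep <- eta; ep[, act[k]] <- ep[, act[k]] + h_fd
        em <- eta; em[, act[k]] <- em[, act[k]] - h_fd
        G[, k] <<- (pred_fun(ep) - pred_fun(em)) / (2 * h_fd)
      }
    }
    have_state <<- TRUE
  }

  # per-subject q x q matrix of G-weighted cross products + 2/omega2 diag
  build_H <- function(weight, scale_omega) {
    H <- matrix(0, n, nrow(pairs))
    for (p in seq_len(nrow(pairs))) {
      jk <- pairs[p, ]
      H[, p] <- rowsum(G[, jk[1]] * G[, jk[2]] * weight, subj)[, 1]
      if (jk[1] == jk[2]) H[, p] <- H[, p] + scale_omega / omega2a[jk[1]]
    }
    H
  }

  for (iter in seq_len(max_iter)) {
    refresh(eta)
    r <- y - f
    g2 <- g^2
    # first and second derivatives of the per-observation loss wrt f;
    # the exact d2l/df2 (not just the Gauss-Newton 2/g^2) keeps the inner
    # Newton iteration quadratically convergent under eta-eps interaction
    w <- -2 * r / g2
    c2 <- 2 / g2
    if (interaction && error$sigma_prop > 0) {
      sp2 <- error$sigma_prop^2
      g4 <- g2^2
      w <- w + (1 / g2 - r^2 / g4) * (2 * sp2 * f)
      c2 <- c2 + 4 * r * sp2 * f / g4 + 2 * sp2 * (1 / g2 - r^2 / g4) +
        2 * sp2 * f * (-2 * sp2 * f / g4 + 2 * r / g4 + 4 * r^2 * sp2 * f / (g4 * g2))
      c2 <- pmax(c2, 0.2 / g2)  # positive-definiteness floor
    }
    grad <- matrix(0, n, q)
    for (k in seq_len(q)) {
      grad[, k] <- rowsum(G[, k] * w, subj)[, 1] + 2 * eta[, act[k]] / omega2a[k]
    }
    # Levenberg damping on the diagonal
    Hd <- build_H(c2, 2)
    for (d in seq_len(q)) Hd[, diag_idx[d]] <- Hd[, diag_idx[d]] * (1 + lam)
    step <- .solve_sym_vec(Hd, -grad, q)
    step[!is.finite(step)] <- 0

    # Newton-decrement stop: predicted objective decrease of the full step
    dec <- -0.5 * rowSums(grad * step)
    if (max(dec) < inner_tol) break

    # per-subject backtracking line search
    scale <- rep(1, n)
    improved <- rep(FALSE, n)
    eta_new <- eta
    l_new <- l_cur
    for (ls in 1:10) {
      trial <- eta
      trial[, act] <- eta[, act, drop = FALSE] + step * scale
      l_trial <- l_of(trial)
      take <- !improved & is.finite(l_trial) & (l_trial <= l_cur + 1e-12)
      if (any(take)) {
        eta_new[take, act] <- trial[take, act]
        l_new[take] <- l_trial[take]
        improved <- improved | take
      }
      if (all(improved)) break
      scale[!improved] <- scale[!improved] / 4
    }
    lam <- ifelse(improved, pmax(lam / 10, 0), pmax(lam * 10, 1e-4))
    delta_l <- abs(l_new - l_cur)
    stalled <- !any(improved)
    moved <- any(improved)
    if (moved) {
      eta <- eta_new
      l_cur <- l_new
      have_state <- FALSE
    }
    # stop on stagnation: no subject improved, or improvements are below tol
    if (stalled || max(delta_l) < inner_tol) break
  }

  # final FOCE assembly at eta_hat with the standard Gauss-Newton
  # information G' diag(1/g^2) G + Omega^-1
  if (!have_state) refresh(eta)
  H_std <- build_H(1 / g^2, 1)
  nll_i <- l_cur + n_i * log(2 * pi) + sum(log(omega2a)) +
    .logdet_sym_vec(H_std, q)
  list(nll = sum(nll_i), eta = eta, nll_subject = nll_i)
}

#' FOCE objective function (-2 log marginal likelihood)
#'
#' First-order conditional estimation with optional eta-epsilon interaction:
#' per subject, the conditional mode of the random effects is located by a
#' damped Gauss-Newton search and the marginal -2 log-likelihood is assembled
#' from the Laplace/FOCE approximation expanded there (normalization
#' constants included, so the value is exact for models linear in eta with
#' additive error).
#'
#' @param model a [pop_model()].
#' @param dataset a validated `pk_dataset` with observations.
#' @param interaction evaluate the residual variance at the conditional eta
#'   (`TRUE`, FOCE-I) or at eta = 0.
#' @param eta_start optional warm-start matrix of conditional modes
#'   (subjects x 3).
#' @return A list with `neg2ll` and `eta_hat` (subjects x 3 matrix of
#'   conditional modes, columns `eta_cl`, `eta_v2`, `eta_ka`, rownames the
#'   subject ids).
#' @export
foce_objective <- function(model, dataset, interaction = TRUE,
                           eta_start = NULL) {
  pre <- .precompute_design(dataset)
  res <- .foce_pre(model, pre, interaction, eta_start)
  eta <- res$eta
  colnames(eta) <- c("eta_cl", "eta_v2", "eta_ka")
  rownames(eta) <- pre$ids
  list(neg2ll = res$nll, eta_hat = eta)
}

# engine call on a precomputed design (fit() hot path); engine = "cpp" uses
# the compiled per-subject Newton search, "r" the reference R implementation
# (identical algorithm, compared in the tests)
.foce_pre <- function(model, pre, interaction = TRUE, eta_start = NULL,
                      engine = c("cpp", "r")) {
  engine <- match.arg(engine)
  omega2 <- c(model$iiv$omega2_cl, model$iiv$omega2_v2, model$iiv$omega2_ka)
  act <- omega2 > 0
  if (engine == "cpp" && any(act)) {
    base <- .individual_params_vec(model, pre$crcl, pre$alb, pre$geno,
                                   matrix(0, pre$n_subj, 3))
    if (is.null(eta_start)) eta_start <- matrix(0, pre$n_subj, 3)
    res <- .foce_inner_cpp(pre$y_sorted, pre$obs_count,
                           pre$pair_u_sorted, pre$pair_amt_sorted,
                           pre$pair_local_sorted, pre$pair_count,
                           base$ka, base$v_f, base$cl_f, base$v2_f,
                           base$cl2_f, omega2,
                           model$error$sigma_prop, model$error$sigma_add,
                           interaction, eta_start, 1e-12, 150L)
    n_i <- pre$obs_count
    nll_i <- res$l + n_i * log(2 * pi) + sum(log(omega2[act])) + res$logdet
    return(list(nll = sum(nll_i), eta = res$eta, nll_subject = nll_i))
  }
  pred_fun <- function(eta) .pred_from_pre(model, pre, eta, full = FALSE)
  grad_fun <- function(eta) {
    p <- .individual_params_vec(model, pre$crcl, pre$alb, pre$geno, eta)
    .conc_pairs_grad_cpp(pre$pair_u, pre$pair_amt, pre$pair_subj0,
                         pre$pair_obs0, pre$n_obs,
                         p$ka, p$v_f, p$cl_f, p$v2_f, p$cl2_f)
  }
  .foce_core(pre$y, pre$obs_subj, pred_fun, model$error, omega2,
             interaction = interaction, eta_start = eta_start,
             grad_fun = grad_fun)
}
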