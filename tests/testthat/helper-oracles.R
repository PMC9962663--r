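# Independent oracles used across the suite.

# Matrix-exponential solution of the 3-state linear system
# (depot -> central <-> peripheral, elimination from central). This is an
# entirely separate computational path from the package's eigenvalue closed
# form: exact for a linear ODE, no integration error.
expm_conc_oracle <- function(params, dose, times) {
  k10 <- params$cl_f / params$v_f
  k12 <- params$cl2_f / params$v_f
  k21 <- params$cl2_f / params$v2_f
  A <- matrix(c(-params$ka, 0, 0,
                params$ka, -(k10 + k12), k21,
                0, k12, -k21), 3, 3, byrow = TRUE)
  vapply(times, function(t) {
    x <- as.matrix(Matrix::expm(A * t)) %*% c(dose, 0, 0)
    x[2] / params$v_f
  }, 0)
}

# classic fixed-step RK4 for the same system (cross-checks the oracle itself)
rk4_conc_oracle <- function(params, dose, t_end, dt = 0.001) {
  k10 <- params$cl_f / params$v_f
  k12 <- params$cl2_f / params$v_f
  k21 <- params$cl2_f / params$v2_f
  deriv <- function(x) c(-params$ka * x[1],
                         params$ka * x[1] - (k10 + k12) * x[2] + k21 * x[3],
                         k12 * x[2] - k21 * x[3])
  x <- c(dose, 0, 0)
  n <- ceiling(t_end / dt)
  h <- t_end / n
  for (i in seq_len(n)) {
    k1 <- deriv(x); k2 <- deriv(x + h / 2 * k1)
    k3 <- deriv(x + h / 2 * k2); k4 <- deriv(x + h * k3)
    x <- x + h / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
  }
  x[2] / params$v_f
}

# exact -2 log marginal likelihood of the linear mixed model
# y_ij = theta + eta_i + eps_ij, eta ~ N(0, om2), eps ~ N(0, sig2)
gaussian_lmm_neg2ll <- function(y_list, theta, om2, sig2) {
  sum(vapply(y_list, function(yi) {
    ni <- length(yi)
    V <- diag(sig2, ni) + matrix(om2, ni, ni)
    r <- yi - theta
    ni * log(2 * pi) + determinant(V, logarithm = TRUE)$modulus[1] +
      drop(t(r) %*% solve(V, r))
  }, 0))
}

# random positive structural parameters in a physiologically wide range
random_params <- function() {
  structural_params(ka = exp(stats::runif(1, -1.5, 1.5)),
                    v_f = exp(stats::runif(1, 1.5, 4)),
                    cl_f = exp(stats::runif(1, 0, 2.5)),
                    v2_f = exp(stats::runif(1, 1.5, 4.5)),
                    cl2_f = exp(stats::runif(1, -1, 2)))
}

# small deterministic pk_dataset: one subject, one dose, explicit obs
tiny_dataset <- function(times = c(1, 2, 4, 8, 12, 24), dv = NULL,
                         dose = 80, crcl = 104.38, alb = 4.9,
                         geno = "*1/*1", id = "S1") {
  if (is.null(dv)) dv <- rep(1, length(times))
  pk_dataset(id = id, time = c(0, times), evid = c(1L, rep(0L, length(times))),
             amt = c(dose, rep(NA, length(times))),
             dv = c(NA, dv), crcl = crcl, alb = alb, cyp2c9 = geno)
}

# a small, fast-to-fit model: one random effect, proportional error
small_model <- function(omega2_cl = 0.04, sigma_prop = 0.1) {
  pop_model(typical = list(tv_ka = 1, tv_v_f = 15, tv_cl_f = 7.75,
                           tv_v2_f = 30, tv_cl2_f = 5),
            iiv = list(omega2_cl = omega2_cl),
            error = list(model = "proportional", sigma_prop = sigma_prop))
}
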