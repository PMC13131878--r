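# Independent oracles used across the test files. These deliberately avoid
# the package's own code paths.

# generating truth used by the synthetic studies (typical values, log-sd IIV,
# combined residual components)
TRUTH_TGI <- c(lambda0 = 0.0063, lambda1 = 5.93, kill = 2.4e-5)
TRUTH_OMEGA <- c(lambda0 = 0.85, lambda1 = 0.73, kill = 0.87)
TRUTH_RES <- c(a = 11.22, b = 0.22)
TRUTH_TTE <- c(te_pop = 703.17, beta_lambda0 = -0.75, beta_lambda1 = -0.46,
               beta_cavg = 0.63, omega_te = 0.043)

# brute-force product-limit estimator: walk event times counting risk sets
km_brute <- function(time, status) {
  ut <- sort(unique(time[status == 1]))
  s <- 1
  out <- numeric(length(ut))
  for (i in seq_along(ut)) {
    d <- sum(time == ut[i] & status == 1)
    n_risk <- sum(time >= ut[i])
    s <- s * (1 - d / n_risk)
    out[i] <- s
  }
  list(time = ut, surv = out)
}

# survival from a hazard function by numerical quadrature
surv_from_hazard <- function(hfun, t) {
  vapply(t, function(tt) {
    if (tt == 0) return(1)
    exp(-stats::integrate(hfun, 0, tt, rel.tol = 1e-12,
                          subdivisions = 2000L)$value)
  }, numeric(1))
}

# separable no-drug growth ODE: time to grow from v0 to v by quadrature of
# dt = dv / g(v); used as an independent check of the forward solver
time_to_volume_quadrature <- function(v0, v, lambda0, lambda1, psi = 20) {
  g <- function(x) lambda0 * x / (1 + ((lambda0 / lambda1) * x)^psi)^(1 / psi)
  stats::integrate(function(x) 1 / g(x), v0, v, rel.tol = 1e-12,
                   subdivisions = 2000L)$value
}

# small complete study used by several fitting tests
small_study <- function(seed = 7, n = c(6, 4, 4, 4, 4, 4)) {
  generate_study(default_design(n), default_population(), pk_params(),
                 seed = seed)
}
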