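#' Population model for tumor growth inhibition
#'
#' Typical values, log-normal inter-individual variability (IIV) and residual
#' error of the population TGI model. Individual parameters are
#' `p_i = p_pop * exp(eta_i)` with `eta_i ~ N(0, omega^2)` (diagonal omega),
#' and observations are `y = f + e`, `e ~ N(0, sd(f)^2)` with
#' `sd(f) = a + b f` for the combined error model (see [residual_sd()]).
#'
#' @param theta Named numeric of typical values: `lambda0` (1/h), `lambda1`
#'   (mm3/h), `kill` (mL/ng/h). `lambda1`/`kill` may be omitted for reduced
#'   growth/no-drug models.
#' @param omega Named numeric of IIV standard deviations (log scale) for a
#'   subset of the theta names; parameters not named get no IIV.
#' @param residual Named numeric `c(a = , b = )`: additive (mm3) and
#'   proportional (fraction) residual components.
#' @param error_model `"combined"`, `"additive"` or `"proportional"`.
#' @return An object of class `population_model`.
#' @examples
#' default_population()
#' @export
population_model <- function(theta, omega, residual = c(a = 10, b = 0.2),
                             error_model = c("combined", "additive", "proportional")) {
  error_model <- match.arg(error_model)
  if (is.null(names(theta)) || !all(names(theta) %in% c("lambda0", "lambda1", "kill")))
    abort("`theta` must be named among lambda0, lambda1, kill")
  if (any(theta <= 0)) abort("`theta` must be positive elementwise")
  if (length(omega) && (is.null(names(omega)) || !all(names(omega) %in% names(theta))))
    abort("`omega` names must be a subset of `theta` names")
  if (any(omega < 0)) abort("`omega` must be non-negative")
  a <- unname(residual["a"] %||% 0); b <- unname(residual["b"] %||% 0)
  if (is.na(a)) a <- 0
  if (is.na(b)) b <- 0
  if (error_model == "additive") b <- 0
  if (error_model == "proportional") a <- 0
  if (a <= 0 && b <= 0) abort("residual error cannot be identically zero unless simulating noise-free; set a tiny component instead")
  structure(list(theta = theta, omega = omega,
                 residual = c(a = a, b = b), error_model = error_model),
            class = "population_model")
}

#' Default synthetic-truth population model
#'
#' The generating values used throughout the package's synthetic xenograft
#' studies: exponential growth rate 0.0063 1/h, linear growth rate
#' 5.93 mm3/h, kill rate constant 2.4e-5 mL/ng/h, log-normal IIV standard
#' deviations 0.85 / 0.73 / 0.87 and combined residual error
#' (a = 11.22 mm3, b = 0.22).
#'
#' @return A [population_model()].
#' @export
default_population <- function() {
  population_model(
    theta = c(lambda0 = 0.0063, lambda1 = 5.93, kill = 2.4e-5),
    omega = c(lambda0 = 0.85, lambda1 = 0.73, kill = 0.87),
    residual = c(a = 11.22, b = 0.22),
    error_model = "combined"
  )
}

#' @export
print.population_model <- function(x, ...) {
  cat("<population_model>\n  theta:",
      paste(sprintf("%s = %g", names(x$theta), x$theta), collapse = ", "),
      "\n  omega:",
      if (length(x$omega)) paste(sprintf("%s = %g", names(x$omega), x$omega),
                                 collapse = ", ") else "(none)",
      "\n  residual:", sprintf("a = %g, b = %g (%s)\n",
                               x$residual["a"], x$residual["b"], x$error_model))
  invisible(x)
}

#' Individual parameters from population values and random effects
#'
#' Applies the log-normal IIV model `p_i = p_pop * exp(eta_i)`.
#'
#' @param pop A [population_model()].
#' @param eta A data frame or matrix of per-subject random effects with
#'   columns named after (a subset of) the theta parameters; missing columns
#'   are treated as zero.
#' @return A tibble with one row per subject and one column per parameter.
#' @examples
#' individual_params(default_population(),
#'                   data.frame(lambda0 = c(-0.2, 0, 0.2)))
#' @export
individual_params <- function(pop, eta) {
  eta <- as.data.frame(eta)
  n <- nrow(eta)
  out <- tibble::tibble(.rows = n)
  for (p in names(pop$theta)) {
    e <- if (p %in% names(eta)) eta[[p]] else rep(0, n)
    out[[p]] <- unname(pop$theta[p]) * exp(e)
  }
  out
}

#' Residual error standard deviation
#'
#' `sd = a + b * f` for the combined model (the "combined1" convention),
#' `sd = a` for additive, `sd = b * f` for proportional, with `f` the model
#' prediction.
#'
#' @param prediction Model prediction(s), mm3 (>= 0).
#' @param residual Named numeric `c(a = , b = )`.
#' @param error_model `"combined"`, `"additive"` or `"proportional"`.
#' @return Standard deviation(s), mm3.
#' @export
residual_sd <- function(prediction, residual,
                        error_model = c("combined", "additive", "proportional")) {
  error_model <- match.arg(error_model)
  if (any(prediction < 0)) abort("`prediction` must be non-negative")
  a <- unname(residual["a"]); b <- unname(residual["b"])
  switch(error_model,
         combined = a + b * prediction,
         additive = rep(a, length(prediction)),
         proportional = b * prediction)
}

#' Eta shrinkage
#'
#' `100 * (1 - sd(eta_hat) / omega)`: near 0 when individual data are rich,
#' approaching 100 as the empirical-Bayes estimates collapse to the
#' population value.
#'
#' @param eta_hat Numeric vector of empirical-Bayes eta estimates.
#' @param omega Population IIV standard deviation (> 0).
#' @return Shrinkage in percent.
#' @export
shrinkage_pct <- function(eta_hat, omega) {
  stopifnot_scalar_pos(omega, "omega")
  100 * (1 - stats::sd(eta_hat) / omega)
}

## ---- internal fitting machinery ------------------------------------------

# parameter sets per growth model; kill appended when the study has dosing
growth_par_names <- function(growth, with_kill) {
  base <- switch(growth,
                 simeoni = c("lambda0", "lambda1"),
                 koch = c("lambda0", "lambda1"),
                 exponential = "lambda0",
                 quadratic = "lambda0",
                 abort(sprintf("unknown growth model '%s'", growth)))
  if (with_kill) c(base, "kill") else base
}

# per-subject bundles precomputed once per fit
build_subjects <- function(study, pk) {
  obs <- dplyr::arrange(study$observations, .data$subject, .data$time_h)
  split_obs <- split(obs, obs$subject)
  lapply(split_obs, function(d) {
    arm <- d$arm[1]
    reg <- study$regimens[[arm]]
    if (is.null(reg)) abort(sprintf("no regimen found for arm '%s'", arm))
    list(subject = d$subject[1], arm = arm,
         t = d$time_h, y = d$tv_mm3, tv0 = d$tv_mm3[1],
         dose_times = reg$dose_times,
         conc0 = if (reg$n_doses > 0) dose_conc0(pk, reg) else numeric(),
         treated = reg$dose_mg_per_kg > 0)
  })
}

# prediction at the subject's observation times for phi = log parameters
subj_pred <- function(subj, phi, pn, model_code, kc50, ke, hmax) {
  lam0 <- exp(phi[match("lambda0", pn)])
  lam1 <- if ("lambda1" %in% pn) exp(phi[match("lambda1", pn)]) else 1
  kill <- if ("kill" %in% pn) exp(phi[match("kill", pn)]) else 0
  sim_tv_cpp(subj$t, subj$tv0, lam0, lam1, kill, 20, model_code, kc50,
             subj$dose_times, subj$conc0, ke, hmax)
}

# -2 log residual likelihood of a subject's data at prediction f
# (baseline observation excluded: prediction == regressor there)
neg2ll_data <- function(y, f, a, b) {
  if (length(y) < 2) return(0)
  yy <- y[-1]; ff <- f[-1]
  sdv <- pmax(a + b * ff, 1e-8)
  sum((yy - ff)^2 / sdv^2 + 2 * log(sdv))
}

# MAP objective: -2 log posterior (up to constants) in eta
map_obj <- function(eta, subj, mu, omega, a, b, pn, model_code, kc50, ke, hmax) {
  f <- subj_pred(subj, mu + eta, pn, model_code, kc50, ke, hmax)
  if (any(!is.finite(f))) return(1e12)
  neg2ll_data(subj$y, f, a, b) + sum(eta^2 / omega^2)
}

map_fit_subject <- function(subj, mu, omega, a, b, pn, model_code, kc50, ke,
                            hmax, eta_start = NULL, restart = FALSE) {
  p <- length(pn)
  eta0 <- eta_start %||% rep(0, p)
  fn <- function(e) map_obj(e, subj, mu, omega, a, b, pn, model_code, kc50, ke, hmax)
  fit <- optim(eta0, fn, method = "Nelder-Mead",
               control = list(maxit = 500, reltol = 1e-8))
  # optional restart from zero in case the warm start sat in a worse basin
  if (restart && !is.null(eta_start) && any(eta_start != 0)) {
    fit0 <- optim(rep(0, p), fn, method = "Nelder-Mead",
                  control = list(maxit = 500, reltol = 1e-8))
    if (fit0$value < fit$value) fit <- fit0
  }
  fit
}

# Laplace posterior covariance: 2 * inverse Hessian of the -2 log posterior
laplace_cov <- function(eta_hat, subj, mu, omega, a, b, pn, model_code, kc50,
                        ke, hmax) {
  p <- length(eta_hat)
  fn <- function(e) map_obj(e, subj, mu, omega, a, b, pn, model_code, kc50, ke, hmax)
  h <- 1e-3
  H <- matrix(0, p, p)
  f0 <- fn(eta_hat)
  for (i in seq_len(p)) {
    ei <- rep(0, p); ei[i] <- h
    for (j in i:p) {
      ej <- rep(0, p); ej[j] <- h
      if (i == j) {
        H[i, i] <- (fn(eta_hat + ei) - 2 * f0 + fn(eta_hat - ei)) / h^2
      } else {
        H[i, j] <- H[j, i] <-
          (fn(eta_hat + ei + ej) - fn(eta_hat + ei - ej) -
             fn(eta_hat - ei + ej) + fn(eta_hat - ei - ej)) / (4 * h^2)
      }
    }
  }
  V <- tryCatch(2 * solve(H), error = function(e) NULL)
  if (is.null(V) || any(!is.finite(V)) || any(diag(V) <= 0))
    V <- diag(pmin(omega^2, 1), p)
  # cap at the prior variance: a no-information subject has posterior = prior
  d <- pmin(diag(V), omega^2)
  diag(V) <- d
  V
}

# residual (a, b) update by minimizing the -2 log likelihood profile
update_residual <- function(y_all, f_all, a, b, error_model) {
  est_a <- error_model %in% c("combined", "additive")
  est_b <- error_model %in% c("combined", "proportional")
  par0 <- log(c(if (est_a) max(a, 1e-3), if (est_b) max(b, 1e-4)))
  fn <- function(lp) {
    i <- 1
    aa <- if (est_a) { v <- exp(lp[i]); i <- i + 1; v } else 0
    bb <- if (est_b) exp(lp[i]) else 0
    sdv <- pmax(aa + bb * f_all, 1e-8)
    sum((y_all - f_all)^2 / sdv^2 + 2 * log(sdv))
  }
  opt <- optim(par0, fn, method = if (length(par0) == 1) "Brent" else "Nelder-Mead",
               lower = if (length(par0) == 1) -20 else -Inf,
               upper = if (length(par0) == 1) 20 else Inf,
               control = list(maxit = 400, reltol = 1e-9))
  i <- 1
  a_new <- if (est_a) { v <- exp(opt$par[i]); i <- i + 1; v } else 0
  b_new <- if (est_b) exp(opt$par[i]) else 0
  c(a = a_new, b = b_new)
}

# naive single-subject / pooled starting values from raw trajectories
naive_init <- function(subjects, pn, ke) {
  l0 <- purrr::map_dbl(subjects, function(s) {
    n <- min(length(s$t), 5)
    if (n < 2) return(NA_real_)
    stats::coef(stats::lm(log(pmax(s$y[1:n], 1e-3)) ~ s$t[1:n]))[2]
  })
  l0 <- stats::median(l0[is.finite(l0) & l0 > 0], na.rm = TRUE)
  if (!is.finite(l0) || l0 <= 0) l0 <- 0.005
  # late linear slope among untreated subjects past the apparent switch
  sl <- purrr::map_dbl(subjects, function(s) {
    if (s$treated || length(s$y) < 3) return(NA_real_)
    big <- s$y > 0.5 * max(s$y) & s$y > 300
    if (sum(big) < 2) return(NA_real_)
    i <- which(big)
    (s$y[max(i)] - s$y[min(i)]) / (s$t[max(i)] - s$t[min(i)])
  })
  l1 <- stats::median(sl[is.finite(sl) & sl > 0], na.rm = TRUE)
  if (!is.finite(l1) || l1 <= 0) l1 <- l0 * 800
  # kill: log-growth deficit of treated subjects per unit cumulative exposure
  kk <- purrr::map_dbl(subjects, function(s) {
    if (!s$treated || length(s$y) < 2 || !length(s$conc0)) return(NA_real_)
    tl <- s$t[length(s$t)]
    past <- s$dose_times <= tl
    if (!any(past)) return(NA_real_)
    auc <- sum(s$conc0[past] / ke * (1 - exp(-ke * (tl - s$dose_times[past]))))
    deficit <- l0 * tl - log(pmax(s$y[length(s$y)], 1e-3) / s$tv0)
    if (deficit <= 0 || auc <= 0) return(NA_real_)
    deficit / auc
  })
  k0 <- stats::median(kk[is.finite(kk) & kk > 0], na.rm = TRUE)
  if (!is.finite(k0) || k0 <= 0) k0 <- 1e-5
  mu <- log(c(lambda0 = l0, lambda1 = l1, kill = k0))
  mu[pn]
}

tgi_fit_defaults <- function() {
  list(maxit = 40, tol = 1e-3, hmax = 2, seed = 1L,
       omega_init = 0.3, residual_init = c(a = 10, b = 0.2),
       mcem_iter = 15, mcem_draws = 150, mcem_inflate = 2, mcem_step = 1,
       ll_nsim = 300, ll_inflate = 1.5,
       saem_burn = 150, saem_smooth = 100, saem_rho = 0.4)
}

#' Control settings for [fit_tgi()]
#'
#' @param ... Named overrides of the defaults: `maxit` (EM iterations, 40),
#'   `tol` (relative-change stopping rule, 1e-3), `hmax` (ODE step during
#'   estimation, h; coarser than the simulation default since the implied
#'   error is orders of magnitude below the residual noise),
#'   `seed` (RNG seed for the stochastic pieces), `omega_init`,
#'   `residual_init`, `mcem_iter` / `mcem_draws` / `mcem_inflate` /
#'   `mcem_step` (Monte-Carlo-EM refinement: iterations, importance draws
#'   per subject, proposal-variance inflation, damping), `ll_nsim`
#'   (importance-sampling draws per subject for
#'   the marginal -2LL, 300), `ll_inflate` (proposal-variance inflation),
#'   `saem_burn`, `saem_smooth` (SAEM iteration schedule), `saem_rho`
#'   (initial random-walk scale, in units of omega).
#' @return A named list of control settings.
#' @export
tgi_control <- function(...) {
  ctl <- modifyList(tgi_fit_defaults(), list(...))
  ctl
}

#' Fit the population tumor-growth-inhibition model
#'
#' Maximum-likelihood population estimation of the TGI model with log-normal
#' IIV and combined residual error, fitting control and treated arms
#' simultaneously. Two estimation modes are provided:
#'
#' * `"two_stage"` (default): iterated MAP-EM - each subject's random
#'   effects are estimated by penalized (MAP) fits, and the population
#'   typical values, omegas and residual components are updated from the MAP
#'   estimates plus their Laplace posterior covariances, iterating to
#'   convergence. Fast and deterministic.
#' * `"saem"`: a stochastic EM - a Metropolis-Hastings kernel samples each
#'   subject's etas, and population parameters are updated from
#'   stochastically-averaged sufficient statistics over an exploration phase
#'   (constant step) followed by a smoothing phase (decreasing step).
#'
#' Either way the marginal -2 log-likelihood is evaluated by importance
#' sampling around the final empirical-Bayes modes, and
#' `AIC = -2LL + 2 * n_parameters`.
#'
#' The baseline volume of each subject enters as a regressor (the model
#' prediction at time zero equals the observed baseline), so the baseline
#' observation contributes no residual information.
#'
#' @param study A study object (see [generate_study()] or [read_study_csv()])
#'   with `$observations` and `$regimens`.
#' @param pk A [pk_params()] used to simulate the exposure driving the kill
#'   term (the same configuration used to generate/collect the data).
#' @param init Optional [population_model()] of starting values; defaults to
#'   a naive data-derived start with omega 0.3.
#' @param mode `"two_stage"` or `"saem"`.
#' @param growth Natural-growth law (see [natural_growth_rate()]).
#' @param effect `"linear"` (default) or `"mm"` (Michaelis-Menten kill;
#'   requires `kc50` via `control`... fixed, not estimated).
#' @param kc50 Michaelis-Menten constant (ng/mL) when `effect = "mm"`.
#' @param error_model Residual error model.
#' @param control A [tgi_control()] list.
#' @return An object of class `tgi_fit` with elements `theta`, `omega`,
#'   `residual`, `se`, `rse`, `m2ll`, `aic`, `n_par`, `ebes` (per-subject
#'   empirical-Bayes parameters and etas), `shrinkage`, `convergence`,
#'   `mode`, `growth`. Methods: [tidy()], [glance()], [autoplot()].
#' @examples
#' \donttest{
#' study <- generate_study(default_design(n_per_arm = c(4, 3, 3, 3, 3, 3)),
#'                         default_population(), pk_params(), seed = 7)
#' fit <- fit_tgi(study, pk_params())
#' tidy(fit)
#' }
#' @export
fit_tgi <- function(study, pk, init = NULL, mode = c("two_stage", "saem"),
                    growth = "simeoni", effect = c("linear", "mm"), kc50 = 300,
                    error_model = c("combined", "additive", "proportional"),
                    control = tgi_control()) {
  mode <- match.arg(mode)
  effect <- match.arg(effect)
  error_model <- match.arg(error_model)
  kc50 <- if (effect == "mm") kc50 else 0
  subjects <- build_subjects(study, pk)
  n <- length(subjects)
  if (n < 2) abort("need at least 2 subjects")
  if (any(purrr::map_int(subjects, ~ length(.x$t)) < 1))
    abort("every subject needs at least one observation")
  with_kill <- any(purrr::map_lgl(subjects, "treated"))
  pn <- growth_par_names(growth, with_kill)
  model_code <- growth_model_code(growth)
  hmax <- control$hmax

  # starting values
  if (!is.null(init)) {
    miss <- setdiff(pn, names(init$theta))
    if (length(miss)) abort(sprintf("init lacks theta for: %s", paste(miss, collapse = ", ")))
    mu <- log(init$theta[pn])
    omega <- vapply(pn, function(p) unname(init$omega[p] %||% control$omega_init),
                    numeric(1))
    omega[is.na(omega)] <- control$omega_init
    res <- c(a = unname(init$residual["a"]), b = unname(init$residual["b"]))
  } else {
    mu <- naive_init(subjects, pn, pk$ke)
    omega <- setNames(rep(control$omega_init, length(pn)), pn)
    res <- control$residual_init
  }
  if (error_model == "additive") res["b"] <- 0
  if (error_model == "proportional") res["a"] <- 0
  names(mu) <- pn
  omega <- pmax(omega, 1e-3)

  est <- if (mode == "two_stage") {
    em_map_fit(subjects, mu, omega, res, pn, model_code, kc50, pk$ke,
               error_model, control)
  } else {
    saem_engine(subjects, mu, omega, res, pn, model_code, kc50, pk$ke,
                error_model, control)
  }
  mu <- est$mu; omega <- est$omega; res <- est$res

  # final E-step at the converged estimates: EBEs + Laplace covs
  eta_hat <- matrix(0, n, length(pn), dimnames = list(names(subjects), pn))
  Vs <- vector("list", n)
  for (i in seq_len(n)) {
    f <- map_fit_subject(subjects[[i]], mu, omega, res["a"], res["b"], pn,
                         model_code, kc50, pk$ke, hmax,
                         eta_start = est$eta[i, ], restart = TRUE)
    eta_hat[i, ] <- f$par
    Vs[[i]] <- laplace_cov(f$par, subjects[[i]], mu, omega, res["a"], res["b"],
                           pn, model_code, kc50, pk$ke, hmax)
  }

  m2ll <- marginal_m2ll(subjects, mu, omega, res, pn, model_code, kc50, pk$ke,
                        hmax, eta_hat, Vs, control)
  n_res <- switch(error_model, combined = 2L, 1L)
  n_par <- length(pn) + length(pn) + n_res
  theta <- exp(mu)
  # large-sample SE of a log-normal typical value: omega / sqrt(n informative)
  n_inf <- vapply(pn, function(p)
    if (p == "kill") sum(purrr::map_lgl(subjects, "treated")) else n, numeric(1))
  se <- theta * omega / sqrt(n_inf)
  shrink <- vapply(pn, function(p) shrinkage_pct(eta_hat[, p], omega[p]), numeric(1))

  ebes <- tibble::tibble(
    subject = names(subjects),
    arm = purrr::map_chr(subjects, "arm"),
    tv0 = purrr::map_dbl(subjects, "tv0")
  )
  for (p in pn) ebes[[p]] <- unname(theta[p] * exp(eta_hat[, p]))
  for (p in pn) ebes[[paste0("eta_", p)]] <- unname(eta_hat[, p])

  structure(list(
    theta = theta, omega = omega, residual = res, error_model = error_model,
    se = se, rse = 100 * se / theta, m2ll = m2ll, aic = m2ll + 2 * n_par,
    n_par = n_par, ebes = ebes, shrinkage = shrink,
    convergence = est$convergence, mode = mode, growth = growth,
    effect = effect, kc50 = kc50, pk = pk, control = control,
    n_subjects = n, n_obs = sum(purrr::map_int(subjects, ~ length(.x$t))),
    subjects = subjects
  ), class = "tgi_fit")
}

em_map_fit <- function(subjects, mu, omega, res, pn, model_code, kc50, ke,
                       error_model, control) {
  n <- length(subjects)
  p <- length(pn)
  hmax <- control$hmax
  eta <- matrix(0, n, p)
  trace <- list()
  converged <- FALSE
  for (it in seq_len(control$maxit)) {
    Vdiag <- matrix(0, n, p)
    preds <- vector("list", n)
    for (i in seq_len(n)) {
      f <- map_fit_subject(subjects[[i]], mu, omega, res["a"], res["b"], pn,
                           model_code, kc50, ke, hmax,
                           eta_start = if (it > 1) eta[i, ] else NULL)
      eta[i, ] <- f$par
      V <- laplace_cov(f$par, subjects[[i]], mu, omega, res["a"], res["b"],
                       pn, model_code, kc50, ke, hmax)
      Vdiag[i, ] <- diag(V)
      preds[[i]] <- subj_pred(subjects[[i]], mu + f$par, pn, model_code, kc50,
                              ke, hmax)
    }
    mu_new <- mu + colMeans(eta)
    omega_new <- sqrt(pmax(colMeans(eta^2 + Vdiag), 1e-6))
    y_all <- unlist(purrr::map(subjects, ~ .x$y[-1]))
    f_all <- unlist(purrr::map(preds, ~ .x[-1]))
    res_new <- update_residual(y_all, f_all, res["a"], res["b"], error_model)
    delta <- max(abs(c(exp(mu_new) / exp(mu) - 1,
                       omega_new / omega - 1,
                       (res_new + 1e-6) / (res + 1e-6) - 1)))
    trace[[it]] <- c(iter = it, setNames(exp(mu_new), pn), delta = delta)
    mu <- setNames(mu_new, pn); omega <- setNames(omega_new, pn); res <- res_new
    if (delta < control$tol) { converged <- TRUE; break }
  }
  # Monte-Carlo EM refinement: the MAP/Laplace E-step uses posterior modes,
  # which are biased for the skewed per-subject posteriors that event
  # truncation produces (a subject observed only briefly past the
  # exponential-to-linear switch carries one-sided information). Replace the
  # E-step with importance-sampling posterior moments around the MAP for a
  # fixed number of damped iterations.
  if (control$mcem_iter > 0) {
    out <- with_seed(control$seed + 13L, {
      for (it2 in seq_len(control$mcem_iter)) {
        e1 <- matrix(0, n, p); e2 <- matrix(0, n, p)
        fbar_all <- vector("list", n); r2bar_all <- vector("list", n)
        for (i in seq_len(n)) {
          f <- map_fit_subject(subjects[[i]], mu, omega, res["a"], res["b"],
                               pn, model_code, kc50, ke, hmax,
                               eta_start = eta[i, ])
          eta[i, ] <- f$par
          V <- laplace_cov(f$par, subjects[[i]], mu, omega, res["a"],
                           res["b"], pn, model_code, kc50, ke, hmax)
          sdq <- sqrt(pmax(diag(V), 1e-10) * control$mcem_inflate)
          M <- control$mcem_draws
          # heavy-tailed t proposal: the truncated-design posteriors are
          # skewed, and a normal proposal under-covers the long side
          df_t <- 5
          Z <- matrix(stats::rt(M * p, df = df_t), M, p)
          E <- sweep(Z %*% diag(sdq, p), 2, f$par, `+`)
          ni <- length(subjects[[i]]$y)
          fs <- matrix(0, M, ni)
          lw <- numeric(M)
          for (m in seq_len(M)) {
            pred <- subj_pred(subjects[[i]], mu + E[m, ], pn, model_code,
                              kc50, ke, hmax)
            if (any(!is.finite(pred))) { lw[m] <- -Inf; next }
            fs[m, ] <- pred
            lw[m] <- -0.5 * neg2ll_data(subjects[[i]]$y, pred, res["a"],
                                        res["b"]) +
              sum(dnorm(E[m, ], 0, omega, log = TRUE)) -
              sum(stats::dt(Z[m, ], df = df_t, log = TRUE) - log(sdq))
          }
          w <- exp(lw - max(lw)); w <- w / sum(w)
          e1[i, ] <- colSums(E * w)
          e2[i, ] <- colSums(E^2 * w)
          fbar_all[[i]] <- colSums(fs * w)
          r2bar_all[[i]] <- colSums(sweep(-fs, 2, subjects[[i]]$y, `+`)^2 * w)
        }
        g <- control$mcem_step
        mu <- setNames(mu + g * colMeans(e1), pn)
        omega <- setNames(sqrt(pmax((1 - g) * omega^2 + g * colMeans(e2),
                                    1e-6)), pn)
        # individual parameters keep their meaning under the mu shift
        eta <- sweep(eta, 2, g * colMeans(e1), `-`)
        y_all <- unlist(purrr::map(subjects, ~ .x$y[-1]))
        f_all <- unlist(purrr::map(fbar_all, ~ .x[-1]))
        r2_all <- unlist(purrr::map(r2bar_all, ~ .x[-1]))
        res_cand <- update_residual_moments(y_all, f_all, r2_all, res["a"],
                                            res["b"], error_model)
        res <- (1 - g) * res + g * res_cand
        trace[[length(trace) + 1]] <- c(iter = control$maxit + it2,
                                        setNames(exp(mu), pn), delta = NA)
      }
      list(mu = mu, omega = omega, res = res, eta = eta)
    })
    mu <- out$mu; omega <- out$omega; res <- out$res; eta <- out$eta
  }
  list(mu = mu, omega = omega, res = res, eta = eta,
       convergence = list(converged = converged, iterations = it,
                          trace = dplyr::bind_rows(lapply(trace, as.list))))
}

# residual update from posterior-smoothed squared residuals: minimize the
# expected -2 log likelihood with sd evaluated at the smoothed prediction
update_residual_moments <- function(y_all, f_all, r2_all, a, b, error_model) {
  est_a <- error_model %in% c("combined", "additive")
  est_b <- error_model %in% c("combined", "proportional")
  par0 <- log(c(if (est_a) max(a, 1e-3), if (est_b) max(b, 1e-4)))
  fn <- function(lp) {
    i <- 1
    aa <- if (est_a) { v <- exp(lp[i]); i <- i + 1; v } else 0
    bb <- if (est_b) exp(lp[i]) else 0
    sdv <- pmax(aa + bb * f_all, 1e-8)
    sum(r2_all / sdv^2 + 2 * log(sdv))
  }
  opt <- optim(par0, fn, method = if (length(par0) == 1) "Brent" else "Nelder-Mead",
               lower = if (length(par0) == 1) -20 else -Inf,
               upper = if (length(par0) == 1) 20 else Inf,
               control = list(maxit = 400, reltol = 1e-9))
  i <- 1
  a_new <- if (est_a) { v <- exp(opt$par[i]); i <- i + 1; v } else 0
  b_new <- if (est_b) exp(opt$par[i]) else 0
  c(a = a_new, b = b_new)
}

saem_engine <- function(subjects, mu, omega, res, pn, model_code, kc50, ke,
                        error_model, control) {
  n <- length(subjects); p <- length(pn)
  hmax <- control$hmax
  n_burn <- control$saem_burn; n_smooth <- control$saem_smooth
  with_seed(control$seed, {
    eta <- matrix(0, n, p)
    obj_cur <- vapply(seq_len(n), function(i)
      map_obj(eta[i, ], subjects[[i]], mu, omega, res["a"], res["b"], pn,
              model_code, kc50, ke, hmax), numeric(1))
    rho <- rep(control$saem_rho, p)
    S1 <- matrix(0, n, p); S2 <- matrix(0, n, p)
    Fbar <- purrr::map(subjects, ~ .x$y)  # running smoothed predictions
    R2bar <- purrr::map(subjects, ~ rep(0, length(.x$y)))
    n_pass <- 2L  # MH sweeps per SAEM iteration
    for (it in seq_len(n_burn + n_smooth)) {
      g <- if (it <= n_burn) 1 else 1 / (it - n_burn)
      acc <- rep(0, p)
      for (i in seq_len(n)) {
        for (pass in seq_len(n_pass)) for (j in seq_len(p)) {
          cand <- eta[i, ]
          cand[j] <- cand[j] + rho[j] * omega[j] * rnorm(1)
          obj_cand <- map_obj(cand, subjects[[i]], mu, omega, res["a"],
                              res["b"], pn, model_code, kc50, ke, hmax)
          if (log(runif(1)) < -0.5 * (obj_cand - obj_cur[i])) {
            eta[i, ] <- cand; obj_cur[i] <- obj_cand; acc[j] <- acc[j] + 1
          }
        }
        phi_i <- mu + eta[i, ]
        fi <- subj_pred(subjects[[i]], phi_i, pn, model_code, kc50, ke, hmax)
        S1[i, ] <- (1 - g) * S1[i, ] + g * phi_i
        S2[i, ] <- (1 - g) * S2[i, ] + g * phi_i^2
        Fbar[[i]] <- (1 - g) * Fbar[[i]] + g * fi
        R2bar[[i]] <- (1 - g) * R2bar[[i]] + g * (subjects[[i]]$y - fi)^2
      }
      rho <- pmin(pmax(rho * exp(0.4 * (acc / (n * n_pass) - 0.3)), 0.02), 5)
      if (it <= 3) next  # let the chain move before the first M-step
      mu_old <- mu
      mu <- setNames(colMeans(S1), pn)
      omega_cand <- sqrt(pmax(colMeans(S2) - colMeans(S1)^2, 1e-6))
      # simulated annealing during exploration: variance components may not
      # collapse faster than 5 percent per iteration, or the prior freezes
      # the MH chain before it has dispersed
      omega <- setNames(if (it <= n_burn) pmax(omega_cand, 0.95 * omega)
                        else omega_cand, pn)
      # keep each subject's individual parameters invariant under the mu shift
      eta <- sweep(eta, 2, mu - mu_old, `-`)
      y_all <- unlist(purrr::map(subjects, ~ .x$y[-1]))
      f_all <- unlist(purrr::map(Fbar, ~ .x[-1]))
      # approximate residual update on smoothed predictions
      res_cand <- update_residual(y_all, f_all, res["a"], res["b"], error_model)
      res <- if (it <= n_burn) pmax(res_cand, 0.95 * res) else res_cand
      # objective values refer to old (mu, omega, res); refresh
      obj_cur <- vapply(seq_len(n), function(i)
        map_obj(eta[i, ], subjects[[i]], mu, omega, res["a"], res["b"], pn,
                model_code, kc50, ke, hmax), numeric(1))
    }
    list(mu = mu, omega = omega, res = res, eta = eta,
         convergence = list(converged = TRUE,
                            iterations = n_burn + n_smooth,
                            trace = NULL))
  })
}

# marginal -2LL by importance sampling: proposal N(eta_hat, inflate * V_i)
marginal_m2ll <- function(subjects, mu, omega, res, pn, model_code, kc50, ke,
                          hmax, eta_hat, Vs, control) {
  n <- length(subjects); p <- length(pn)
  M <- control$ll_nsim
  with_seed(control$seed + 7L, {
    ll <- 0
    for (i in seq_len(n)) {
      sdq <- sqrt(pmax(diag(Vs[[i]]), 1e-10) * control$ll_inflate)
      Z <- matrix(rnorm(M * p), M, p)
      E <- sweep(sweep(Z, 2, sdq, `*`), 2, eta_hat[i, ], `+`)
      logw <- vapply(seq_len(M), function(m) {
        e <- E[m, ]
        f <- subj_pred(subjects[[i]], mu + e, pn, model_code, kc50, ke, hmax)
        if (any(!is.finite(f))) return(-Inf)
        n_i <- length(subjects[[i]]$y) - 1
        lp_y <- -0.5 * (neg2ll_data(subjects[[i]]$y, f, res["a"], res["b"]) +
                          max(n_i, 0) * log(2 * pi))
        lp_e <- sum(dnorm(e, 0, omega, log = TRUE))
        lq <- sum(dnorm(e, eta_hat[i, ], sdq, log = TRUE))
        lp_y + lp_e - lq
      }, numeric(1))
      mx <- max(logw)
      ll <- ll + mx + log(mean(exp(logw - mx)))
    }
    -2 * ll
  })
}

#' Empirical-Bayes individual parameter estimates
#'
#' Per-subject posterior-mode (MAP) estimates of the random effects given
#' population estimates, returning individual `lambda0`, `lambda1`, `kill`
#' (as applicable) and the corresponding etas. Subjects with no
#' post-baseline observations fall back to the population values with a
#' warning; untreated subjects carry no information about their kill rate,
#' so their kill EBE shrinks to the typical value.
#'
#' @param study A study object.
#' @param fit A `tgi_fit` (supplies population estimates and settings).
#' @return A tibble: `subject`, `arm`, `tv0`, one column per parameter, one
#'   `eta_*` column per parameter.
#' @export
empirical_bayes <- function(study, fit) {
  subjects <- build_subjects(study, fit$pk)
  pn <- names(fit$theta)
  model_code <- growth_model_code(fit$growth)
  mu <- log(fit$theta)
  if (any(purrr::map_int(subjects, ~ length(.x$t)) < 2))
    warn("subjects with only a baseline observation get population values")
  eta_hat <- t(vapply(subjects, function(s)
    map_fit_subject(s, mu, fit$omega, fit$residual["a"], fit$residual["b"],
                    pn, model_code, fit$kc50, fit$pk$ke, fit$control$hmax)$par,
    numeric(length(pn))))
  out <- tibble::tibble(subject = names(subjects),
                        arm = purrr::map_chr(subjects, "arm"),
                        tv0 = purrr::map_dbl(subjects, "tv0"))
  for (j in seq_along(pn)) out[[pn[j]]] <- unname(fit$theta[pn[j]] * exp(eta_hat[, j]))
  for (j in seq_along(pn)) out[[paste0("eta_", pn[j])]] <- unname(eta_hat[, j])
  out
}

#' Rank fitted models by AIC
#'
#' @param ... Named `tgi_fit` (or `tte_fit`) objects fitted to the same data.
#' @return A tibble sorted ascending by AIC with a `delta_aic` column.
#' @export
compare_models <- function(...) {
  fits <- list(...)
  if (length(fits) == 1 && is.list(fits[[1]]) && !inherits(fits[[1]], c("tgi_fit", "tte_fit")))
    fits <- fits[[1]]
  if (is.null(names(fits)) || any(names(fits) == ""))
    names(fits) <- paste0("model", seq_along(fits))
  ns <- purrr::map_dbl(fits, ~ .x$n_subjects %||% NA_real_)
  if (length(unique(ns[!is.na(ns)])) > 1)
    abort("fits were not run on the same number of subjects")
  out <- purrr::imap_dfr(fits, function(f, nm)
    tibble::tibble(model = nm,
                   growth = f$growth %||% f$family %||% NA_character_,
                   n_par = f$n_par, m2ll = f$m2ll, aic = f$aic))
  out <- dplyr::arrange(out, .data$aic)
  dplyr::mutate(out, delta_aic = .data$aic - .data$aic[1])
}
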