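#' Parametric time-to-event model parameters
#'
#' The base hazard is log-logistic with shape fixed at 4 by convention:
#' `h(t) = (s/Te) (t/Te)^(s-1) / (1 + (t/Te)^s)`, whose scale `Te` equals
#' the median event time. The individual scale is modified by covariates
#' (individual growth rates and regimen average concentration) and a
#' log-normal frailty, see [individual_scale()].
#'
#' @param te_pop Population scale parameter, h (> 0).
#' @param shape Shape parameter `s` (> 0), fixed at 4 by default.
#' @param beta Named numeric of covariate coefficients among `lambda0`,
#'   `lambda1`, `cavg` (may be empty for the base model).
#' @param omega_te Frailty standard deviation on the log scale (>= 0).
#' @param family Hazard family: `"loglogistic"` (default), `"weibull"`,
#'   `"gompertz"`, `"exponential"`.
#' @return An object of class `tte_params`.
#' @examples
#' default_tte_params()
#' @export
tte_params <- function(te_pop, shape = 4, beta = numeric(), omega_te = 0,
                       family = c("loglogistic", "weibull", "gompertz", "exponential")) {
  family <- match.arg(family)
  stopifnot_scalar_pos(te_pop, "te_pop")
  stopifnot_scalar_pos(shape, "shape")
  stopifnot_scalar_pos(omega_te, "omega_te", strict = FALSE)
  if (length(beta) && (is.null(names(beta)) ||
                       !all(names(beta) %in% c("lambda0", "lambda1", "cavg"))))
    abort("`beta` must be named among lambda0, lambda1, cavg")
  structure(list(te_pop = te_pop, shape = shape, beta = beta,
                 omega_te = omega_te, family = family),
            class = "tte_params")
}

#' Default synthetic-truth time-to-event model
#'
#' The generating values used in the package's synthetic survival studies:
#' log-logistic scale 703.17 h, shape 4 (fixed), covariate coefficients
#' -0.75 (`lambda0`), -0.46 (`lambda1`), +0.63 (`cavg`) and frailty 0.043.
#'
#' @return A [tte_params()].
#' @export
default_tte_params <- function() {
  tte_params(te_pop = 703.17, shape = 4,
             beta = c(lambda0 = -0.75, lambda1 = -0.46, cavg = 0.63),
             omega_te = 0.043)
}

#' Hazard and survival functions of the parametric families
#'
#' Parameterizations (scale `te`, shape `s`):
#' * log-logistic: `h = (s/te)(t/te)^(s-1)/(1+(t/te)^s)`,
#'   `S = 1/(1+(t/te)^s)`; `S(te) = 1/2` at any shape, so `te` is the
#'   median event time.
#' * Weibull: `h = (s/te)(t/te)^(s-1)`, `S = exp(-(t/te)^s)`.
#' * Gompertz: `h = (1/te) exp(s t/te)`, `S = exp(-(exp(s t/te)-1)/s)`.
#' * exponential: `h = 1/te`, `S = exp(-t/te)` (shape ignored).
#'
#' @param t Time(s), h (>= 0).
#' @param te Scale, h (> 0).
#' @param shape Shape (> 0).
#' @param family Family name.
#' @return Hazard (1/h) or survival probability, vectorized over `t`.
#' @examples
#' surv_survival(703.17, te = 703.17)  # 0.5: the scale is the median
#' @export
surv_hazard <- function(t, te, shape = 4,
                        family = c("loglogistic", "weibull", "gompertz", "exponential")) {
  family <- match.arg(family)
  if (any(t < 0)) abort("`t` must be non-negative")
  stopifnot_scalar_pos(te, "te"); stopifnot_scalar_pos(shape, "shape")
  switch(family,
    loglogistic = (shape / te) * (t / te)^(shape - 1) / (1 + (t / te)^shape),
    weibull = (shape / te) * (t / te)^(shape - 1),
    gompertz = (1 / te) * exp(shape * t / te),
    exponential = rep(1 / te, length(t))
  )
}

#' @rdname surv_hazard
#' @export
surv_survival <- function(t, te, shape = 4,
                          family = c("loglogistic", "weibull", "gompertz", "exponential")) {
  family <- match.arg(family)
  if (any(t < 0)) abort("`t` must be non-negative")
  stopifnot_scalar_pos(te, "te"); stopifnot_scalar_pos(shape, "shape")
  switch(family,
    loglogistic = 1 / (1 + (t / te)^shape),
    weibull = exp(-(t / te)^shape),
    gompertz = exp(-(exp(shape * t / te) - 1) / shape),
    exponential = exp(-t / te)
  )
}

# covariate design matrix in the scale model:
# log Te_i = log Te_pop + b_l0 (l0_i/med - 1) + b_l1 (l1_i/med - 1)
#          + b_cavg (cavg_i/med) + eta_i
# The cavg term is not centered by -1, so zero exposure (vehicle) leaves the
# scale at its reference value.
tte_design <- function(cov, beta_names, medians) {
  X <- matrix(0, nrow(cov), length(beta_names),
              dimnames = list(NULL, beta_names))
  for (b in beta_names) {
    if (!b %in% names(cov)) abort(sprintf("covariate column '%s' missing", b))
    med <- medians[[b]]
    if (!is.finite(med) || med <= 0) abort(sprintf("median for '%s' must be positive", b))
    X[, b] <- if (b == "cavg") cov[[b]] / med else cov[[b]] / med - 1
  }
  X
}

default_medians <- function(cov, beta_names) {
  out <- lapply(beta_names, function(b) {
    if (!b %in% names(cov)) abort(sprintf("covariate column '%s' missing", b))
    stats::median(cov[[b]])
  })
  names(out) <- beta_names
  out
}

#' Individual scale parameters under the covariate model
#'
#' Computes `Te_i = Te_pop * exp(b_l0 (l0_i/med_l0 - 1)) *
#' exp(b_l1 (l1_i/med_l1 - 1)) * exp(b_cavg cavg_i/med_cavg) * exp(eta_i)`
#' for whichever coefficients are present in `p$beta`. Note the exposure
#' term is not median-centered by subtraction, so an unexposed subject
#' (cavg = 0) gets multiplier 1.
#'
#' @param cov Data frame of per-subject covariates with columns among
#'   `lambda0`, `lambda1`, `cavg`.
#' @param p A [tte_params()].
#' @param medians Named list of normalizing medians; default: column medians
#'   of `cov` (all subjects, controls included).
#' @param eta Optional per-subject frailty deviates (default 0).
#' @return Numeric vector of individual scales, h.
#' @export
individual_scale <- function(cov, p, medians = NULL, eta = 0) {
  bn <- names(p$beta)
  if (!length(bn)) return(rep(p$te_pop, nrow(cov)) * exp(eta))
  medians <- medians %||% default_medians(cov, bn)
  X <- tte_design(cov, bn, medians)
  p$te_pop * exp(drop(X %*% p$beta) + eta)
}

#' Right-censored log-likelihood of the time-to-event model
#'
#' `sum over events of log h(t_i) + log S(t_i)` plus
#' `sum over censored of log S(t_i)`, with individual scales from
#' [individual_scale()]. When `p$omega_te > 0` the frailty is marginalized
#' per subject by Gauss-Hermite quadrature.
#'
#' @param p A [tte_params()].
#' @param events Data frame: `subject`, `time_h` (> 0), `status` (1 event,
#'   0 censored).
#' @param cov Data frame of covariates aligned with `events` by `subject`
#'   (or row order when no subject column); may be `NULL` for the base model.
#' @param medians Normalizing medians (see [individual_scale()]).
#' @param gh_nodes Gauss-Hermite node count for frailty marginalization.
#' @return Log-likelihood (scalar).
#' @export
loglik_tte <- function(p, events, cov = NULL, medians = NULL, gh_nodes = 21) {
  ev <- align_events_cov(events, cov)
  if (any(ev$events$time_h <= 0))
    abort("event/censoring times must be positive")
  if (any(ev$events$time_h == 0 & ev$events$status == 1))
    abort("an event at t = 0 has zero hazard under shape > 1")
  te_i <- individual_scale(ev$cov, p, medians)
  tte_ll_vec(ev$events$time_h, ev$events$status, te_i, p, gh_nodes) |> sum()
}

# hazard/survival with vector scale (internal; exported versions take scalar te)
surv_h_vec <- function(t, te, shape, family) {
  switch(family,
    loglogistic = (shape / te) * (t / te)^(shape - 1) / (1 + (t / te)^shape),
    weibull = (shape / te) * (t / te)^(shape - 1),
    gompertz = (1 / te) * exp(shape * t / te),
    exponential = 1 / te + 0 * t
  )
}
surv_S_vec <- function(t, te, shape, family) {
  switch(family,
    loglogistic = 1 / (1 + (t / te)^shape),
    weibull = exp(-(t / te)^shape),
    gompertz = exp(-(exp(shape * t / te) - 1) / shape),
    exponential = exp(-t / te)
  )
}

# per-subject log-likelihood contributions, frailty marginalized if needed
tte_ll_vec <- function(time, status, te_i, p, gh_nodes = 21) {
  ll_at <- function(te_vec) {
    S <- surv_S_vec(time, te_vec, p$shape, p$family)
    h <- surv_h_vec(time, te_vec, p$shape, p$family)
    log(pmax(S, 1e-300)) + status * log(pmax(h, 1e-300))
  }
  if (p$omega_te <= 0) return(ll_at(te_i))
  gh <- pracma::gaussHermite(gh_nodes)
  # integral over eta ~ N(0, omega^2): nodes sqrt(2) * omega * x, weights w/sqrt(pi)
  contrib <- matrix(0, length(time), gh_nodes)
  for (k in seq_len(gh_nodes)) {
    contrib[, k] <- ll_at(te_i * exp(sqrt(2) * p$omega_te * gh$x[k]))
  }
  mx <- apply(contrib, 1, max)
  mx + log(colSums(t(exp(contrib - mx)) * (gh$w / sqrt(pi))))
}

align_events_cov <- function(events, cov) {
  events <- tibble::as_tibble(events)
  if (!all(c("time_h", "status") %in% names(events)))
    abort("`events` needs columns time_h and status")
  if (is.null(cov)) {
    cov <- tibble::tibble(.rows = nrow(events))
  } else {
    cov <- tibble::as_tibble(cov)
    if ("subject" %in% names(events) && "subject" %in% names(cov)) {
      idx <- match(events$subject, cov$subject)
      if (any(is.na(idx))) abort("missing covariates for some subjects")
      cov <- cov[idx, ]
    } else if (nrow(cov) != nrow(events)) {
      abort("`cov` must match `events` by subject column or row count")
    }
  }
  list(events = events, cov = cov)
}

#' Fit a parametric time-to-event model by censored maximum likelihood
#'
#' Maximizes the right-censored likelihood over the population scale, any
#' covariate coefficients present in `covariates`, and (optionally) the
#' frailty standard deviation. The log-logistic shape is fixed at 4 by
#' default; `estimate_shape = TRUE` frees it (used when screening hazard
#' families). Standard errors come from the observed information
#' (numerical Hessian at the optimum); `AIC = -2LL + 2 p`.
#'
#' @param events Data frame: `subject`, `time_h`, `status` (1 event /
#'   0 censored).
#' @param covariates Optional data frame with `subject` plus columns among
#'   `lambda0`, `lambda1`, `cavg`; every present column gets a coefficient.
#' @param family Hazard family (see [surv_hazard()]).
#' @param shape Fixed shape value (default 4); ignored if `estimate_shape`.
#' @param estimate_shape Estimate the shape instead of fixing it.
#' @param frailty `"none"` (default) or `"estimate"` (log-normal frailty on
#'   the scale, positivity floor 1e-4, Gauss-Hermite marginalization).
#' @param medians Normalizing medians for the covariate model; default
#'   column medians over all fitted subjects.
#' @param init Optional named list of starting values (`te_pop`, `beta`,
#'   `omega_te`, `shape`).
#' @param gh_nodes Gauss-Hermite node count for frailty marginalization.
#' @return An object of class `tte_fit`: `te_pop`, `beta`, `omega_te`,
#'   `shape`, `family`, `se` (named, delta-method for `te_pop`), `rse`,
#'   `m2ll`, `aic`, `n_par`, `medians`, `convergence`. Methods: [tidy()],
#'   [glance()].
#' @examples
#' set.seed(1)
#' cov <- data.frame(subject = as.character(1:120))
#' ev <- simulate_events(cov, tte_params(te_pop = 700), censor_time = 2400)
#' fit_tte(ev)$te_pop
#' @export
fit_tte <- function(events, covariates = NULL,
                    family = c("loglogistic", "weibull", "gompertz", "exponential"),
                    shape = 4, estimate_shape = FALSE,
                    frailty = c("none", "estimate"),
                    medians = NULL, init = NULL, gh_nodes = 21) {
  family <- match.arg(family)
  frailty <- match.arg(frailty)
  ev <- align_events_cov(events, covariates)
  events <- ev$events; cov <- ev$cov
  if (sum(events$status == 1) < 1) abort("need at least one event")
  if (any(events$time_h <= 0)) abort("times must be positive")
  bn <- intersect(c("lambda0", "lambda1", "cavg"), names(cov))
  if (length(bn)) medians <- medians %||% default_medians(cov, bn)

  # parameter vector: log te, betas, [log omega], [log shape]
  te0 <- init$te_pop %||% stats::median(events$time_h)
  b0 <- setNames(rep(0, length(bn)), bn)
  if (!is.null(init$beta)) b0[names(init$beta)] <- init$beta
  om0 <- max(init$omega_te %||% 0.1, 1e-3)
  sh0 <- init$shape %||% shape
  par <- c(log(te0), b0,
           if (frailty == "estimate") log(om0),
           if (estimate_shape) log(sh0))
  unpack <- function(par) {
    i <- 1L
    # clamp against under/overflow during line searches
    te <- min(max(exp(par[i]), 1e-6), 1e10); i <- i + 1L
    beta <- if (length(bn)) setNames(par[i:(i + length(bn) - 1L)], bn) else numeric()
    i <- i + length(bn)
    om <- if (frailty == "estimate") { v <- min(max(exp(par[i]), 1e-4), 100); i <- i + 1L; v } else 0
    sh <- if (estimate_shape) min(max(exp(par[i]), 1e-3), 1e3) else shape
    tte_params(te, sh, beta, om, family)
  }
  nll <- function(par) {
    p <- unpack(par)
    val <- -sum(tte_ll_vec(events$time_h, events$status,
                           individual_scale(cov, p, medians), p, gh_nodes))
    if (!is.finite(val)) 1e12 else val
  }
  opt <- optim(par, nll, method = "BFGS",
               control = list(maxit = 500, reltol = 1e-10))
  if (length(par) > 1) {
    opt2 <- optim(opt$par, nll, method = "Nelder-Mead",
                  control = list(maxit = 2000, reltol = 1e-10))
    if (opt2$value < opt$value) opt <- opt2
  }
  p_hat <- unpack(opt$par)
  H <- tryCatch(optimHess(opt$par, nll), error = function(e) NULL)
  vc <- if (!is.null(H)) tryCatch(solve(H), error = function(e) NULL) else NULL
  par_names <- c("te_pop", if (length(bn)) paste0("beta_", bn),
                 if (frailty == "estimate") "omega_te",
                 if (estimate_shape) "shape")
  se <- setNames(rep(NA_real_, length(par_names)), par_names)
  if (!is.null(vc) && all(is.finite(diag(vc))) && all(diag(vc) >= 0)) {
    sdv <- sqrt(diag(vc))
    se["te_pop"] <- p_hat$te_pop * sdv[1]          # delta method, log scale
    if (length(bn)) se[paste0("beta_", bn)] <- sdv[2:(1 + length(bn))]
    i <- 2 + length(bn)
    if (frailty == "estimate") { se["omega_te"] <- p_hat$omega_te * sdv[i]; i <- i + 1 }
    if (estimate_shape) se["shape"] <- p_hat$shape * sdv[i]
  }
  est <- c(te_pop = p_hat$te_pop,
           if (length(bn)) setNames(p_hat$beta, paste0("beta_", bn)),
           if (frailty == "estimate") c(omega_te = p_hat$omega_te),
           if (estimate_shape) c(shape = p_hat$shape))
  n_par <- length(par)
  separation_check(events, cov, bn)
  structure(list(
    te_pop = p_hat$te_pop, beta = p_hat$beta, omega_te = p_hat$omega_te,
    shape = p_hat$shape, family = family, estimates = est,
    se = se, rse = 100 * se / abs(est),
    m2ll = 2 * opt$value, aic = 2 * opt$value + 2 * n_par, n_par = n_par,
    medians = medians, frailty = frailty,
    n_subjects = nrow(events), n_events = sum(events$status == 1),
    convergence = list(code = opt$convergence, value = opt$value),
    events = events, cov = cov, gh_nodes = gh_nodes
  ), class = "tte_fit")
}

# warn when a covariate perfectly orders events vs censored records
separation_check <- function(events, cov, bn) {
  evt <- events$status == 1
  if (!any(evt) || all(evt)) return(invisible())
  for (b in bn) {
    x <- cov[[b]]
    if (max(x[evt]) < min(x[!evt]) || min(x[evt]) > max(x[!evt]))
      warn(sprintf("covariate '%s' perfectly separates events from censored records", b))
  }
  invisible()
}

#' Simulate event/censoring records from the time-to-event model
#'
#' Draws event times by the inverse CDF: for the log-logistic family,
#' `t = Te_i (1/u - 1)^(1/s)` with `u ~ U(0,1)` (so `u = 0.5` returns the
#' individual median `Te_i` exactly); closed-form inverses are used for the
#' other families. Times past `censor_time` are recorded as censored at
#' `censor_time`.
#'
#' @param cov Data frame of per-subject covariates (needs a `subject`
#'   column; covariate columns as in [individual_scale()]).
#' @param p A [tte_params()]; frailty deviates are drawn when
#'   `p$omega_te > 0`.
#' @param censor_time Administrative censoring time, h (> 0). May be a
#'   vector (per subject).
#' @param medians Normalizing medians (see [individual_scale()]).
#' @param seed Optional seed (local to this call).
#' @return A tibble: `subject`, `time_h`, `status` (1 event, 0 censored).
#' @export
simulate_events <- function(cov, p, censor_time = 2400, medians = NULL,
                            seed = NULL) {
  stopifnot(all(censor_time > 0))
  cov <- tibble::as_tibble(cov)
  n <- nrow(cov)
  with_seed(seed, {
    eta <- if (p$omega_te > 0) rnorm(n, 0, p$omega_te) else rep(0, n)
    te_i <- individual_scale(cov, p, medians, eta = eta)
    u <- runif(n)
    t_ev <- switch(p$family,
      loglogistic = te_i * (1 / u - 1)^(1 / p$shape),
      weibull = te_i * (-log(u))^(1 / p$shape),
      gompertz = te_i / p$shape * log(1 - p$shape * log(u)),
      exponential = -te_i * log(u)
    )
    cens <- rep_len(censor_time, n)
    tibble::tibble(
      subject = if ("subject" %in% names(cov)) cov$subject else as.character(seq_len(n)),
      time_h = pmin(t_ev, cens),
      status = as.integer(t_ev <= cens)
    )
  })
}
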