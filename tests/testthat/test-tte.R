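test_that("log-logistic hazard has its closed-form values", {
  te <- 703.17
  expect_equal(surv_hazard(0, te, 4), 0)
  expect_equal(surv_hazard(te, te, 4), 2 / te)
  expect_equal(surv_hazard(0, te, 1), 1 / te)
  # unimodal for shape > 1: rises then falls
  h <- surv_hazard(seq(1, 5000, 1), te, 4)
  pk <- which.max(h)
  expect_true(all(diff(h[1:pk]) > 0) && all(diff(h[pk:length(h)]) < 0))
})

test_that("survival follows from the hazard and the scale is the median", {
  te <- 703.17
  expect_equal(surv_survival(0, te, 4), 1)
  # S(Te) = 1/2 exactly, at any shape: the scale is the median event time
  for (s in c(1, 2, 4, 7.3))
    expect_equal(surv_survival(te, te, s), 0.5)
  # quadrature of the hazard reproduces the closed-form survival, every
  # family; compared on the cumulative-hazard (log-survival) scale, where
  # the steep Gompertz tail stays representable
  for (fam in c("loglogistic", "weibull", "gompertz", "exponential")) {
    # the steep Gompertz tail drives S below double precision past ~1.3 Te
    tt <- if (fam == "gompertz") c(0.1, 0.5, 1, 1.2) * te
          else c(0.1, 0.5, 1, 1.5, 2) * te
    H_quad <- vapply(tt, function(t1)
      stats::integrate(function(u) surv_hazard(u, te, 4, fam), 0, t1,
                       rel.tol = 1e-12, subdivisions = 2000L)$value,
      numeric(1))
    H_closed <- -log(surv_survival(tt, te, 4, fam))
    expect_lt(max(abs(H_quad - H_closed) / (1 + H_closed)), 1e-8)
  }
})

test_that("the covariate model scales the median as specified", {
  p <- tte_params(te_pop = 703.17, beta = c(lambda0 = -0.75,
                                            lambda1 = -0.46, cavg = 0.63))
  med <- list(lambda0 = 0.0063, lambda1 = 5.93, cavg = 200)
  # all covariates at median, no exposure: scale is te_pop exactly
  cov0 <- data.frame(lambda0 = 0.0063, lambda1 = 5.93, cavg = 0)
  expect_equal(individual_scale(cov0, p, med), 703.17)
  # doubling lambda0 multiplies the scale by exp(beta_lambda0)
  cov1 <- data.frame(lambda0 = 2 * 0.0063, lambda1 = 5.93, cavg = 0)
  expect_equal(individual_scale(cov1, p, med), 703.17 * exp(-0.75))
  # exposure at the median multiplies by exp(0.63) ~ 1.878 (not centered)
  cov2 <- data.frame(lambda0 = 0.0063, lambda1 = 5.93, cavg = 200)
  expect_equal(individual_scale(cov2, p, med), 703.17 * exp(0.63))
  expect_equal(exp(0.63), 1.878, tolerance = 1e-3)
  expect_error(individual_scale(data.frame(lambda0 = 1), p, med), "missing")
})

test_that("censored log-likelihood matches hand-computed contributions", {
  p <- tte_params(te_pop = 500, shape = 4)
  # single censored subject: log S(t)
  ev_c <- data.frame(subject = "a", time_h = 600, status = 0)
  expect_equal(loglik_tte(p, ev_c), -log(1 + (600 / 500)^4))
  # single event at t = Te: log h + log S = log(2/Te) + log(1/2)
  ev_e <- data.frame(subject = "a", time_h = 500, status = 1)
  expect_equal(loglik_tte(p, ev_e), log(2 / 500) + log(0.5))
  expect_error(loglik_tte(p, data.frame(subject = "a", time_h = 0, status = 1)),
               "positive")
  # likelihood at larger Te is better for an all-censored dataset
  ev_all_c <- data.frame(subject = letters[1:4], time_h = 300, status = 0)
  expect_gt(loglik_tte(tte_params(5000), ev_all_c),
            loglik_tte(tte_params(500), ev_all_c))
  expect_error(fit_tte(ev_all_c), "at least one event")
})

test_that("censored ML recovers the scale and matches survreg", {
  set.seed(8)
  n <- 500
  cov <- data.frame(subject = as.character(1:n))
  p <- tte_params(te_pop = 700, shape = 4)
  ev <- simulate_events(cov, p, censor_time = 2400)
  fit <- fit_tte(ev)
  expect_equal(fit$te_pop, 700, tolerance = 0.05)
  # independent reference: survreg log-logistic with fixed scale 1/shape
  sr <- survival::survreg(survival::Surv(ev$time_h, ev$status) ~ 1,
                          dist = "loglogistic", scale = 1 / 4)
  expect_equal(fit$te_pop, unname(exp(coef(sr)[1])), tolerance = 1e-3)

  # with covariates: coefficients match survreg and carry the right signs
  gen <- generate_events(seed = 15)
  f2 <- fit_tte(gen$events, gen$covariates, medians = gen$medians)
  x <- gen$covariates[match(gen$events$subject, gen$covariates$subject), ]
  sr2 <- survival::survreg(
    survival::Surv(gen$events$time_h, gen$events$status) ~
      I(x$lambda0 / gen$medians$lambda0 - 1) +
      I(x$lambda1 / gen$medians$lambda1 - 1) +
      I(x$cavg / gen$medians$cavg),
    dist = "loglogistic", scale = 1 / 4)
  expect_equal(unname(f2$beta), unname(coef(sr2)[-1]), tolerance = 0.01)
  expect_lt(f2$beta["lambda0"], 0)
  expect_lt(f2$beta["lambda1"], 0)
  expect_gt(f2$beta["cavg"], 0)
})

test_that("family screening prefers the generating hazard by AIC", {
  set.seed(9)
  cov <- data.frame(subject = as.character(1:300))
  ev <- simulate_events(cov, tte_params(te_pop = 700, shape = 4),
                        censor_time = 2400)
  f_ll <- fit_tte(ev, family = "loglogistic", estimate_shape = TRUE)
  f_ex <- fit_tte(ev, family = "exponential")
  f_wb <- fit_tte(ev, family = "weibull", estimate_shape = TRUE)
  cmp <- compare_models(loglogistic = f_ll, weibull = f_wb, exponential = f_ex)
  expect_equal(cmp$model[1], "loglogistic")
})

test_that("event simulation has the documented inverse-CDF properties", {
  cov <- data.frame(subject = as.character(1:4000))
  p <- tte_params(te_pop = 650, shape = 4)
  ev <- simulate_events(cov, p, censor_time = 1e6, seed = 77)
  # empirical median converges to the scale for homogeneous subjects
  expect_equal(median(ev$time_h), 650, tolerance = 0.05)
  expect_true(all(ev$status == 1))
  # tiny censoring window censors everyone
  ev0 <- simulate_events(cov, p, censor_time = 1e-6, seed = 77)
  expect_true(all(ev0$status == 0))
  expect_true(all(ev0$time_h == 1e-6))
  # seeded determinism without disturbing the ambient RNG stream
  a <- simulate_events(cov, p, censor_time = 2400, seed = 5)
  b <- simulate_events(cov, p, censor_time = 2400, seed = 5)
  expect_identical(a, b)
})

test_that("rescaling time rescales the scale estimate and shifts -2LL by the Jacobian", {
  set.seed(10)
  cov <- data.frame(subject = as.character(1:200))
  ev <- simulate_events(cov, tte_params(te_pop = 700, shape = 4),
                        censor_time = 2400)
  f1 <- fit_tte(ev)
  ev2 <- dplyr::mutate(ev, time_h = time_h * 24)
  f2 <- fit_tte(ev2)
  expect_equal(f2$te_pop, 24 * f1$te_pop, tolerance = 1e-4)
  # each event density picks up a 1/24 Jacobian factor
  expect_equal(f2$m2ll - f1$m2ll, 2 * sum(ev$status) * log(24),
               tolerance = 1e-4)
})

test_that("frailty estimation stays near zero when the truth is near zero", {
  gen <- generate_events(seed = 23)
  f <- fit_tte(gen$events, gen$covariates, medians = gen$medians,
               frailty = "estimate")
  expect_gte(f$omega_te, 1e-4)
  expect_lt(f$omega_te, 0.5)
  expect_equal(f$te_pop, 703.17, tolerance = 0.15)
})
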