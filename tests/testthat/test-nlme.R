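test_that("log-normal IIV maps etas to individual parameters", {
  pop <- default_population()
  # eta = 0 reproduces the typical values exactly
  ip <- individual_params(pop, data.frame(lambda0 = 0, lambda1 = 0, kill = 0))
  expect_equal(unlist(ip), pop$theta, ignore_attr = TRUE)
  # reported CV% for omega = 0.85 is 100 sqrt(exp(w^2)-1) ~ 102.8 (printed
  # tables round the omega, so agreement is to ~0.2 percent)
  expect_equal(100 * sqrt(exp(0.85^2) - 1), 102.82, tolerance = 2e-3)
  # large-sample mean of log p_i - log p_pop is 0 within MC error
  set.seed(3)
  eta <- data.frame(lambda0 = rnorm(2e4, 0, 0.85))
  ip <- individual_params(pop, eta)
  expect_equal(mean(log(ip$lambda0) - log(pop$theta["lambda0"])), 0,
               tolerance = 0.02)
  expect_true(all(ip$lambda0 > 0))
})

test_that("residual error model combines additive and proportional parts", {
  res <- c(a = 11.22, b = 0.22)
  expect_equal(residual_sd(0, res), 11.22)
  expect_equal(residual_sd(c(10, 400), c(a = 5, b = 0)), c(5, 5))
  # pure proportional scales linearly
  expect_equal(residual_sd(200, c(a = 0, b = 0.22), "proportional"),
               2 * residual_sd(100, c(a = 0, b = 0.22), "proportional"))
  expect_error(residual_sd(-1, res), "non-negative")
})

test_that("shrinkage measures collapse of the EBE distribution", {
  set.seed(5)
  eta <- rnorm(200, 0, 0.8)
  expect_equal(shrinkage_pct(eta, sd(eta)), 0)
  expect_equal(shrinkage_pct(rep(0, 50), 0.8), 100)
  # more shrinkage when the EBEs are pulled harder toward zero
  expect_gt(shrinkage_pct(0.3 * eta, 0.8), shrinkage_pct(0.9 * eta, 0.8))
  expect_error(shrinkage_pct(eta, 0), "positive")
})

test_that("population fit recovers a noise-free study within a percent", {
  pop0 <- population_model(
    theta = c(lambda0 = 0.0063, lambda1 = 5.93, kill = 2.4e-5),
    omega = c(lambda0 = 1e-3, lambda1 = 1e-3, kill = 1e-3),
    residual = c(a = 0.5, b = 0.001))
  st <- generate_study(default_design(c(6, 4, 4, 4, 4, 4)), pop0, pk_params(),
                       seed = 5)
  fit <- fit_tgi(st, pk_params(), control = tgi_control(mcem_iter = 0))
  expect_equal(unname(fit$theta["lambda0"]), 0.0063, tolerance = 0.01)
  expect_equal(unname(fit$theta["lambda1"]), 5.93, tolerance = 0.01)
  expect_equal(unname(fit$theta["kill"]), 2.4e-5, tolerance = 0.01)
  expect_true(fit$aic > fit$m2ll)
  expect_equal(fit$aic, fit$m2ll + 2 * fit$n_par)
})

test_that("two-stage fitting is deterministic and tidy/glance are consistent", {
  st <- small_study(seed = 11, n = c(3, 2, 2, 2, 2, 2))
  ctl <- tgi_control(maxit = 6, mcem_iter = 2, mcem_draws = 40, ll_nsim = 50)
  f1 <- fit_tgi(st, pk_params(), control = ctl)
  f2 <- fit_tgi(st, pk_params(), control = ctl)
  expect_identical(f1$theta, f2$theta)
  expect_identical(f1$m2ll, f2$m2ll)
  td <- tidy(f1)
  expect_true(all(c("term", "estimate", "rse_pct", "iiv_cv_pct",
                    "shrinkage_pct") %in% names(td)))
  expect_equal(glance(f1)$n_subjects, 13)
  expect_equal(td$estimate[td$term == "lambda0"],
               unname(f1$theta["lambda0"]))
})

test_that("marginal likelihood matches Gauss-Hermite quadrature on a toy set", {
  skip_if_not_installed("pracma")
  pop <- population_model(
    theta = c(lambda0 = 0.0063, lambda1 = 5.93),
    omega = c(lambda0 = 0.4, lambda1 = 0.3),
    residual = c(a = 8, b = 0.15))
  des <- default_design(c(3, 1, 1, 1, 1, 1))
  des$arms <- des$arms[1, ]  # controls only: 2-d random effect
  st <- generate_study(des, pop, pk_params(), seed = 21)
  pk <- pk_params()
  subj <- tgitte:::build_subjects(st, pk)
  pn <- c("lambda0", "lambda1")
  mu <- log(pop$theta[pn]); omega <- pop$omega[pn]; res <- pop$residual
  ctl <- tgi_control(ll_nsim = 4000)
  eta <- matrix(0, 3, 2); Vs <- vector("list", 3)
  for (i in 1:3) {
    f <- tgitte:::map_fit_subject(subj[[i]], mu, omega, res["a"], res["b"],
                                  pn, 0L, 0, pk$ke, 2)
    eta[i, ] <- f$par
    Vs[[i]] <- tgitte:::laplace_cov(f$par, subj[[i]], mu, omega, res["a"],
                                    res["b"], pn, 0L, 0, pk$ke, 2)
  }
  m2ll_is <- tgitte:::marginal_m2ll(subj, mu, omega, res, pn, 0L, 0, pk$ke, 2,
                                    eta, Vs, ctl)
  # oracle: adaptive (MAP-centered) tensor Gauss-Hermite, 25 nodes per axis
  gh <- pracma::gaussHermite(25)
  ll <- 0
  for (i in 1:3) {
    sdq <- sqrt(pmax(diag(Vs[[i]]), 1e-10))
    nodes1 <- eta[i, 1] + sqrt(2) * sdq[1] * gh$x
    nodes2 <- eta[i, 2] + sqrt(2) * sdq[2] * gh$x
    Li <- 0
    ni <- length(subj[[i]]$y) - 1
    for (a1 in seq_along(nodes1)) for (a2 in seq_along(nodes2)) {
      e <- c(nodes1[a1], nodes2[a2])
      pred <- tgitte:::subj_pred(subj[[i]], mu + e, pn, 0L, 0, pk$ke, 2)
      integrand <- exp(-0.5 * (tgitte:::neg2ll_data(subj[[i]]$y, pred,
                                                    res["a"], res["b"]) +
                                 ni * log(2 * pi))) *
        prod(dnorm(e, 0, omega))
      Li <- Li + gh$w[a1] * gh$w[a2] * integrand *
        exp(sum((e - eta[i, ])^2 / (2 * sdq^2))) * 2 * prod(sdq)
    }
    ll <- ll + log(Li)
  }
  expect_equal(m2ll_is, -2 * ll, tolerance = 0.5 / abs(2 * ll))
})

test_that("empirical-Bayes estimates behave with rich, sparse and control data", {
  pop <- population_model(
    theta = c(lambda0 = 0.0063, lambda1 = 5.93, kill = 2.4e-5),
    omega = c(lambda0 = 0.5, lambda1 = 0.4, kill = 0.5),
    residual = c(a = 2, b = 0.04))  # low noise: EBEs near per-subject truth
  st <- generate_study(default_design(c(4, 2, 2, 2, 2, 2)), pop, pk_params(),
                       seed = 31)
  fit <- fit_tgi(st, pk_params(), init = pop,
                 control = tgi_control(maxit = 4, mcem_iter = 0, ll_nsim = 50))
  eb <- empirical_bayes(st, fit)
  m <- dplyr::inner_join(eb, st$truth, by = c("subject", "arm"),
                         suffix = c("_hat", "_true"))
  treated <- m$arm != "vehicle"
  # dense low-noise data: individual lambda0 within ~15 percent of truth
  expect_lt(median(abs(m$lambda0_hat / m$lambda0_true - 1)), 0.15)
  # controls carry no kill information: EBE collapses to the typical value
  ctrl <- m$arm == "vehicle"
  expect_equal(m$kill_hat[ctrl], rep(unname(fit$theta["kill"]), sum(ctrl)),
               tolerance = 1e-4)
  # mean eta over a correctly specified population is near zero
  expect_lt(abs(mean(eb$eta_lambda0)), 0.25)
})

test_that("a subject reduced to sparse data shrinks toward the population", {
  pop <- population_model(
    theta = c(lambda0 = 0.0063, lambda1 = 5.93, kill = 2.4e-5),
    omega = c(lambda0 = 0.6, lambda1 = 0.5, kill = 0.6),
    residual = c(a = 5, b = 0.1))
  st <- generate_study(default_design(c(6, 1, 1, 1, 1, 1)), pop, pk_params(),
                       seed = 41)
  fit <- structure(list(theta = pop$theta, omega = pop$omega,
                        residual = pop$residual, error_model = "combined",
                        growth = "simeoni", kc50 = 0, pk = pk_params(),
                        control = tgi_control(), ebes = TRUE),
                   class = "tgi_fit")
  eb_dense <- empirical_bayes(st, fit)
  st2 <- st
  # keep only the baseline and one later observation per subject
  st2$observations <- dplyr::ungroup(
    dplyr::slice(dplyr::group_by(st2$observations, subject),
                 unique(c(1, dplyr::n()))))
  eb_sparse <- suppressWarnings(empirical_bayes(st2, fit))
  expect_lt(sd(eb_sparse$eta_lambda0), sd(eb_dense$eta_lambda0) + 1e-9)
  expect_gt(shrinkage_pct(eb_sparse$eta_lambda0, 0.6),
            shrinkage_pct(eb_dense$eta_lambda0, 0.6))
})

test_that("model comparison ranks the generating growth structure first", {
  st <- small_study(seed = 13, n = c(6, 2, 2, 2, 2, 2))
  ctl <- tgi_control(maxit = 6, mcem_iter = 0, ll_nsim = 150)
  f_sim <- fit_tgi(st, pk_params(), growth = "simeoni", control = ctl)
  f_exp <- fit_tgi(st, pk_params(), growth = "exponential", control = ctl)
  cmp <- compare_models(simeoni = f_sim, exponential = f_exp)
  expect_equal(cmp$model[1], "simeoni")
  expect_equal(cmp$delta_aic[1], 0)
  expect_gt(cmp$delta_aic[2], 0)
  # identical fits tie at delta AIC 0
  cmp2 <- compare_models(a = f_sim, b = f_sim)
  expect_equal(cmp2$delta_aic, c(0, 0))
})

test_that("SAEM mode agrees with the deterministic mode on a small study", {
  st <- small_study(seed = 17, n = c(4, 2, 2, 2, 2, 2))
  ctl <- tgi_control(maxit = 8, mcem_iter = 3, mcem_draws = 60,
                     saem_burn = 60, saem_smooth = 40, ll_nsim = 60, seed = 2L)
  f_em <- fit_tgi(st, pk_params(), control = ctl)
  f_sa <- fit_tgi(st, pk_params(), mode = "saem", control = ctl)
  # same data, same model: typical values agree to well within their spread
  for (p in names(f_em$theta))
    expect_equal(unname(f_sa$theta[p]), unname(f_em$theta[p]),
                 tolerance = 0.5)
  # seeded determinism
  f_sa2 <- fit_tgi(st, pk_params(), mode = "saem", control = ctl)
  expect_identical(f_sa$theta, f_sa2$theta)
})
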