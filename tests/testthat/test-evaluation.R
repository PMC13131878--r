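test_that("Kaplan-Meier estimator matches hand-computed product limits", {
  # four events, no censoring: 0.75, 0.5, 0.25, 0
  km <- km_curve(data.frame(time_h = 1:4, status = 1))
  expect_equal(km$survival[km$n_event > 0], c(0.75, 0.5, 0.25, 0))
  # events at 2 and 4, censored at 3, 5, 6
  km2 <- km_curve(data.frame(time_h = c(2, 4, 3, 5, 6),
                             status = c(1, 1, 0, 0, 0)))
  ev <- km2[km2$n_event > 0, ]
  expect_equal(ev$survival, c(0.8, 0.8 * (1 - 1 / 3)))
  # all censored: flat at one
  km3 <- km_curve(data.frame(time_h = c(5, 7), status = 0))
  expect_true(all(km3$survival == 1))
})

test_that("Kaplan-Meier matches a brute-force oracle on exhaustive small instances", {
  # every censoring pattern over 6 subjects with distinct times, plus tied
  # configurations over 5 subjects
  for (n in c(6)) {
    times <- seq_len(n)
    for (mask in 0:(2^n - 1)) {
      status <- as.integer(intToBits(mask)[1:n])
      if (sum(status) == 0) next
      km <- km_curve(data.frame(time_h = times, status = status))
      oracle <- km_brute(times, status)
      got <- km$survival[km$n_event > 0]
      expect_equal(unname(got), oracle$surv)
      expect_equal(km$time_h[km$n_event > 0], oracle$time)
    }
  }
  set.seed(14)
  for (r in 1:25) {
    times <- sample(1:3, 5, replace = TRUE)
    status <- sample(0:1, 5, replace = TRUE)
    if (sum(status) == 0) next
    km <- km_curve(data.frame(time_h = times, status = status))
    oracle <- km_brute(times, status)
    expect_equal(unname(km$survival[km$n_event > 0]), oracle$surv)
  }
})

test_that("KM curves are non-increasing and arm-stratified", {
  gen <- generate_events(seed = 31)
  km <- km_curve(gen$events)
  for (a in unique(km$arm))
    expect_true(all(diff(km$survival[km$arm == a]) <= 1e-12))
  expect_setequal(unique(km$arm), unique(gen$events$arm))
})

test_that("the VPC band is deterministic, ordered, and calibrated on its own model", {
  gen <- generate_events(seed = 31)
  fit <- fit_tte(gen$events, gen$covariates, medians = gen$medians)
  arms <- gen$events[, c("subject", "arm")]
  v1 <- vpc_tte(fit, arms = arms, n_sim = 300, seed = 9)
  v2 <- vpc_tte(fit, arms = arms, n_sim = 300, seed = 9)
  expect_identical(v1, v2)
  expect_true(all(v1$pred_lo_S <= v1$pred_median_S + 1e-12))
  expect_true(all(v1$pred_median_S <= v1$pred_hi_S + 1e-12))
  # observed data were generated by (nearly) the fitted model: the observed
  # KM should sit inside the 90 percent band at ~90 percent of grid points
  inside <- v1$observed_S >= v1$pred_lo_S - 1e-12 &
    v1$observed_S <= v1$pred_hi_S + 1e-12
  expect_gte(mean(inside), 0.85)
  expect_warning(vpc_tte(fit, arms = arms, n_sim = 50, seed = 9), "n_sim")
})

test_that("bootstrap machinery resamples, stratifies and collapses correctly", {
  # identical subjects: the interval collapses onto the point estimate
  subj <- data.frame(subject = as.character(1:12), x = 5,
                     arm = rep(c("a", "b"), 6))
  bc <- bootstrap_ci(subj, function(d) c(m = mean(d$x)), n_boot = 50, seed = 3)
  expect_equal(bc$lo, 5)
  expect_equal(bc$hi, 5)
  # stratified resampling preserves per-arm counts in every replicate
  counts <- bootstrap_ci(subj, function(d) c(n_a = sum(d$arm == "a"),
                                             n_b = sum(d$arm == "b")),
                         n_boot = 40, strata = "arm", seed = 3)
  expect_equal(counts$lo, c(6, 6))
  expect_equal(counts$hi, c(6, 6))
  # determinism
  subj$x <- rnorm(12)
  b1 <- bootstrap_ci(subj, function(d) c(m = mean(d$x)), n_boot = 60, seed = 5)
  b2 <- bootstrap_ci(subj, function(d) c(m = mean(d$x)), n_boot = 60, seed = 5)
  expect_identical(b1, b2)
  # failing refits are counted and excluded
  flaky <- function(d) if (mean(d$x) > median(subj$x)) stop("no") else c(m = 1)
  bf <- suppressWarnings(bootstrap_ci(subj, flaky, n_boot = 40, seed = 5))
  expect_gt(bf$n_fail[1], 0)
  expect_equal(bf$n_ok[1] + bf$n_fail[1], 40)
})

test_that("bootstrap intervals cover the truth at roughly the nominal rate", {
  # scaled-down outer replication: 30 studies x 120 resamples, scale-only fit
  te_true <- 650
  n_outer <- 30
  covered <- logical(n_outer)
  for (r in seq_len(n_outer)) {
    cov <- data.frame(subject = as.character(1:40))
    ev <- simulate_events(cov, tte_params(te_pop = te_true, shape = 4),
                          censor_time = 2400, seed = 1000 + r)
    bc <- bootstrap_ci(ev, function(d) c(te = fit_tte(d)$te_pop),
                       n_boot = 120, seed = r)
    covered[r] <- bc$lo[1] <= te_true && te_true <= bc$hi[1]
  }
  expect_gte(mean(covered), 0.8)  # ~95 percent nominal, small-sample slack
})

test_that("goodness-of-fit tables standardize the residuals", {
  pop <- default_population()
  st <- generate_study(default_design(c(8, 6, 6, 6, 6, 6)), pop, pk_params(),
                       seed = 19)
  # anchor the regressor at the latent baseline so the evaluation model is
  # exactly the generating model, then evaluate residuals at the generating
  # parameters with the true etas: IWRES must be standard-normal-ish
  first <- !duplicated(st$observations$subject)
  st$observations$tv_mm3[first] <-
    st$truth$tv0_true[match(st$observations$subject[first], st$truth$subject)]
  truth_fit <- structure(list(
    theta = pop$theta, omega = pop$omega, residual = pop$residual,
    error_model = "combined", growth = "simeoni", kc50 = 0, pk = pk_params(),
    control = tgi_control(hmax = 0.5), n_subjects = 38,
    ebes = dplyr::transmute(st$truth, subject, arm,
                            lambda0, lambda1, kill,
                            eta_lambda0, eta_lambda1, eta_kill,
                            tv0 = tv0_obs)), class = "tgi_fit")
  g <- gof_tables(st, truth_fit)
  expect_true(all(c("observed", "pred_pop", "pred_ind", "iwres") %in% names(g)))
  expect_lt(abs(mean(g$iwres)), 0.1)
  expect_true(sd(g$iwres) > 0.9 && sd(g$iwres) < 1.1)
  # population predictions scatter wider than individual ones under IIV
  expect_gt(sd(log(g$observed / g$pred_pop)), sd(log(g$observed / g$pred_ind)))
})

test_that("noise-free data fitted at the truth give zero residuals", {
  pop0 <- population_model(
    theta = c(lambda0 = 0.0063, lambda1 = 5.93, kill = 2.4e-5),
    omega = c(lambda0 = 1e-6, lambda1 = 1e-6, kill = 1e-6),
    residual = c(a = 1e-6, b = 1e-8))
  st <- generate_study(default_design(c(3, 1, 1, 1, 1, 1)), pop0, pk_params(),
                       seed = 2)
  truth_fit <- structure(list(
    theta = pop0$theta, omega = pop0$omega,
    residual = c(a = 1, b = 0),  # unit sd so iwres equals the raw residual
    error_model = "combined", growth = "simeoni", kc50 = 0, pk = pk_params(),
    control = tgi_control(hmax = 0.5),
    ebes = dplyr::transmute(st$truth, subject, arm, lambda0, lambda1, kill,
                            eta_lambda0, eta_lambda1, eta_kill)),
    class = "tgi_fit")
  g <- gof_tables(st, truth_fit)
  expect_lt(max(abs(g$iwres)), 0.01)
})
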