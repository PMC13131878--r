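#' Kaplan-Meier survival curve
#'
#' Product-limit estimate of the survivor function, optionally stratified by
#' arm. Computation is delegated to [survival::survfit()]; this wrapper
#' returns a tidy step-function table.
#'
#' @param events Data frame: `time_h`, `status` (1 event / 0 censored),
#'   optionally `arm` and `subject`.
#' @param by_arm Stratify by the `arm` column when present (default `TRUE`).
#' @return A tibble of class `km_curve`: `arm`, `time_h`, `n_risk`,
#'   `n_event`, `n_censor`, `survival`. The step starts at
#'   `(0, 1)` implicitly; rows appear at every observed time.
#' @examples
#' km_curve(data.frame(time_h = c(1, 2, 3, 4), status = 1))
#' @export
km_curve <- function(events, by_arm = TRUE) {
  events <- tibble::as_tibble(events)
  if (!nrow(events)) abort("`events` is empty")
  df <- data.frame(
    time = events$time_h, status = events$status,
    arm = if (by_arm && "arm" %in% names(events)) events$arm else "all")
  sf <- survival::survfit(survival::Surv(time, status) ~ arm, data = df,
                          se.fit = FALSE)
  smry <- summary(sf, censored = TRUE)
  strata <- if (is.null(smry$strata)) factor(rep("arm=all", length(smry$time)))
            else smry$strata
  out <- tibble::tibble(
    arm = sub("^arm=", "", as.character(strata)),
    time_h = smry$time,
    n_risk = smry$n.risk,
    n_event = smry$n.event,
    n_censor = smry$n.censor,
    survival = smry$surv
  )
  structure(out, class = c("km_curve", class(tibble::tibble())))
}

# right-continuous step-function evaluation of a KM curve on a grid
km_eval <- function(km_times, km_surv, grid) {
  if (!length(km_times)) return(rep(1, length(grid)))
  idx <- findInterval(grid, km_times)
  c(1, km_surv)[idx + 1]
}

#' Kaplan-Meier visual predictive check for the time-to-event model
#'
#' Simulates `n_sim` replicate studies from a fitted time-to-event model
#' (same subjects, covariates and per-subject censoring times as the
#' original design), computes a Kaplan-Meier curve per replicate and arm,
#' and returns the pointwise median and a 90 percent (by default)
#' prediction band on a common time grid, alongside the observed curve.
#'
#' @param fit A `tte_fit`.
#' @param arms Optional data frame `subject`, `arm` used to stratify;
#'   default: an `arm` column carried by the fitted events, else one stratum.
#' @param censor_time Per-subject administrative censoring times for the
#'   simulations; default: each subject's observed censoring time for
#'   censored records and the maximum observed time for events.
#' @param n_sim Number of simulated studies (default 1000; values below 100
#'   trigger a warning).
#' @param probs Lower/upper band probabilities (default `c(0.05, 0.95)`).
#' @param grid Common time grid; default 61 points from 0 to the maximum
#'   observed time.
#' @param seed Seed for the simulations (local to this call).
#' @return A tibble of class `vpc_band`: `arm`, `time_h`, `observed_S`,
#'   `pred_median_S`, `pred_lo_S`, `pred_hi_S`.
#' @export
vpc_tte <- function(fit, arms = NULL, censor_time = NULL, n_sim = 1000,
                    probs = c(0.05, 0.95), grid = NULL, seed = 1L) {
  if (n_sim < 100) warn("n_sim < 100 gives unstable prediction bands")
  events <- fit$events
  cov <- fit$cov
  cov$subject <- if ("subject" %in% names(events)) events$subject
                 else as.character(seq_len(nrow(events)))
  arm <- if (!is.null(arms)) arms$arm[match(events$subject, arms$subject)]
         else if ("arm" %in% names(events)) events$arm
         else rep("all", nrow(events))
  if (is.null(censor_time))
    censor_time <- ifelse(events$status == 0, events$time_h, max(events$time_h))
  grid <- grid %||% seq(0, max(events$time_h), length.out = 61)
  p <- tte_params(fit$te_pop, fit$shape, fit$beta, fit$omega_te, fit$family)

  arms_u <- unique(arm)
  seeds <- child_seeds(seed, n_sim)
  sims <- array(NA_real_, c(n_sim, length(arms_u), length(grid)),
                dimnames = list(NULL, arms_u, NULL))
  for (s in seq_len(n_sim)) {
    ev <- simulate_events(cov, p, censor_time = censor_time,
                          medians = fit$medians, seed = seeds[s])
    for (a in arms_u) {
      sel <- arm == a
      sf <- survival::survfit(
        survival::Surv(ev$time_h[sel], ev$status[sel]) ~ 1, se.fit = FALSE)
      et <- sf$time[sf$n.event > 0]
      es <- sf$surv[sf$n.event > 0]
      sims[s, a, ] <- km_eval(et, es, grid)
    }
  }
  obs_km <- km_curve(dplyr::mutate(events, arm = arm), by_arm = TRUE)
  out <- purrr::map_dfr(arms_u, function(a) {
    oa <- dplyr::filter(obs_km, .data$arm == a, .data$n_event > 0)
    tibble::tibble(
      arm = a, time_h = grid,
      observed_S = km_eval(oa$time_h, oa$survival, grid),
      pred_median_S = apply(sims[, a, , drop = FALSE], 3, median),
      pred_lo_S = apply(sims[, a, , drop = FALSE], 3, quantile, probs[1]),
      pred_hi_S = apply(sims[, a, , drop = FALSE], 3, quantile, probs[2])
    )
  })
  structure(out, class = c("vpc_band", class(tibble::tibble())),
            n_sim = n_sim, probs = probs)
}

#' Subject-resampling bootstrap confidence intervals
#'
#' Resamples subjects with replacement (within arm when `strata` is given),
#' refits with `fit_fn`, and returns per-parameter percentile intervals.
#' Replicates whose refit throws an error are dropped from the percentiles;
#' their count is reported, with a warning above 10 percent.
#'
#' @param subjects A data frame with one row per subject (any columns;
#'   passed to `fit_fn` after resampling). Row order defines the subjects.
#' @param fit_fn Function taking the resampled subject table and returning a
#'   named numeric vector of estimates.
#' @param n_boot Number of bootstrap replicates (default 1000).
#' @param strata Optional column name to stratify resampling by (per-stratum
#'   subject counts are preserved in every replicate).
#' @param seed Seed (local to this call).
#' @param probs Interval probabilities (default `c(0.025, 0.975)`).
#' @return A tibble of class `boot_ci`: `term`, `median`, `lo`, `hi`,
#'   `n_ok`, `n_fail`.
#' @export
bootstrap_ci <- function(subjects, fit_fn, n_boot = 1000, strata = NULL,
                         seed = 1L, probs = c(0.025, 0.975)) {
  subjects <- tibble::as_tibble(subjects)
  n <- nrow(subjects)
  if (!is.null(strata)) {
    groups <- split(seq_len(n), subjects[[strata]])
    if (any(lengths(groups) < 2)) abort("need >= 2 subjects per stratum")
  } else {
    groups <- list(seq_len(n))
  }
  seeds <- child_seeds(seed, n_boot)
  reps <- vector("list", n_boot)
  for (b in seq_len(n_boot)) {
    idx <- with_seed(seeds[b],
      unlist(lapply(groups, function(g) sample(g, length(g), replace = TRUE))))
    # assign via [<- so a failed (NULL) replicate does not shrink the list
    reps[b] <- list(tryCatch(fit_fn(subjects[idx, , drop = FALSE]),
                             error = function(e) NULL))
  }
  ok <- !vapply(reps, is.null, logical(1))
  n_fail <- sum(!ok)
  if (n_fail > 0.1 * n_boot)
    warn(sprintf("%d of %d bootstrap refits failed", n_fail, n_boot))
  if (!any(ok)) abort("all bootstrap refits failed")
  mat <- do.call(rbind, reps[ok])
  out <- tibble::tibble(
    term = colnames(mat),
    median = unname(apply(mat, 2, median)),
    lo = unname(apply(mat, 2, quantile, probs[1])),
    hi = unname(apply(mat, 2, quantile, probs[2])),
    n_ok = sum(ok), n_fail = n_fail
  )
  structure(out, class = c("boot_ci", class(tibble::tibble())))
}

#' Bootstrap a fitted time-to-event model
#'
#' Convenience wrapper around [bootstrap_ci()]: resamples subjects (with
#' their covariates) stratified by arm when available, refitting with the
#' original estimates as starting values.
#'
#' @param fit A `tte_fit`.
#' @param n_boot,seed,probs Passed to [bootstrap_ci()].
#' @param stratify_by_arm Stratify resampling by the `arm` column of the
#'   fitted events when present (default `TRUE`).
#' @return A `boot_ci` tibble.
#' @export
bootstrap_tte <- function(fit, n_boot = 1000, seed = 1L,
                          probs = c(0.025, 0.975), stratify_by_arm = TRUE) {
  tab <- dplyr::bind_cols(fit$events, fit$cov[setdiff(names(fit$cov), names(fit$events))])
  strata <- if (stratify_by_arm && "arm" %in% names(tab)) "arm" else NULL
  init <- list(te_pop = fit$te_pop, beta = fit$beta,
               omega_te = fit$omega_te, shape = fit$shape)
  bn <- names(fit$beta)
  fit_fn <- function(d) {
    cov <- if (length(bn)) d[, c(intersect("subject", names(d)), bn)] else NULL
    f <- fit_tte(d[, c(intersect(c("subject", "arm"), names(d)), "time_h", "status")],
                 covariates = cov, family = fit$family, shape = fit$shape,
                 frailty = fit$frailty, medians = fit$medians, init = init,
                 gh_nodes = fit$gh_nodes)
    f$estimates
  }
  bootstrap_ci(tab, fit_fn, n_boot = n_boot, strata = strata, seed = seed,
               probs = probs)
}

#' Goodness-of-fit table for a population TGI fit
#'
#' Observed volumes against population predictions (typical parameters) and
#' individual predictions (empirical-Bayes parameters), plus individual
#' weighted residuals `IWRES = (obs - ipred) / sd(ipred)`. Baseline rows are
#' excluded (the baseline is a regressor, so both predictions equal the
#' observation there).
#'
#' @param study A study object.
#' @param fit A `tgi_fit` with EBEs.
#' @return A tibble: `subject`, `arm`, `time_h`, `observed`, `pred_pop`,
#'   `pred_ind`, `iwres`.
#' @export
gof_tables <- function(study, fit) {
  if (is.null(fit$ebes)) abort("fit carries no empirical-Bayes estimates")
  subjects <- build_subjects(study, fit$pk)
  pn <- names(fit$theta)
  model_code <- growth_model_code(fit$growth)
  mu <- log(fit$theta)
  purrr::map_dfr(subjects, function(s) {
    if (length(s$t) < 2) return(NULL)
    eb <- fit$ebes[fit$ebes$subject == s$subject, ]
    if (!nrow(eb)) abort(sprintf("no EBEs for subject %s", s$subject))
    eta_i <- as.numeric(eb[1, paste0("eta_", pn)])
    f_pop <- subj_pred(s, mu, pn, model_code, fit$kc50, fit$pk$ke,
                       fit$control$hmax)
    f_ind <- subj_pred(s, mu + eta_i, pn, model_code, fit$kc50, fit$pk$ke,
                       fit$control$hmax)
    sdv <- residual_sd(f_ind, fit$residual, fit$error_model)
    tibble::tibble(
      subject = s$subject, arm = s$arm, time_h = s$t[-1],
      observed = s$y[-1], pred_pop = f_pop[-1], pred_ind = f_ind[-1],
      iwres = (s$y[-1] - f_ind[-1]) / pmax(sdv[-1], 1e-8)
    )
  })
}
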