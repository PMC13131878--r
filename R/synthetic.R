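#' Define a xenograft study design
#'
#' A design couples dosing regimens with arm sizes, the baseline-volume
#' range, the observation schedule (daily during the dosing period, then
#' twice weekly with alternating 72/96 h gaps), the survival endpoint
#' threshold and the study horizon.
#'
#' @param arms A data frame with columns `arm` (regimen preset name or
#'   label), `n` (mice per arm); or use [default_design()].
#' @param regimens Named list of [regimen()] objects keyed by arm label;
#'   default: [regimen_preset()] applied to the arm labels.
#' @param baseline_range Length-2 range of baseline volumes, mm3
#'   (default `c(37, 251)`).
#' @param horizon_h Study horizon, h (default 2400, i.e. 100 days).
#' @param threshold Event threshold, mm3 (default 1500).
#' @param twice_weekly_gaps Post-dosing observation gaps, h (default
#'   `c(72, 96)` alternating).
#' @return An object of class `study_design`.
#' @export
study_design <- function(arms, regimens = NULL, baseline_range = c(37, 251),
                         horizon_h = 2400, threshold = 1500,
                         twice_weekly_gaps = c(72, 96)) {
  arms <- tibble::as_tibble(arms)
  if (!all(c("arm", "n") %in% names(arms))) abort("`arms` needs columns arm, n")
  if (any(arms$n < 1)) abort("every arm needs at least one mouse")
  regimens <- regimens %||%
    setNames(lapply(arms$arm, regimen_preset), arms$arm)
  if (!all(arms$arm %in% names(regimens)))
    abort("every arm needs a regimen")
  last_dose <- max(c(0, unlist(lapply(regimens, function(r) r$dose_times))))
  if (horizon_h <= last_dose) abort("horizon must exceed the last dose time")
  if (threshold <= max(baseline_range))
    abort("threshold must exceed the largest baseline volume")
  structure(list(arms = arms, regimens = regimens,
                 baseline_range = baseline_range, horizon_h = horizon_h,
                 threshold = threshold, twice_weekly_gaps = twice_weekly_gaps),
            class = "study_design")
}

#' Default 104-mouse study design
#'
#' Six arms emulating a three-experiment xenograft efficacy program:
#' vehicle (n = 24, pooled controls) and 0.3 / 0.6 / 0.9 mg/kg Q1dx5,
#' 2.40 mg/kg Q3dx6, 2.85 mg/kg BIWx6 (n = 16 each), for 104 mice total.
#' Baselines uniform on 37-251 mm3, observations daily through the dosing
#' period then twice weekly to day 100, event at 1500 mm3.
#'
#' @param n_per_arm Optional length-6 integer vector overriding the arm
#'   sizes (vehicle first).
#' @return A [study_design()].
#' @export
default_design <- function(n_per_arm = c(24, 16, 16, 16, 16, 16)) {
  arms <- tibble::tibble(
    arm = c("vehicle", "0.3 Q1dx5", "0.6 Q1dx5", "0.9 Q1dx5",
            "2.40 Q3dx6", "2.85 BIWx6"),
    n = as.integer(n_per_arm)
  )
  study_design(arms)
}

# observation schedule for one arm: daily through the dosing period (vehicle
# follows the shortest treated window, 96 h), then alternating 72/96 h gaps
schedule_times <- function(reg, horizon_h, gaps = c(72, 96)) {
  dosing_end <- if (reg$n_doses > 0) max(reg$dose_times) else 96
  times <- seq(0, dosing_end, by = 24)
  t <- times[length(times)]
  i <- 0L
  while (t < horizon_h) {
    t <- t + gaps[i %% length(gaps) + 1L]
    i <- i + 1L
    if (t <= horizon_h) times <- c(times, t)
  }
  times
}

#' Generate a complete synthetic xenograft study
#'
#' For each mouse: draws a true baseline volume uniformly from the design
#' range; draws individual growth/kill parameters log-normally around the
#' population typical values; simulates the noise-free tumor trajectory at
#' the scheduled observation times under the arm's regimen; adds combined
#' residual noise to the observations (floored at 0.1 mm3 - calipers report
#' positive volumes); truncates at the event (first scheduled observation at
#' or above the threshold) or censors at the horizon. The returned object
#' carries the full per-subject truth for parameter-recovery oracles.
#'
#' The recorded baseline regressor is the noisy baseline observation - what
#' an analyst would use - not the latent truth.
#'
#' @param design A [study_design()].
#' @param pop A [population_model()]; defaults to [default_population()].
#' @param pk A [pk_params()].
#' @param seed Seed (local to this call).
#' @param growth Natural-growth law used for the truth (default simeoni).
#' @return An object of class `xeno_study`: list with tibbles
#'   `observations` (`subject`, `arm`, `time_h`, `tv_mm3`), `dosing`
#'   (`subject`, `time_h`, `amount_mg_kg`), `events` (`subject`, `arm`,
#'   `time_h`, `status`), `truth` (per-subject true parameters and etas,
#'   latent baseline, continuous threshold-crossing time `t_cross_h`),
#'   plus `regimens`, `arms`, `design`.
#' @examples
#' study <- generate_study(default_design(), seed = 42)
#' nrow(study$observations)
#' @export
generate_study <- function(design, pop = default_population(),
                           pk = pk_params(), seed = 1L, growth = "simeoni") {
  getv <- function(v, nm, default = NA_real_)
    if (nm %in% names(v)) unname(v[nm]) else default
  with_seed(seed, {
    pn <- names(pop$theta)
    subj_rows <- list(); dose_rows <- list(); event_rows <- list(); truth_rows <- list()
    id <- 0L
    for (ai in seq_len(nrow(design$arms))) {
      arm <- design$arms$arm[ai]
      reg <- design$regimens[[arm]]
      times <- schedule_times(reg, design$horizon_h, design$twice_weekly_gaps)
      for (m in seq_len(design$arms$n[ai])) {
        id <- id + 1L
        sid <- sprintf("S%03d", id)
        tv0 <- runif(1, design$baseline_range[1], design$baseline_range[2])
        eta <- setNames(rnorm(length(pn), 0,
                              vapply(pn, function(p) getv(pop$omega, p, 0),
                                     numeric(1))),
                        pn)
        p_i <- pop$theta * exp(eta)
        pars <- tgi_params(lambda0 = getv(p_i, "lambda0"),
                           lambda1 = getv(p_i, "lambda1", 1),
                           kill = getv(p_i, "kill", 0),
                           tv0 = tv0)
        traj <- simulate_tumor(pars, pk, reg, times, model = growth)
        sdv <- residual_sd(traj$tv_mm3, pop$residual, pop$error_model)
        y <- pmax(traj$tv_mm3 + rnorm(length(times), 0, sdv), 0.1)
        y[1] <- pmax(tv0 + rnorm(1, 0, residual_sd(tv0, pop$residual,
                                                   pop$error_model)), 0.1)
        hit <- which(y >= design$threshold)
        if (length(hit)) {
          keep <- seq_len(hit[1])
          status <- 1L
        } else {
          keep <- seq_along(times)
          status <- 0L
        }
        subj_rows[[id]] <- tibble::tibble(
          subject = sid, arm = arm, time_h = times[keep], tv_mm3 = y[keep])
        if (reg$n_doses > 0)
          dose_rows[[id]] <- tibble::tibble(
            subject = sid, time_h = reg$dose_times,
            amount_mg_kg = reg$dose_mg_per_kg)
        event_rows[[id]] <- tibble::tibble(
          subject = sid, arm = arm, time_h = times[keep][length(keep)],
          status = status)
        # continuous crossing of the noise-free trajectory, for oracles
        dense <- simulate_tumor(pars, pk, reg,
                                seq(0, design$horizon_h, by = 12),
                                model = growth)
        truth_rows[[id]] <- tibble::tibble(
          subject = sid, arm = arm, tv0_true = tv0, tv0_obs = y[1],
          lambda0 = getv(p_i, "lambda0"),
          lambda1 = getv(p_i, "lambda1"),
          kill = getv(p_i, "kill", 0),
          eta_lambda0 = getv(eta, "lambda0"),
          eta_lambda1 = getv(eta, "lambda1"),
          eta_kill = getv(eta, "kill"),
          t_cross_h = time_to_threshold(dense, design$threshold, "continuous"))
      }
    }
    structure(list(
      observations = dplyr::bind_rows(subj_rows),
      dosing = dplyr::bind_rows(dose_rows),
      events = dplyr::bind_rows(event_rows),
      truth = dplyr::bind_rows(truth_rows),
      regimens = design$regimens,
      arms = design$arms,
      design = design,
      pk = pk, pop = pop, seed = seed
    ), class = "xeno_study")
  })
}

#' @export
print.xeno_study <- function(x, ...) {
  cat(sprintf("<xeno_study> %d subjects, %d observations, %d arms; %d events / %d censored\n",
              length(unique(x$observations$subject)), nrow(x$observations),
              nrow(x$arms), sum(x$events$status == 1), sum(x$events$status == 0)))
  invisible(x)
}

#' Generate event records directly from the time-to-event model
#'
#' Bypasses the tumor-growth stage: draws per-subject growth-rate
#' covariates log-normally (medians and log-sds as configured), assigns
#' regimen-level average concentrations across arms (0 for vehicle),
#' computes individual scales under the covariate model, and draws
#' event/censoring records by inverse-CDF sampling. Used for fast
#' recovery tests of the survival stage.
#'
#' @param p A [tte_params()]; defaults to [default_tte_params()].
#' @param n Total subjects (allocated across arms proportionally to the
#'   default design).
#' @param cov_typical Named typical values for the log-normal covariate
#'   draws (default `lambda0` 0.0063, `lambda1` 5.93).
#' @param cov_omega Named log-sds (default 0.85, 0.73).
#' @param cavg_by_arm Named vector of regimen Cavg values, ng/mL; default
#'   computed from [pk_params()] defaults for the built-in regimens.
#' @param arm_weights Named allocation weights, same names as
#'   `cavg_by_arm`; default the default-design arm sizes.
#' @param censor_time Administrative censoring, h (default 2400).
#' @param seed Seed (local to this call).
#' @return A list: `events` (tibble `subject`, `arm`, `time_h`, `status`),
#'   `covariates` (tibble `subject`, `lambda0`, `lambda1`, `cavg`),
#'   `medians` (the normalizing medians used), `truth` (`p` and the
#'   per-subject true scales).
#' @export
generate_events <- function(p = default_tte_params(), n = 104,
                            cov_typical = c(lambda0 = 0.0063, lambda1 = 5.93),
                            cov_omega = c(lambda0 = 0.85, lambda1 = 0.73),
                            cavg_by_arm = NULL, arm_weights = NULL,
                            censor_time = 2400, seed = 1L) {
  if (n < 1) abort("`n` must be at least 1")
  if (is.null(cavg_by_arm)) {
    pk <- pk_params()
    presets <- c("vehicle", "0.3 Q1dx5", "0.6 Q1dx5", "0.9 Q1dx5",
                 "2.40 Q3dx6", "2.85 BIWx6")
    cavg_by_arm <- setNames(
      vapply(presets, function(a) pk_cavg(pk, regimen_preset(a)), numeric(1)),
      presets)
  }
  arm_weights <- arm_weights %||%
    setNames(c(24, 16, 16, 16, 16, 16)[seq_along(cavg_by_arm)], names(cavg_by_arm))
  with_seed(seed, {
    n_arm <- pmax(1L, round(n * arm_weights / sum(arm_weights)))
    # adjust rounding drift on the largest arm
    n_arm[which.max(n_arm)] <- n_arm[which.max(n_arm)] + (n - sum(n_arm))
    arm <- rep(names(cavg_by_arm), n_arm)
    cov <- tibble::tibble(
      subject = sprintf("S%03d", seq_len(n)),
      arm = arm,
      lambda0 = unname(cov_typical["lambda0"]) *
        exp(rnorm(n, 0, unname(cov_omega["lambda0"]))),
      lambda1 = unname(cov_typical["lambda1"]) *
        exp(rnorm(n, 0, unname(cov_omega["lambda1"]))),
      cavg = unname(cavg_by_arm[arm])
    )
    medians <- default_medians(cov, names(p$beta))
    ev <- simulate_events(cov[, c("subject", names(p$beta))], p,
                          censor_time = censor_time, medians = medians)
    ev$arm <- arm
    te_i <- individual_scale(cov, p, medians)
    list(events = ev[, c("subject", "arm", "time_h", "status")],
         covariates = cov,
         medians = medians,
         truth = list(params = p, te_i = te_i))
  })
}
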