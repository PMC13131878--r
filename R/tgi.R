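#' Tumor-growth-inhibition model parameters
#'
#' Parameters of the tumor-growth ODE: unperturbed growth switches smoothly
#' from exponential (rate `lambda0`, 1/h) to linear (rate `lambda1`, mm3/h)
#' around the switch volume `lambda1 / lambda0`, with sharpness set by the
#' exponent `psi` (fixed at 20 by convention, which makes the transition
#' essentially instantaneous). Drug effect is a first-order kill
#' `kill * Cp(t) * TV` proportional to plasma concentration; setting
#' `kc50 > 0` switches to a saturable Michaelis-Menten kill
#' `kill * Cp/(kc50 + Cp) * TV` (off by default).
#'
#' @param lambda0 Exponential growth rate, 1/h (> 0).
#' @param lambda1 Linear growth rate, mm3/h (> 0).
#' @param kill Kill rate constant, mL/ng/h (>= 0).
#' @param tv0 Baseline tumor volume, mm3 (> 0); a per-subject regressor.
#' @param psi Switching exponent, dimensionless; fixed at 20 unless overridden.
#' @param kc50 Michaelis-Menten constant, ng/mL; 0 selects the linear kill.
#' @return An object of class `tgi_params`.
#' @examples
#' p <- tgi_params(lambda0 = 0.0063, lambda1 = 5.93, kill = 2.4e-5, tv0 = 100)
#' p$lambda1 / p$lambda0  # switch volume, mm3
#' @export
tgi_params <- function(lambda0, lambda1, kill = 0, tv0, psi = 20, kc50 = 0) {
  stopifnot_scalar_pos(lambda0, "lambda0")
  stopifnot_scalar_pos(lambda1, "lambda1")
  stopifnot_scalar_pos(kill, "kill", strict = FALSE)
  stopifnot_scalar_pos(tv0, "tv0")
  stopifnot_scalar_pos(psi, "psi")
  stopifnot_scalar_pos(kc50, "kc50", strict = FALSE)
  structure(list(lambda0 = lambda0, lambda1 = lambda1, kill = kill,
                 tv0 = tv0, psi = psi, kc50 = kc50),
            class = "tgi_params")
}

growth_model_code <- function(model) {
  switch(model,
         simeoni = 0L, exponential = 1L, koch = 2L, quadratic = 3L,
         abort(sprintf("unknown growth model '%s'", model)))
}

#' Instantaneous tumor growth rate under drug exposure
#'
#' Evaluates the right-hand side of the growth-inhibition ODE,
#' `dTV/dt = lambda0 TV / (1 + ((lambda0/lambda1) TV)^psi)^(1/psi)
#'  - kill Cp TV`, at volume `tv` and concentration `cp`. For
#' `(lambda0/lambda1) TV << 1` this reduces to exponential growth
#' `lambda0 TV`; for `>> 1` it approaches the linear rate `lambda1`
#' (minus the kill term).
#'
#' @param tv Tumor volume(s), mm3 (> 0).
#' @param cp Plasma concentration(s), ng/mL (>= 0).
#' @param p A [tgi_params()].
#' @return Growth rate(s), mm3/h.
#' @export
tgi_growth_rate <- function(tv, cp, p) {
  if (any(tv <= 0)) abort("`tv` must be positive")
  if (any(cp < 0)) abort("`cp` must be non-negative")
  killterm <- if (p$kc50 > 0) p$kill * cp / (p$kc50 + cp) else p$kill * cp
  natural_growth_rate(tv, p = p, model = "simeoni") - killterm * tv
}

#' Natural (unperturbed) tumor growth rate
#'
#' Candidate growth laws screened during structural model development:
#' * `simeoni`: `lambda0 TV / (1 + ((lambda0/lambda1) TV)^psi)^(1/psi)` -
#'   exponential-to-linear switch;
#' * `exponential`: `lambda0 TV`;
#' * `koch`: `2 lambda0 lambda1 TV / (lambda1 + 2 lambda0 TV)` -
#'   exponential-like `2 lambda0 TV` as TV -> 0, plateauing at rate
#'   `lambda1` as TV -> Inf;
#' * `quadratic`: `2 lambda0 sqrt(tv0 TV)`, i.e. quadratic-in-time growth
#'   `TV(t) = tv0 (1 + lambda0 t)^2`.
#'
#' @param tv Tumor volume(s), mm3 (> 0).
#' @param t Time, h (unused by the shipped laws; kept for time-dependent ones).
#' @param p A [tgi_params()] (uses the fields each law needs).
#' @param model One of `"simeoni"`, `"exponential"`, `"koch"`, `"quadratic"`.
#' @return Growth rate(s), mm3/h.
#' @export
natural_growth_rate <- function(tv, t = 0, p, model = "simeoni") {
  if (any(tv <= 0)) abort("`tv` must be positive")
  growth_model_code(model)  # validates name
  switch(model,
    simeoni = {
      # stable evaluation of lambda0 TV / (1 + ((l0/l1) TV)^psi)^(1/psi)
      b <- p$psi * (log(tv) + log(p$lambda0) - log(p$lambda1))
      lse <- ifelse(b > 35, b, ifelse(b < -35, exp(b), log1p(exp(b))))
      p$lambda0 * tv * exp(-lse / p$psi)
    },
    exponential = p$lambda0 * tv,
    koch = 2 * p$lambda0 * p$lambda1 * tv / (p$lambda1 + 2 * p$lambda0 * tv),
    quadratic = 2 * p$lambda0 * sqrt(p$tv0 * tv)
  )
}

#' Simulate a tumor-volume trajectory
#'
#' Integrates the growth-inhibition ODE in log-volume with the plasma
#' concentration profile from [pk_concentration()] as forcing. The default
#' engine is a compiled fixed-step fourth-order Runge-Kutta scheme that
#' restarts at every dose time (where Cp jumps); `engine = "lsoda"` uses the
#' adaptive implicit solver from \pkg{deSolve} as an independent reference.
#' Halving `hmax` (or the lsoda tolerances) changes volumes by well under
#' 0.1 percent at the defaults.
#'
#' @param p A [tgi_params()]; `p$tv0` is the volume at `times[1]`.
#' @param pk A [pk_params()].
#' @param reg A [regimen()].
#' @param times Strictly increasing observation times, h; the first element
#'   is the initial time.
#' @param engine `"rk4"` (compiled, default) or `"lsoda"` (deSolve reference).
#' @param hmax Maximum RK4 step, h (default 0.5).
#' @param model Natural-growth law, see [natural_growth_rate()].
#' @return A tibble of class `tgi_trajectory` with columns `time_h`, `tv_mm3`.
#' @examples
#' p <- tgi_params(lambda0 = 0.0063, lambda1 = 5.93, kill = 2.4e-5, tv0 = 100)
#' simulate_tumor(p, pk_params(), regimen_preset("0.9 Q1dx5"), seq(0, 480, 24))
#' @export
simulate_tumor <- function(p, pk, reg, times, engine = c("rk4", "lsoda"),
                           hmax = 0.5, model = "simeoni") {
  engine <- match.arg(engine)
  times <- as.numeric(times)
  if (length(times) < 1 || any(diff(times) <= 0))
    abort("`times` must be strictly increasing")
  if (p$tv0 <= 0) abort("`tv0` must be positive")
  conc0 <- if (reg$n_doses > 0) dose_conc0(pk, reg) else numeric()
  tv <- if (engine == "rk4") {
    sim_tv_cpp(times, p$tv0, p$lambda0, p$lambda1, p$kill, p$psi,
               growth_model_code(model), p$kc50,
               reg$dose_times, conc0, pk$ke, hmax)
  } else {
    sim_tv_lsoda(p, pk, reg, times, model)
  }
  if (any(!is.finite(tv)))
    abort(sprintf("solver failure (engine %s) at lambda0=%g lambda1=%g kill=%g tv0=%g",
                  engine, p$lambda0, p$lambda1, p$kill, p$tv0))
  structure(tibble::tibble(time_h = times, tv_mm3 = tv),
            class = c("tgi_trajectory", "tbl_df", "tbl", "data.frame"))
}

# deSolve reference solver: integrates log TV with events at dose times
sim_tv_lsoda <- function(p, pk, reg, times, model = "simeoni") {
  if (!requireNamespace("deSolve", quietly = TRUE))
    abort("engine 'lsoda' needs the deSolve package")
  td <- if (reg$n_doses > 0) reg$dose_times else numeric()
  conc0 <- if (reg$n_doses > 0) dose_conc0(pk, reg) else numeric()
  rhs <- function(t, y, parms) {
    tv <- exp(y[1])
    cp <- if (length(td)) sum(conc0[td <= t + 1e-12] *
                                exp(-pk$ke * (t - td[td <= t + 1e-12]))) else 0
    killterm <- if (p$kc50 > 0) p$kill * cp / (p$kc50 + cp) else p$kill * cp
    list(natural_growth_rate(tv, t, p, model) / tv - killterm)
  }
  breaks <- sort(unique(c(times, td[td > times[1] & td < times[length(times)]])))
  out <- deSolve::lsoda(c(u = log(p$tv0)), breaks, rhs, parms = NULL,
                        rtol = 1e-8, atol = 1e-10)
  exp(out[match(times, out[, "time"]), "u"])
}

#' Time at which a trajectory reaches a volume threshold
#'
#' With the default `rule = "discrete"` the event time is the first grid time
#' whose volume is at or above the threshold, matching how a caliper study
#' observes the endpoint at scheduled measurements. `rule = "continuous"`
#' log-linearly interpolates the crossing between the bracketing grid times
#' (for sensitivity analysis).
#'
#' @param traj A trajectory tibble with `time_h` and `tv_mm3` (e.g. from
#'   [simulate_tumor()]).
#' @param threshold Volume threshold, mm3 (default 1500).
#' @param rule `"discrete"` (default) or `"continuous"`.
#' @return The crossing time in hours, or `NA_real_` if the threshold is
#'   never reached within the trajectory.
#' @export
time_to_threshold <- function(traj, threshold = 1500,
                              rule = c("discrete", "continuous")) {
  rule <- match.arg(rule)
  if (!nrow(traj)) abort("empty trajectory")
  stopifnot_scalar_pos(threshold, "threshold")
  hit <- which(traj$tv_mm3 >= threshold)
  if (!length(hit)) return(NA_real_)
  i <- hit[1]
  if (rule == "discrete" || i == 1) return(traj$time_h[i])
  t1 <- traj$time_h[i - 1]; t2 <- traj$time_h[i]
  v1 <- traj$tv_mm3[i - 1]; v2 <- traj$tv_mm3[i]
  t1 + (t2 - t1) * (log(threshold) - log(v1)) / (log(v2) - log(v1))
}
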