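#' Pharmacokinetic parameters for the one-compartment bolus model
#'
#' The exposure driver is a one-compartment model with linear (first-order)
#' elimination, dosed as an intravenous bolus. Both parameters are expressed
#' per kg of body weight, so per-kg dosing cancels body weight throughout:
#' a dose of D mg/kg produces an initial concentration of
#' `D * 1e6 / volume_dist` ng/mL.
#'
#' The defaults (`clearance = 115` mL/h/kg, `volume_dist = 1000` mL/kg,
#' elimination half-life about 6 h) are nominal placeholder values typical of
#' a small molecule given intravenously to mice; they are configuration
#' inputs, not estimates from any particular study, and every simulation/fit
#' pair in this package uses the same values on both sides.
#'
#' @param clearance Plasma clearance, mL/h/kg. Must be positive.
#' @param volume_dist Apparent volume of distribution, mL/kg. Must be positive.
#' @return An object of class `pk_params` with fields `clearance`,
#'   `volume_dist` and the derived elimination rate constant `ke` (1/h).
#' @examples
#' pk <- pk_params()
#' log(2) / pk$ke  # elimination half-life, h
#' @export
pk_params <- function(clearance = 115, volume_dist = 1000) {
  stopifnot_scalar_pos(clearance, "clearance")
  stopifnot_scalar_pos(volume_dist, "volume_dist")
  structure(
    list(clearance = clearance, volume_dist = volume_dist,
         ke = clearance / volume_dist),
    class = "pk_params"
  )
}

#' @export
print.pk_params <- function(x, ...) {
  cat(sprintf(
    "<pk_params> CL = %g mL/h/kg, V = %g mL/kg (ke = %.4g 1/h, t1/2 = %.3g h)\n",
    x$clearance, x$volume_dist, x$ke, log(2) / x$ke))
  invisible(x)
}

#' Define a dosing regimen
#'
#' A regimen is a label, a per-administration dose (mg/kg) and an ordered
#' vector of dose times in hours. The vehicle arm is a regimen with dose 0
#' and no dose times.
#'
#' @param name Regimen label, e.g. `"0.3 Q1dx5"`.
#' @param dose_mg_per_kg Dose per administration, mg/kg (>= 0).
#' @param dose_times Strictly increasing dose times, hours.
#' @return An object of class `regimen`.
#' @seealso [regimen_preset()] for the built-in schedules.
#' @export
regimen <- function(name, dose_mg_per_kg, dose_times = numeric()) {
  stopifnot_scalar_pos(dose_mg_per_kg, "dose_mg_per_kg", strict = FALSE)
  dose_times <- as.numeric(dose_times)
  if (length(dose_times) && (any(!is.finite(dose_times)) || any(dose_times < 0)))
    abort("`dose_times` must be finite and non-negative")
  if (length(dose_times) > 1 && any(diff(dose_times) <= 0))
    abort("`dose_times` must be strictly increasing")
  if (dose_mg_per_kg > 0 && !length(dose_times))
    abort("a regimen with a positive dose needs at least one dose time")
  structure(
    list(name = as.character(name), dose_mg_per_kg = dose_mg_per_kg,
         dose_times = dose_times, n_doses = length(dose_times)),
    class = "regimen"
  )
}

#' @export
print.regimen <- function(x, ...) {
  cat(sprintf("<regimen> %s: %g mg/kg at {%s} h\n", x$name, x$dose_mg_per_kg,
              paste(x$dose_times, collapse = ", ")))
  invisible(x)
}

#' Built-in dosing regimens
#'
#' Presets matching the study design emulated by [default_design()]:
#' * `Q1dx5` - once daily for five days (0, 24, 48, 72, 96 h);
#' * `Q3dx6` - every third day, six doses (0, 72, ..., 360 h);
#' * `BIWx6` - twice weekly, six doses, alternating 72/96 h gaps
#'   (0, 72, 168, 240, 336, 408 h);
#' * `vehicle` - no drug.
#'
#' @param name One of `"vehicle"`, `"0.3 Q1dx5"`, `"0.6 Q1dx5"`,
#'   `"0.9 Q1dx5"`, `"2.40 Q3dx6"`, `"2.85 BIWx6"`, or a custom
#'   `"<dose> <schedule>"` combination of those doses/schedules.
#' @return A [regimen()].
#' @export
regimen_preset <- function(name) {
  if (name == "vehicle") return(regimen("vehicle", 0))
  parts <- strsplit(trimws(name), "\\s+")[[1]]
  if (length(parts) != 2)
    abort(sprintf("unknown regimen preset '%s'", name))
  dose <- suppressWarnings(as.numeric(parts[1]))
  if (!is.finite(dose)) abort(sprintf("unknown regimen preset '%s'", name))
  times <- switch(parts[2],
    "Q1dx5" = seq(0, 96, by = 24),
    "Q3dx6" = seq(0, 360, by = 72),
    "BIWx6" = c(0, 72, 168, 240, 336, 408),
    abort(sprintf("unknown schedule '%s'", parts[2]))
  )
  regimen(name, dose, times)
}

# initial concentration contributed by each bolus, ng/mL
dose_conc0 <- function(pk, reg) {
  rep(reg$dose_mg_per_kg * 1e6 / pk$volume_dist, reg$n_doses)
}

# bare numeric Cp(t), superposition of mono-exponentials
cp_vec <- function(pk, reg, times) {
  if (any(times < 0)) abort("concentration requested at negative time")
  if (reg$n_doses == 0 || reg$dose_mg_per_kg == 0) return(rep(0, length(times)))
  cp_profile_cpp(as.numeric(times), reg$dose_times, dose_conc0(pk, reg), pk$ke)
}

#' Plasma concentration-time profile
#'
#' Evaluates Cp(t) for a regimen under the one-compartment bolus model by
#' superposition: each dose contributes `(D/V) exp(-ke (t - td))` for
#' `t >= td`. Concentration is zero before the first dose and for vehicle.
#'
#' @param pk A [pk_params()].
#' @param reg A [regimen()].
#' @param times Times (h) at which to evaluate, all >= 0.
#' @return A tibble with columns `time_h` and `conc_ng_ml`.
#' @examples
#' pk_concentration(pk_params(), regimen_preset("0.3 Q1dx5"), c(0, 12, 24, 36))
#' @export
pk_concentration <- function(pk, reg, times) {
  tibble::tibble(time_h = as.numeric(times), conc_ng_ml = cp_vec(pk, reg, times))
}

#' Regimen-level average concentration by non-compartmental analysis
#'
#' Computes `Cavg = AUC[t0, t1] / (t1 - t0)` where the AUC is evaluated
#' non-compartmentally on a dense grid (`n_grid` points per dosing interval)
#' with the log-down trapezoid rule between post-dose points (falling back to
#' the linear trapezoid where concentrations are zero or non-decreasing).
#' The default window runs from the first dose to the last dose plus the
#' regimen's final inter-dose interval, i.e. the treatment period.
#'
#' @param pk A [pk_params()].
#' @param reg A [regimen()].
#' @param window Length-2 numeric `(t0, t1)` in hours, `t1 > t0 >= 0`;
#'   `NULL` uses the default treatment-period window.
#' @param n_grid Grid points per dosing interval (default 100).
#' @return Average concentration over the window, ng/mL (scalar).
#' @examples
#' pk_cavg(pk_params(), regimen_preset("2.40 Q3dx6"))
#' @export
pk_cavg <- function(pk, reg, window = NULL, n_grid = 100) {
  if (reg$n_doses == 0 || reg$dose_mg_per_kg == 0) return(0)
  window <- window %||% default_cavg_window(reg)
  if (length(window) != 2 || !all(is.finite(window)) ||
      window[2] <= window[1] || window[1] < 0)
    abort("`window` must be (t0, t1) with t1 > t0 >= 0")
  auc_nca(pk, reg, window, n_grid) / diff(window)
}

default_cavg_window <- function(reg) {
  td <- reg$dose_times
  last_gap <- if (length(td) > 1) diff(td)[length(td) - 1] else 24
  c(td[1], td[length(td)] + last_gap)
}

auc_nca <- function(pk, reg, window, n_grid = 100) {
  td <- reg$dose_times
  # integrate interval by interval between dose times: the concentration
  # jumps at a dose, so the value entering the last trapezoid of an interval
  # must be the pre-dose (left) limit, not the post-dose value
  knots <- sort(unique(c(window, td[td > window[1] & td < window[2]])))
  total <- 0
  for (i in seq_len(length(knots) - 1)) {
    grid <- seq(knots[i], knots[i + 1], length.out = n_grid + 1)
    t_eval <- grid
    t_eval[length(t_eval)] <- t_eval[length(t_eval)] - 1e-9  # left limit
    cp <- cp_vec(pk, reg, t_eval)
    dt <- diff(grid)
    c1 <- head(cp, -1); c2 <- tail(cp, -1)
    seg <- (c1 + c2) / 2 * dt                     # linear trapezoid
    logdown <- c1 > 0 & c2 > 0 & c2 < c1          # strictly declining: log rule
    seg[logdown] <- (c1[logdown] - c2[logdown]) /
      log(c1[logdown] / c2[logdown]) * dt[logdown]
    total <- total + sum(seg)
  }
  total
}

#' Exposure summary table for a set of regimens
#'
#' @param pk A [pk_params()].
#' @param regimens A list of [regimen()] objects (or preset names).
#' @param window Optional shared Cavg window; default is each regimen's
#'   treatment-period window.
#' @return A tibble with one row per regimen: `name`, `dose_mg_per_kg`,
#'   `n_doses`, `window_t0`, `window_t1`, `auc`, `cavg`.
#' @export
pk_exposure_table <- function(pk, regimens, window = NULL) {
  regimens <- lapply(regimens, function(r)
    if (inherits(r, "regimen")) r else regimen_preset(r))
  purrr::map_dfr(regimens, function(r) {
    w <- window %||%
      (if (r$n_doses > 0) default_cavg_window(r) else c(NA_real_, NA_real_))
    tibble::tibble(
      name = r$name, dose_mg_per_kg = r$dose_mg_per_kg, n_doses = r$n_doses,
      window_t0 = w[1], window_t1 = w[2],
      auc = if (r$dose_mg_per_kg > 0) auc_nca(pk, r, w) else 0,
      cavg = if (r$dose_mg_per_kg > 0) pk_cavg(pk, r, w) else 0
    )
  })
}
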