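#' @export
print.tgi_fit <- function(x, ...) {
  cat(sprintf("<tgi_fit> %s growth, %s kill, %s mode; %d subjects, %d observations\n",
              x$growth, x$effect, x$mode, x$n_subjects, x$n_obs))
  cat(sprintf("  -2LL = %.2f, AIC = %.2f (%d parameters)\n", x$m2ll, x$aic, x$n_par))
  print(tidy(x))
  invisible(x)
}

#' @export
print.tte_fit <- function(x, ...) {
  cat(sprintf("<tte_fit> %s family (shape %.3g%s); %d subjects, %d events\n",
              x$family, x$shape, if (x$frailty == "estimate") ", frailty" else "",
              x$n_subjects, x$n_events))
  cat(sprintf("  -2LL = %.2f, AIC = %.2f (%d parameters)\n", x$m2ll, x$aic, x$n_par))
  print(tidy(x))
  invisible(x)
}

#' Tidy a population TGI fit
#'
#' One row per reported quantity, mirroring the conventional population
#' parameter table: typical value, standard error, RSE percent, IIV as
#' omega and CV percent, eta shrinkage.
#'
#' @param x A `tgi_fit`.
#' @param ... Unused.
#' @return A tibble: `term`, `estimate`, `std_error`, `rse_pct`, `omega`,
#'   `iiv_cv_pct`, `shrinkage_pct`.
#' @export
tidy.tgi_fit <- function(x, ...) {
  pn <- names(x$theta)
  rows <- tibble::tibble(
    term = pn,
    estimate = unname(x$theta),
    std_error = unname(x$se[pn]),
    rse_pct = unname(x$rse[pn]),
    omega = unname(x$omega[pn]),
    iiv_cv_pct = 100 * sqrt(exp(x$omega[pn]^2) - 1),
    shrinkage_pct = unname(x$shrinkage[pn])
  )
  res <- tibble::tibble(
    term = c("residual_a", "residual_b"),
    estimate = unname(x$residual[c("a", "b")]),
    std_error = NA_real_, rse_pct = NA_real_, omega = NA_real_,
    iiv_cv_pct = NA_real_, shrinkage_pct = NA_real_
  )
  res <- res[x$residual[c("a", "b")] > 0 |
               c("a", "b") %in% switch(x$error_model, combined = c("a", "b"),
                                       additive = "a", proportional = "b"), ]
  dplyr::bind_rows(rows, res)
}

#' Glance at a population TGI fit
#'
#' @param x A `tgi_fit`.
#' @param ... Unused.
#' @return A one-row tibble: `n_subjects`, `n_obs`, `n_par`, `m2ll`, `aic`,
#'   `converged`, `mode`, `growth`.
#' @export
glance.tgi_fit <- function(x, ...) {
  tibble::tibble(
    n_subjects = x$n_subjects, n_obs = x$n_obs, n_par = x$n_par,
    m2ll = x$m2ll, aic = x$aic,
    converged = isTRUE(x$convergence$converged),
    mode = x$mode, growth = x$growth
  )
}

#' Tidy a parametric time-to-event fit
#'
#' @param x A `tte_fit`.
#' @param ... Unused.
#' @return A tibble: `term`, `estimate`, `std_error`, `rse_pct`.
#' @export
tidy.tte_fit <- function(x, ...) {
  est <- x$estimates
  tibble::tibble(
    term = names(est),
    estimate = unname(est),
    std_error = unname(x$se[names(est)]),
    rse_pct = unname(x$rse[names(est)])
  )
}

#' Glance at a parametric time-to-event fit
#'
#' @param x A `tte_fit`.
#' @param ... Unused.
#' @return A one-row tibble: `n_subjects`, `n_events`, `n_par`, `m2ll`,
#'   `aic`, `family`, `shape`.
#' @export
glance.tte_fit <- function(x, ...) {
  tibble::tibble(
    n_subjects = x$n_subjects, n_events = x$n_events, n_par = x$n_par,
    m2ll = x$m2ll, aic = x$aic, family = x$family, shape = x$shape
  )
}

#' Plot a Kaplan-Meier curve
#'
#' @param object A `km_curve` from [km_curve()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.km_curve <- function(object, ...) {
  df <- dplyr::bind_rows(
    tibble::tibble(arm = unique(object$arm), time_h = 0, survival = 1),
    tibble::as_tibble(object)[, c("arm", "time_h", "survival")]
  )
  cens <- dplyr::filter(tibble::as_tibble(object), .data$n_censor > 0)
  ggplot2::ggplot(df, ggplot2::aes(.data$time_h, .data$survival,
                                   color = .data$arm)) +
    ggplot2::geom_step() +
    ggplot2::geom_point(data = cens, shape = 3, show.legend = FALSE) +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = "Time (h)", y = "Survival fraction", color = "Arm") +
    ggplot2::theme_minimal()
}

#' Plot a time-to-event visual predictive check
#'
#' Observed Kaplan-Meier curves over the simulation-based median and
#' prediction band, faceted by arm.
#'
#' @param object A `vpc_band` from [vpc_tte()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.vpc_band <- function(object, ...) {
  df <- tibble::as_tibble(object)
  ggplot2::ggplot(df, ggplot2::aes(.data$time_h)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$pred_lo_S,
                                      ymax = .data$pred_hi_S),
                         fill = "steelblue", alpha = 0.3) +
    ggplot2::geom_line(ggplot2::aes(y = .data$pred_median_S),
                       color = "steelblue", linetype = 2) +
    ggplot2::geom_step(ggplot2::aes(y = .data$observed_S), color = "black") +
    ggplot2::facet_wrap(~arm) +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = "Time (h)", y = "Survival fraction") +
    ggplot2::theme_minimal()
}

#' Goodness-of-fit panels for a population TGI fit
#'
#' Observations against population and individual predictions, and
#' individual weighted residuals against individual predictions and time.
#'
#' @param object A `tgi_fit`.
#' @param study The study the model was fitted to.
#' @param ... Unused.
#' @return A list of four ggplots: `obs_vs_pop`, `obs_vs_ind`,
#'   `iwres_vs_pred`, `iwres_vs_time`.
#' @export
plot_gof <- function(object, study, ...) {
  g <- gof_tables(study, object)
  base <- ggplot2::theme_minimal()
  list(
    obs_vs_pop = ggplot2::ggplot(g, ggplot2::aes(.data$pred_pop, .data$observed)) +
      ggplot2::geom_point(alpha = 0.4) +
      ggplot2::geom_abline(slope = 1, intercept = 0, color = "red") +
      ggplot2::labs(x = "Population prediction (mm3)", y = "Observed (mm3)") + base,
    obs_vs_ind = ggplot2::ggplot(g, ggplot2::aes(.data$pred_ind, .data$observed)) +
      ggplot2::geom_point(alpha = 0.4) +
      ggplot2::geom_abline(slope = 1, intercept = 0, color = "red") +
      ggplot2::labs(x = "Individual prediction (mm3)", y = "Observed (mm3)") + base,
    iwres_vs_pred = ggplot2::ggplot(g, ggplot2::aes(.data$pred_ind, .data$iwres)) +
      ggplot2::geom_point(alpha = 0.4) +
      ggplot2::geom_hline(yintercept = 0, color = "red") +
      ggplot2::labs(x = "Individual prediction (mm3)", y = "IWRES") + base,
    iwres_vs_time = ggplot2::ggplot(g, ggplot2::aes(.data$time_h, .data$iwres)) +
      ggplot2::geom_point(alpha = 0.4) +
      ggplot2::geom_hline(yintercept = 0, color = "red") +
      ggplot2::labs(x = "Time (h)", y = "IWRES") + base
  )
}

#' Spaghetti plot of study tumor-volume trajectories
#'
#' @param study A `xeno_study`.
#' @param log_scale Plot volume on the log scale (default `TRUE`).
#' @return A ggplot faceted by arm.
#' @export
plot_trajectories <- function(study, log_scale = TRUE) {
  p <- ggplot2::ggplot(study$observations,
                       ggplot2::aes(.data$time_h, .data$tv_mm3,
                                    group = .data$subject)) +
    ggplot2::geom_line(alpha = 0.5) +
    ggplot2::facet_wrap(~arm) +
    ggplot2::labs(x = "Time (h)", y = "Tumor volume (mm3)") +
    ggplot2::theme_minimal()
  if (log_scale) p <- p + ggplot2::scale_y_log10()
  p
}
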