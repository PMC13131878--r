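# tgitte

Two-stage translational modeling for preclinical oncology: link drug
exposure, tumor growth dynamics and survival in mouse xenograft efficacy
studies.

In these studies "survival" is the time until a subcutaneous tumor reaches a
predefined volume (1,500 mm³ here). `tgitte` is for modelers who want to go
beyond per-arm tumor-volume summaries and ask how exposure shapes growth,
and how growth translates into survival:

1. **Stage one — tumor growth inhibition (TGI).** A population (nonlinear
   mixed-effects) model of tumor volume,

   dTV/dt = λ₀·TV / [1 + ((λ₀/λ₁)·TV)²⁰]^(1/20) − k·Cp(t)·TV,

   where growth switches from exponential (rate λ₀, 1/h) to linear (rate
   λ₁, mm³/h) near TV = λ₁/λ₀, and drug kill is proportional to the plasma
   concentration Cp(t) from a one-compartment bolus PK model. Log-normal
   inter-individual variability, combined residual error (sd = a + b·f),
   baseline volume as a per-subject regressor. Fitting is iterated MAP-EM
   with a Monte-Carlo-EM refinement (default) or a SAEM-style stochastic EM;
   both return empirical-Bayes individual parameters, shrinkage, an
   importance-sampled −2LL and AIC.

2. **Stage two — time to event (TTE).** A parametric log-logistic survival
   model, h(t) = (s/Tₑ)(t/Tₑ)^(s−1)/[1+(t/Tₑ)^s] with shape s = 4 fixed, so
   the scale Tₑ is the median event time. Covariates act multiplicatively on
   the scale: the stage-one individual growth rates (median-normalized,
   centered) and the regimen-level average concentration Cavg
   (median-normalized, *not* centered, so vehicle is the reference).
   Censored maximum likelihood, optional log-normal frailty, Weibull /
   Gompertz / exponential alternatives for family screening by AIC.

Evaluation tools include Kaplan-Meier curves, dose-stratified visual
predictive checks with 90% prediction bands from repeated simulation,
subject-resampling bootstrap CIs, and goodness-of-fit/IWRES tables. A
synthetic-study generator (104 mice across vehicle and five dosing
regimens, daily-then-twice-weekly sampling to day 100) stands in for
non-public study data and doubles as the ground-truth oracle for the test
suite. Everything is tidyverse-shaped: tibbles in and out, `tidy()` /
`glance()` on fits, `autoplot()` on curves and bands.

## A worked example

```r
library(tgitte)

pk    <- pk_params()                       # CL = 115 mL/h/kg, V = 1000 mL/kg
study <- generate_study(default_design(), default_population(), pk, seed = 42)
study
#> <xeno_study> 104 subjects, 1704 observations, 6 arms; 99 events / 5 censored

pk_exposure_table(pk, study$regimens)[, c("name", "dose_mg_per_kg", "cavg")]
#> # A tibble: 6 × 3
#>   name       dose_mg_per_kg  cavg
#>   <chr>               <dbl> <dbl>
#> 1 vehicle              0       0
#> 2 0.3 Q1dx5            0.3   107.
#> 3 0.6 Q1dx5            0.6   214.
#> 4 0.9 Q1dx5            0.9   322.
#> 5 2.40 Q3dx6           2.4   290.
#> 6 2.85 BIWx6           2.85  310.

fit <- fit_tgi(study, pk)                  # population TGI fit (~2 min)
tidy(fit)
#> # A tibble: 5 × 7
#>   term        estimate   std_error rse_pct  omega iiv_cv_pct shrinkage_pct
#>   <chr>          <dbl>       <dbl>   <dbl>  <dbl>      <dbl>         <dbl>
#> 1 lambda0    0.00834    0.000816      9.79  0.998      131.           12.0
#> 2 lambda1    5.21       0.375         7.20  0.735       84.6          20.7
#> 3 kill       0.0000212  0.00000245   11.6   1.04       139.           31.6
#> 4 residual_a 8.41      NA            NA    NA           NA            NA
#> 5 residual_b 0.249     NA            NA    NA           NA            NA
```

The regimen exposure table shows the dose-proportional Cavg of
the daily regimens (107/214/322 ng/mL) and the comparable exposure of the
two high-dose intermittent regimens (~300 ng/mL). The population fit
recovers the generating truth (λ₀ = 0.0063 1/h, λ₁ = 5.93 mm³/h,
k = 2.4e-5 mL/ng/h, a = 11.22, b = 0.22) within the single-study sampling
spread at n = 104, which at this design is of the same order as the ±20%
band the recovery tests use (the methods vignette discusses why); this draw
lands high on λ₀ and low on k. The
empirical-Bayes growth rates then feed the survival stage:

```r
cavg <- pk_exposure_table(pk, study$regimens)
covs <- dplyr::transmute(fit$ebes, subject, lambda0, lambda1,
                         cavg = cavg$cavg[match(arm, cavg$name)])
tfit <- fit_tte(study$events, covs)
tidy(tfit)
#> # A tibble: 4 × 4
#>   term         estimate std_error rse_pct
#>   <chr>           <dbl>     <dbl>   <dbl>
#> 1 te_pop       555.      43.1        7.76
#> 2 beta_lambda0  -0.0149   0.00987   66.3
#> 3 beta_lambda1  -0.467    0.0697    14.9
#> 4 beta_cavg      0.267    0.0765    28.7
```

The signs carry the biology: faster linear growth shortens survival
(β = −0.47), higher regimen exposure lengthens it (β = +0.27). In this
end-to-end demonstration the event times come from the tumor-growth process
itself, so the log-linear covariate model is an approximation and the
coefficient magnitudes are not comparable to a fit of data generated under
the covariate model; the direct recovery experiment (`generate_events()`
followed by `fit_tte()`, as run by the acceptance script) recovers
generating coefficients of −0.75 / −0.46 / +0.63 with median bias within a
few percent over 20 replicates. A VPC and bootstrap close the loop:

```r
vpc <- vpc_tte(tfit, arms = study$events[, c("subject", "arm")],
               n_sim = 1000, seed = 2)
autoplot(vpc)                              # observed KM vs the 90% band
bootstrap_tte(tfit, n_boot = 1000, seed = 3)
```

`run_pipeline(config, out_dir)` runs simulate → fit-tgi → covariates →
fit-tte → vpc → bootstrap → report from a YAML config with full seed
determinism, writing each stage's CSV/JSON artifacts.

## Package layout

- `R/pk.R` — one-compartment bolus PK, regimens, NCA Cavg
- `R/tgi.R` — growth laws, forward ODE simulation (`src/simeoni.cpp`),
  threshold detection
- `R/nlme.R` — population model, MAP-EM/MC-EM and SAEM estimation, EBEs,
  shrinkage, AIC
- `R/tte.R` — hazard families, covariate scale model, censored ML, event
  simulation
- `R/evaluation.R` — Kaplan-Meier, VPC bands, bootstrap, GOF/IWRES
- `R/synthetic.R` — study designs and the synthetic-data generator
- `R/io.R`, `R/pipeline.R` — validated CSV dialects, YAML-configured
  pipeline
- `vignettes/tgi-tte-framework.Rmd` — the model, its assumptions, numerical
  choices and limitations
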