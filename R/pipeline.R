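pipeline_defaults <- function() {
  list(
    seed = 1L,
    design = list(n_per_arm = c(24, 16, 16, 16, 16, 16)),
    pk = list(clearance = 115, volume_dist = 1000),
    truth = list(
      theta = c(lambda0 = 0.0063, lambda1 = 5.93, kill = 2.4e-5),
      omega = c(lambda0 = 0.85, lambda1 = 0.73, kill = 0.87),
      residual = c(a = 11.22, b = 0.22)
    ),
    tgi = list(mode = "two_stage", maxit = 25),
    tte = list(family = "loglogistic", shape = 4, frailty = "none"),
    evaluation = list(n_sim = 1000, n_boot = 1000),
    threshold = 1500
  )
}

#' Assemble and validate a pipeline configuration
#'
#' @param config A named list of overrides, or a path to a YAML file with
#'   the same structure. See `pipeline_defaults` in the source for the
#'   complete default tree (seed, design, pk, truth, tgi, tte, evaluation).
#' @return A validated config list of class `pipeline_config`.
#' @export
pipeline_config <- function(config = list()) {
  if (is.character(config)) {
    if (!file.exists(config))
      abort(sprintf("config file '%s' does not exist", config))
    config <- yaml::read_yaml(config)
    for (blk in c("truth")) {
      for (f in names(config[[blk]]))
        config[[blk]][[f]] <- unlist(config[[blk]][[f]])
    }
  }
  cfg <- modifyList(pipeline_defaults(), config)
  if (is.null(cfg$seed)) abort("`seed` is mandatory")
  cfg$seed <- as.integer(cfg$seed)
  if (length(cfg$design$n_per_arm) != 6)
    abort("design$n_per_arm must have 6 entries (vehicle first)")
  structure(cfg, class = "pipeline_config")
}

stage_try <- function(stage, expr) {
  tryCatch(expr, error = function(e)
    abort(sprintf("[stage %s] %s", stage, conditionMessage(e))))
}

#' Run the end-to-end simulation / estimation / evaluation pipeline
#'
#' Executes, in order: `simulate` (synthetic study generation),
#' `fit-tgi` (population growth-inhibition fit), `covariates`
#' (empirical-Bayes growth rates + regimen Cavg), `fit-tte` (covariate
#' survival model), `vpc`, `bootstrap` (survival-stage), `report`.
#' Every stage writes its CSV/JSON artifacts into `out_dir`; rerunning with
#' the same config and seed reproduces identical outputs.
#'
#' @param config A [pipeline_config()] (or list/YAML path coerced by it).
#' @param out_dir Output directory.
#' @param seed Optional override of `config$seed`.
#' @param stages Subset of stages to run (in canonical order); later stages
#'   require the earlier ones in the same call.
#' @return Invisibly, a list with the fitted objects and written paths.
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir,
                         seed = NULL,
                         stages = c("simulate", "fit-tgi", "covariates",
                                    "fit-tte", "vpc", "bootstrap", "report")) {
  if (!inherits(config, "pipeline_config")) config <- pipeline_config(config)
  if (!is.null(seed)) config$seed <- as.integer(seed)
  stages <- match.arg(stages, several.ok = TRUE)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  seeds <- child_seeds(config$seed, 4)
  res <- list(config = config, paths = character())
  pk <- pk_params(config$pk$clearance, config$pk$volume_dist)

  if ("simulate" %in% stages) {
    message("[simulate] generating synthetic study")
    res$study <- stage_try("simulate", {
      pop <- population_model(config$truth$theta, config$truth$omega,
                              config$truth$residual)
      generate_study(default_design(config$design$n_per_arm), pop, pk,
                     seed = seeds[1])
    })
    res$paths <- c(res$paths, write_study_csv(res$study, out_dir))
  }
  if ("fit-tgi" %in% stages) {
    if (is.null(res$study)) abort("[stage fit-tgi] no study simulated/loaded")
    message("[fit-tgi] population TGI fit (mode ", config$tgi$mode, ")")
    res$tgi_fit <- stage_try("fit-tgi",
      fit_tgi(res$study, pk, mode = config$tgi$mode,
              control = tgi_control(maxit = config$tgi$maxit,
                                    seed = seeds[2])))
    p <- file.path(out_dir, "tgi_parameters.csv")
    utils::write.csv(tidy(res$tgi_fit), p, row.names = FALSE)
    jsonlite::write_json(
      list(m2ll = res$tgi_fit$m2ll, aic = res$tgi_fit$aic,
           n_par = res$tgi_fit$n_par),
      file.path(out_dir, "tgi_fit.json"), auto_unbox = TRUE, digits = NA)
    res$paths <- c(res$paths, tgi_parameters = p)
  }
  if ("covariates" %in% stages) {
    if (is.null(res$tgi_fit)) abort("[stage covariates] needs the fit-tgi stage")
    message("[covariates] EBEs + regimen Cavg")
    res$covariates <- stage_try("covariates", {
      eb <- res$tgi_fit$ebes
      expo <- pk_exposure_table(pk, res$study$regimens)
      cavg <- setNames(expo$cavg, expo$name)
      tibble::tibble(subject = eb$subject, arm = eb$arm,
                     lambda0 = eb$lambda0, lambda1 = eb$lambda1,
                     cavg = unname(cavg[eb$arm]))
    })
    p <- file.path(out_dir, "covariates.csv")
    utils::write.csv(res$covariates, p, row.names = FALSE)
    res$paths <- c(res$paths, covariates = p)
  }
  if ("fit-tte" %in% stages) {
    if (is.null(res$covariates)) abort("[stage fit-tte] needs the covariates stage")
    message("[fit-tte] covariate survival model")
    res$tte_fit <- stage_try("fit-tte",
      fit_tte(res$study$events,
              res$covariates[, c("subject", "lambda0", "lambda1", "cavg")],
              family = config$tte$family, shape = config$tte$shape,
              frailty = config$tte$frailty))
    p <- file.path(out_dir, "tte_parameters.csv")
    utils::write.csv(tidy(res$tte_fit), p, row.names = FALSE)
    jsonlite::write_json(
      list(m2ll = res$tte_fit$m2ll, aic = res$tte_fit$aic,
           n_par = res$tte_fit$n_par),
      file.path(out_dir, "tte_fit.json"), auto_unbox = TRUE, digits = NA)
    res$paths <- c(res$paths, tte_parameters = p)
  }
  if ("vpc" %in% stages) {
    if (is.null(res$tte_fit)) abort("[stage vpc] needs the fit-tte stage")
    message("[vpc] ", config$evaluation$n_sim, " simulated studies")
    res$vpc <- stage_try("vpc",
      vpc_tte(res$tte_fit, n_sim = config$evaluation$n_sim, seed = seeds[3]))
    p <- file.path(out_dir, "vpc.csv")
    utils::write.csv(res$vpc, p, row.names = FALSE)
    res$paths <- c(res$paths, vpc = p)
  }
  if ("bootstrap" %in% stages) {
    if (is.null(res$tte_fit)) abort("[stage bootstrap] needs the fit-tte stage")
    message("[bootstrap] ", config$evaluation$n_boot, " survival-stage replicates")
    res$bootstrap <- stage_try("bootstrap",
      bootstrap_tte(res$tte_fit, n_boot = config$evaluation$n_boot,
                    seed = seeds[4]))
    p <- file.path(out_dir, "bootstrap.csv")
    utils::write.csv(res$bootstrap, p, row.names = FALSE)
    res$paths <- c(res$paths, bootstrap = p)
  }
  if ("report" %in% stages) {
    manifest <- list(
      seed = config$seed,
      config_hash = rlang::hash(unclass(config)),
      stages = stages,
      files = as.list(res$paths)
    )
    p <- file.path(out_dir, "manifest.json")
    jsonlite::write_json(manifest, p, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
    res$paths <- c(res$paths, manifest = p)
  }
  invisible(res)
}
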