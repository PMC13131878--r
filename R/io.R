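#' Write a study to CSV files
#'
#' Emits the NONMEM/Monolix-style long-format dataset (columns `ID`, `TIME`,
#' `DV`, `AMT`, `EVID`, `ARM`, `TV0`; `"."` for inapplicable fields), the
#' event records, the truth table when present, and a JSON manifest
#' recording the seed and design.
#'
#' @param study A `xeno_study`.
#' @param dir Output directory (created if needed).
#' @param prefix File-name prefix (default `"study"`).
#' @return Invisibly, the named vector of written paths.
#' @export
write_study_csv <- function(study, dir, prefix = "study") {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  obs <- dplyr::mutate(study$observations, EVID = 0L,
                       AMT = NA_real_, DV = .data$tv_mm3)
  dos <- if (nrow(study$dosing)) {
    arm_of <- study$observations$arm[match(study$dosing$subject,
                                           study$observations$subject)]
    tibble::tibble(subject = study$dosing$subject, arm = arm_of,
                   time_h = study$dosing$time_h, EVID = 1L,
                   AMT = study$dosing$amount_mg_kg, DV = NA_real_)
  } else NULL
  tv0 <- dplyr::summarise(dplyr::group_by(study$observations, .data$subject),
                          TV0 = .data$tv_mm3[which.min(.data$time_h)])
  all_rows <- dplyr::bind_rows(obs, dos)
  all_rows <- dplyr::arrange(all_rows, .data$subject, .data$time_h, .data$EVID)
  all_rows$TV0 <- tv0$TV0[match(all_rows$subject, tv0$subject)]
  out <- tibble::tibble(
    ID = all_rows$subject, TIME = all_rows$time_h,
    DV = ifelse(is.na(all_rows$DV), ".", format(all_rows$DV, digits = 8)),
    AMT = ifelse(is.na(all_rows$AMT), ".", format(all_rows$AMT, digits = 8)),
    EVID = all_rows$EVID, ARM = all_rows$arm, TV0 = all_rows$TV0
  )
  paths <- c(
    dataset = file.path(dir, paste0(prefix, "_dataset.csv")),
    events = file.path(dir, paste0(prefix, "_events.csv")),
    manifest = file.path(dir, paste0(prefix, "_manifest.json"))
  )
  utils::write.csv(out, paths["dataset"], row.names = FALSE, quote = FALSE)
  utils::write.csv(study$events, paths["events"], row.names = FALSE, quote = FALSE)
  if (!is.null(study$truth) && nrow(study$truth)) {
    paths["truth"] <- file.path(dir, paste0(prefix, "_truth.csv"))
    utils::write.csv(study$truth, paths["truth"], row.names = FALSE, quote = FALSE)
  }
  arms <- study$arms
  manifest <- list(
    seed = study$seed, n_subjects = length(unique(study$observations$subject)),
    n_observations = nrow(study$observations),
    arms = lapply(seq_len(nrow(arms)), function(i) list(
      arm = arms$arm[i], n = arms$n[i],
      dose_mg_per_kg = study$regimens[[arms$arm[i]]]$dose_mg_per_kg,
      dose_times = study$regimens[[arms$arm[i]]]$dose_times)),
    files = as.list(paths[setdiff(names(paths), "manifest")])
  )
  jsonlite::write_json(manifest, paths["manifest"], auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(paths)
}

collect_issue <- function(issues, line, msg) {
  c(issues, sprintf("line %d: %s", line, msg))
}

#' Read a study dataset from CSV
#'
#' Reads the long-format dialect written by [write_study_csv()] (columns
#' `ID`, `TIME`, `DV`, `AMT`, `EVID`, `ARM`, optional `TV0`) with strict
#' validation: every schema violation is collected and reported with its
#' line number (header = line 1) before the read fails.
#'
#' @param path CSV path.
#' @param regimens Optional named list of [regimen()] objects keyed by arm
#'   label; default: reconstructed from the dose rows (dose amount and
#'   times shared within each arm), with vehicle arms getting a zero-dose
#'   regimen.
#' @return A `xeno_study` (without truth/events unless supplied separately;
#'   see [read_events_csv()]).
#' @export
read_study_csv <- function(path, regimens = NULL) {
  if (!file.exists(path)) abort(sprintf("dataset file '%s' does not exist", path))
  raw <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = "character")
  need <- c("ID", "TIME", "DV", "AMT", "EVID", "ARM")
  miss <- setdiff(need, names(raw))
  if (length(miss))
    abort(sprintf("dataset lacks required columns: %s", paste(miss, collapse = ", ")))
  issues <- character()
  line <- seq_len(nrow(raw)) + 1L  # header is line 1
  num <- function(x) suppressWarnings(as.numeric(x))
  time <- num(raw$TIME); evid <- num(raw$EVID)
  dv <- num(ifelse(raw$DV == ".", NA, raw$DV))
  amt <- num(ifelse(raw$AMT == ".", NA, raw$AMT))
  for (i in seq_len(nrow(raw))) {
    if (is.na(time[i]) || time[i] < 0)
      issues <- collect_issue(issues, line[i], "TIME must be a non-negative number")
    if (is.na(evid[i]) || !evid[i] %in% c(0, 1))
      issues <- collect_issue(issues, line[i], "EVID must be 0 or 1")
    if (!is.na(evid[i]) && evid[i] == 0) {
      if (raw$DV[i] == "." || is.na(dv[i]))
        issues <- collect_issue(issues, line[i], "observation row (EVID=0) needs numeric DV")
      else if (dv[i] <= 0)
        issues <- collect_issue(issues, line[i], "tumor volume DV must be positive")
      if (raw$AMT[i] != "." && !is.na(amt[i]) && amt[i] != 0)
        issues <- collect_issue(issues, line[i], "observation row cannot carry a dose AMT")
    }
    if (!is.na(evid[i]) && evid[i] == 1) {
      if (raw$DV[i] != ".")
        issues <- collect_issue(issues, line[i], "dose row (EVID=1) cannot carry DV")
      if (raw$AMT[i] == "." || is.na(amt[i]) || amt[i] < 0)
        issues <- collect_issue(issues, line[i], "dose row needs non-negative numeric AMT")
    }
  }
  # per-subject monotone observation times, no duplicates
  obs_idx <- which(!is.na(evid) & evid == 0 & !is.na(time))
  for (s in unique(raw$ID[obs_idx])) {
    ii <- obs_idx[raw$ID[obs_idx] == s]
    tt <- time[ii]
    bad <- which(duplicated(tt))
    for (b in bad)
      issues <- collect_issue(issues, line[ii[b]],
                              sprintf("duplicate observation time for subject %s", s))
    if (is.unsorted(tt, strictly = FALSE))
      issues <- collect_issue(issues, line[ii[which(diff(tt) < 0)[1] + 1]],
                              sprintf("observation times not sorted for subject %s", s))
  }
  if (length(issues))
    abort(paste(c(sprintf("invalid dataset '%s':", path), issues), collapse = "\n"))

  obs <- tibble::tibble(subject = raw$ID[evid == 0], arm = raw$ARM[evid == 0],
                        time_h = time[evid == 0], tv_mm3 = dv[evid == 0])
  dosing <- tibble::tibble(subject = raw$ID[evid == 1],
                           arm = raw$ARM[evid == 1],
                           time_h = time[evid == 1],
                           amount_mg_kg = amt[evid == 1])
  arms <- dplyr::summarise(dplyr::group_by(obs, arm = .data$arm),
                           n = dplyr::n_distinct(.data$subject))
  if (is.null(regimens)) {
    regimens <- lapply(arms$arm, function(a) {
      d <- dosing[dosing$arm == a, ]
      if (!nrow(d)) return(regimen(a, 0))
      one <- d[d$subject == d$subject[1], ]
      regimen(a, one$amount_mg_kg[1], sort(one$time_h))
    })
    names(regimens) <- arms$arm
  }
  structure(list(observations = obs,
                 dosing = dosing[, c("subject", "time_h", "amount_mg_kg")],
                 events = NULL, truth = NULL,
                 regimens = regimens, arms = arms, design = NULL),
            class = "xeno_study")
}

#' Read / write event records
#'
#' Events CSV: columns `subject`, `time_h`, `status` (1 event / 0 censored),
#' plus any covariate columns. Validation reports line-numbered errors.
#'
#' @param path CSV path.
#' @return `read_events_csv`: a tibble of events (with any extra columns).
#' @export
read_events_csv <- function(path) {
  if (!file.exists(path)) abort(sprintf("events file '%s' does not exist", path))
  raw <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("subject", "time_h", "status")
  miss <- setdiff(need, names(raw))
  if (length(miss))
    abort(sprintf("events file lacks columns: %s", paste(miss, collapse = ", ")))
  issues <- character()
  for (i in seq_len(nrow(raw))) {
    if (!is.numeric(raw$time_h[i]) || is.na(raw$time_h[i]) || raw$time_h[i] <= 0)
      issues <- collect_issue(issues, i + 1L, "time_h must be positive")
    if (!raw$status[i] %in% c(0, 1))
      issues <- collect_issue(issues, i + 1L, "status must be 0 or 1")
  }
  dup <- which(duplicated(raw$subject))
  for (d in dup) issues <- collect_issue(issues, d + 1L, "duplicate subject id")
  if (length(issues))
    abort(paste(c(sprintf("invalid events file '%s':", path), issues), collapse = "\n"))
  tibble::as_tibble(raw)
}

#' @rdname read_events_csv
#' @param events A data frame of events (and covariates).
#' @return `write_events_csv`: the path, invisibly.
#' @export
write_events_csv <- function(events, path) {
  utils::write.csv(events, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
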