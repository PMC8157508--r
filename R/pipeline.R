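# Study pipeline: orchestrates the replication analyses on a census CSV +
# survey CSV pair and emits result tables in which every second-stage
# estimate is accompanied by its first-stage F (no naked IV estimates).

fit_for <- function(frame, config, f_refuse = 1, f_warn = 10) {
  if (frame$outcome_scale == "probability") {
    linear_probability_iv(frame, config$se_type, f_refuse = f_refuse,
                          f_warn = f_warn)
  } else {
    fit_2sls(frame, config$se_type, f_refuse = f_refuse, f_warn = f_warn)
  }
}

unestimable_row <- function(label, n, reason) {
  row <- iv_fit_row(structure(list(
    beta_2sls = list(estimate = NA_real_, se = NA_real_,
                     ci = c(lower = NA_real_, upper = NA_real_)),
    pi_first_stage = list(estimate = NA_real_, se = NA_real_,
                          ci = c(lower = NA_real_, upper = NA_real_)),
    rho_reduced_form = list(estimate = NA_real_, se = NA_real_,
                            ci = c(lower = NA_real_, upper = NA_real_)),
    beta_ols = list(estimate = NA_real_, se = NA_real_,
                    ci = c(lower = NA_real_, upper = NA_real_)),
    f_first_stage = NA_real_, weak_instrument = NA, n = n,
    se_type = NA_character_, outcome_scale = "score", scale = 1
  ), class = "iv_fit"), label = label)
  row$note <- reason
  row
}

run_one <- function(data, outcome, treatment, coding, config, label) {
  # a weak-instrument warning is recorded in the row (weak_instrument
  # column + note), not propagated; a refusal marks the row unestimable
  res <- tryCatch({
    frame <- build_frame(data, outcome, treatment, coding, config)
    fit <- withCallingHandlers(
      fit_for(frame, config),
      dentiv_weak_instrument_warning = function(w) {
        invokeRestart("muffleWarning")
      })
    row <- iv_fit_row(fit, label = label)
    row$note <- if (fit$weak_instrument) {
      sprintf("weak instrument (F = %.1f)", fit$f_first_stage)
    } else ""
    row
  }, dentiv_error = function(e) {
    unestimable_row(label, nrow(data), conditionMessage(e))
  })
  res
}

results_table <- function(rows, report) {
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "report") <- report
  class(out) <- c("dentiv_results", "data.frame")
  out
}

run_report <- function(config, prep, analysis) {
  list(
    analysis = analysis,
    exclusions = prep$exclusions,
    n_analysed = nrow(prep$data),
    coding = config$coding$name,
    coding_values = config$coding$values,
    day_mapping_breaks = config$day_mapping$breaks,
    se_type = config$se_type,
    birth_cohort = config$birth_cohort,
    birth_year_terms = config$birth_year_terms,
    age_split = config$age_split,
    birth_year_split = config$birth_year_split,
    caseness_cutoff = config$caseness_cutoff,
    multiple_testing = "none (stratified CIs reported as-is)"
  )
}

#' Run the main analyses
#'
#' Six analyses mirroring the study's headline tables: the continuous
#' (mid-point-coded) treatment and the two dichotomised contrasts, each
#' against the PHQ-8 total score and the caseness indicator. Every row
#' reports first stage (with F), reduced form, second stage and OLS.
#'
#' @param survey,census Input data.frames.
#' @param config A [study_config()].
#' @return A `dentiv_results` data.frame with a `report` attribute holding
#'   the audit trail (exclusions, coding, mapping, SE settings).
#' @export
run_main <- function(survey, census, config = study_config()) {
  prep <- prepare_study_data(survey, census, config)
  specs <- list(
    list("continuous x PHQ-8 total", "total", "continuous"),
    list("continuous x caseness", "caseness", "continuous"),
    list(">=1 tooth lost x PHQ-8 total", "total", "any_loss"),
    list(">=1 tooth lost x caseness", "caseness", "any_loss"),
    list("edentulous x PHQ-8 total", "total", "edentulous"),
    list("edentulous x caseness", "caseness", "edentulous")
  )
  rows <- lapply(specs, function(s) {
    run_one(prep$data, s[[2]], s[[3]], config$coding, config, s[[1]])
  })
  results_table(rows, run_report(config, prep, "main"))
}

#' Run the stratified analyses
#'
#' Re-runs the continuous-treatment, total-score analysis within each
#' stratum of: age (split at `config$age_split`), year of birth (split
#' after `config$birth_year_split`), gender, household income bracket and
#' dental-care utilisation. Strata partition the sample; no pooling across
#' strata; a stratum whose design is degenerate is marked unestimable and
#' the run continues.
#'
#' @inheritParams run_main
#' @return A `dentiv_results` data.frame, one row per stratum.
#' @export
run_stratified <- function(survey, census, config = study_config()) {
  prep <- prepare_study_data(survey, census, config)
  data <- prep$data
  strata <- list(
    list(sprintf("age < %d", config$age_split),
         data$age < config$age_split),
    list(sprintf("age >= %d", config$age_split),
         data$age >= config$age_split),
    list(sprintf("born <= %d", config$birth_year_split),
         data$birth_year <= config$birth_year_split),
    list(sprintf("born >= %d", config$birth_year_split + 1L),
         data$birth_year > config$birth_year_split),
    list("men", data$gender == "male"),
    list("women", data$gender == "female")
  )
  if ("income_stratum" %in% names(data) && !all(is.na(data$income_stratum))) {
    strata <- c(strata, list(
      list("income < $50k", data$income_stratum == "lt50k"),
      list("income >= $50k", data$income_stratum == "ge50k")))
  }
  if ("dental_visit_stratum" %in% names(data) &&
      !all(is.na(data$dental_visit_stratum))) {
    strata <- c(strata, list(
      list("dental visit within year",
           data$dental_visit_stratum == "visit_within_year"),
      list("no recent dental visit",
           data$dental_visit_stratum == "no_recent_visit")))
  }
  rows <- lapply(strata, function(s) {
    sub <- data[which(s[[2]]), , drop = FALSE]
    if (!nrow(sub)) return(unestimable_row(s[[1]], 0L, "empty stratum"))
    run_one(sub, "total", "continuous", config$coding, config, s[[1]])
  })
  results_table(rows, run_report(config, prep, "stratified"))
}

#' Run the coding sensitivity analyses
#'
#' Re-runs the continuous-treatment analyses (total score and caseness)
#' under each supplied alternative bracket coding, side by side with the
#' main mid-point coding.
#'
#' @inheritParams run_main
#' @param codings Named list of [tooth_coding()]s; defaults to
#'   `config$sensitivity` (plus the main coding, always included first).
#' @return A `dentiv_results` data.frame.
#' @export
run_sensitivity <- function(survey, census, config = study_config(),
                            codings = config$sensitivity) {
  prep <- prepare_study_data(survey, census, config)
  all_codings <- c(list(config$coding), codings)
  rows <- list()
  for (cd in all_codings) {
    for (oc in c("total", "caseness")) {
      rows[[length(rows) + 1L]] <- run_one(
        prep$data, oc, "continuous", cd, config,
        sprintf("%s x %s", cd$name,
                if (oc == "total") "PHQ-8 total" else "caseness"))
    }
  }
  results_table(rows, run_report(config, prep, "sensitivity"))
}

#' Run the per-item analyses
#'
#' Eight 2SLS runs, one per PHQ-8 item score (0-3 outcome), with the same
#' continuous treatment and design as the main analysis. An item with no
#' outcome variation is marked unestimable.
#'
#' @inheritParams run_main
#' @return A `dentiv_results` data.frame, one row per item.
#' @export
run_item_level <- function(survey, census, config = study_config()) {
  item_labels <- c("little interest", "feeling down", "sleep problems",
                   "little energy", "appetite", "feeling bad about self",
                   "concentration", "moving/speaking slowly")
  prep <- prepare_study_data(survey, census, config)
  rows <- lapply(1:8, function(j) {
    outcome <- paste0("item", j)
    y <- prep$data[[paste0(outcome, "_score")]]
    label <- sprintf("item %d (%s)", j, item_labels[j])
    if (stats::var(y) == 0) {
      return(unestimable_row(label, nrow(prep$data),
                             "item score has no variation"))
    }
    run_one(prep$data, outcome, "continuous", config$coding, config, label)
  })
  results_table(rows, run_report(config, prep, "item-level"))
}

#' @export
print.dentiv_results <- function(x, digits = 3, ...) {
  cat(format_results(x, digits = digits), sep = "\n")
  invisible(x)
}

#' Format a results table as text
#'
#' A human-readable table in the layout of the study's result tables:
#' first stage (with F), second stage and OLS per analysis row.
#'
#' @param results A `dentiv_results` data.frame.
#' @param digits Significant digits.
#' @return Character vector of lines.
#' @export
format_results <- function(results, digits = 3) {
  report <- attr(results, "report")
  fmt <- function(est, lo, hi) {
    ifelse(is.na(est), "--",
           sprintf("%.*f (%.*f to %.*f)", digits, est, digits, lo, digits, hi))
  }
  lines <- c(
    sprintf("Analysis: %s | n analysed = %d | SEs: %s | coding: %s",
            report$analysis, report$n_analysed, report$se_type,
            report$coding),
    sprintf("%-32s %8s %28s %8s %28s %28s", "label", "n",
            "first stage (95% CI)", "F", "second stage (95% CI)",
            "OLS (95% CI)"))
  for (i in seq_len(nrow(results))) {
    r <- results[i, ]
    lines <- c(lines, sprintf(
      "%-32s %8d %28s %8s %28s %28s%s",
      r$label, r$n,
      fmt(r$first_stage, r$first_stage_lower, r$first_stage_upper),
      ifelse(is.na(r$first_stage_f), "--",
             sprintf("%.1f", r$first_stage_f)),
      fmt(r$second_stage, r$second_stage_lower, r$second_stage_upper),
      fmt(r$ols, r$ols_lower, r$ols_upper),
      ifelse(nzchar(r$note), paste0("  [", r$note, "]"), "")))
  }
  lines
}

#' Write a results table to disk
#'
#' Emits machine-readable CSV and JSON (with the full audit report) and a
#' human-readable text table.
#'
#' @param results A `dentiv_results` data.frame.
#' @param dir Output directory (created if absent).
#' @param name Basename for the three files.
#' @return Invisibly, the paths written.
#' @export
write_results <- function(results, dir, name = "results") {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- c(csv = file.path(dir, paste0(name, ".csv")),
             json = file.path(dir, paste0(name, ".json")),
             txt = file.path(dir, paste0(name, ".txt")))
  utils::write.csv(as.data.frame(results), paths[["csv"]], row.names = FALSE)
  jsonlite::write_json(
    list(report = attr(results, "report"),
         results = as.data.frame(results)),
    paths[["json"]], auto_unbox = TRUE, digits = NA, dataframe = "rows")
  writeLines(format_results(results), paths[["txt"]])
  invisible(paths)
}
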