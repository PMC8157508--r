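# Frame assembly: joins the survey table with the exposure instrument,
# applies the cohort filter and complete-case exclusions, codes treatment
# and outcome, and builds the covariate design (year-of-birth, survey
# wave, gender, state indicator columns plus intercept).

SURVEY_COLUMNS <- c("respondent_id", "birth_year", "wave", "gender", "state",
                    "county_id", "teeth_bracket", paste0("phq", 1:8))

#' Study configuration
#'
#' Bundles the analysis settings: cohort filter, treatment coding and
#' sensitivity value sets, PHQ day mapping, covariance type, and the
#' stratification thresholds. Thresholds are explicit here and echoed in
#' every emitted report.
#'
#' @param census_path,survey_path Optional input CSV paths (used by
#'   [read_study_inputs()] and the command-line wrapper).
#' @param birth_cohort Inclusive birth-year filter; default 1940-1978, the
#'   cohorts whose childhood falls inside the fluoridation census span.
#' @param coding Main [tooth_coding()]; default mid-points.
#' @param sensitivity Named list of length-4 value sets for
#'   [sensitivity_codings()] re-runs (e.g. mean/median/mode replacements).
#' @param day_mapping A [phq8_day_mapping()].
#' @param se_type `"HC1"`, `"classical"` or `"cluster"`.
#' @param cluster_on `"county"` or `"state"` when `se_type = "cluster"`.
#' @param birth_year_terms `"factor"` (one indicator per year, default) or
#'   `"linear"` (a single trend term).
#' @param age_split Age threshold for the age stratification; default 50.
#' @param birth_year_split Last birth year of the older cohort stratum;
#'   default 1959 (the cohort midpoint).
#' @param caseness_cutoff PHQ-8 total defining probable major depression.
#' @param seed Seed for any resampling (none is used by the core analyses;
#'   kept for reproducibility of extensions).
#' @return An object of class `study_config`.
#' @export
study_config <- function(census_path = NULL, survey_path = NULL,
                         birth_cohort = c(1940L, 1978L),
                         coding = midpoint_coding(),
                         sensitivity = NULL,
                         day_mapping = phq8_day_mapping(),
                         se_type = c("HC1", "classical", "cluster"),
                         cluster_on = c("county", "state"),
                         birth_year_terms = c("factor", "linear"),
                         age_split = 50L,
                         birth_year_split = 1959L,
                         caseness_cutoff = 10L,
                         seed = 1L) {
  se_type <- match.arg(se_type)
  cluster_on <- match.arg(cluster_on)
  birth_year_terms <- match.arg(birth_year_terms)
  birth_cohort <- check_year_pair(birth_cohort, "birth_cohort")
  if (!inherits(coding, "tooth_coding")) stop_config("`coding` must be a tooth_coding")
  if (!inherits(day_mapping, "phq8_day_mapping")) {
    stop_config("`day_mapping` must be a phq8_day_mapping")
  }
  sens <- if (!is.null(sensitivity)) sensitivity_codings(sensitivity)
  structure(list(
    census_path = census_path, survey_path = survey_path,
    birth_cohort = birth_cohort, coding = coding,
    sensitivity = sens, day_mapping = day_mapping,
    se_type = se_type, cluster_on = cluster_on,
    birth_year_terms = birth_year_terms,
    age_split = as.integer(age_split),
    birth_year_split = as.integer(birth_year_split),
    caseness_cutoff = as.integer(caseness_cutoff),
    seed = as.integer(seed)
  ), class = "study_config")
}

#' Read a study configuration from YAML
#'
#' Recognised keys mirror the [study_config()] arguments; `coding` and
#' `sensitivity` entries are given as 4-value lists.
#'
#' @param path YAML file path.
#' @return A `study_config`.
#' @export
read_study_config <- function(path) {
  raw <- yaml::read_yaml(path)
  args <- list()
  for (key in c("census_path", "survey_path", "birth_cohort", "se_type",
                "cluster_on", "birth_year_terms", "age_split",
                "birth_year_split", "caseness_cutoff", "seed")) {
    if (!is.null(raw[[key]])) args[[key]] <- unlist(raw[[key]])
  }
  if (!is.null(raw$coding)) {
    args$coding <- tooth_coding(unlist(raw$coding),
                                name = raw$coding_name %||% "config")
  }
  if (!is.null(raw$day_mapping)) {
    args$day_mapping <- phq8_day_mapping(unlist(raw$day_mapping))
  }
  if (!is.null(raw$sensitivity)) {
    args$sensitivity <- lapply(raw$sensitivity, unlist)
  }
  do.call(study_config, args)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read the census and survey inputs named in a study config
#'
#' @param config A [study_config()] with `census_path` and `survey_path`.
#' @return A list with `census` and `survey` data.frames.
#' @export
read_study_inputs <- function(config) {
  if (is.null(config$census_path) || is.null(config$survey_path)) {
    stop_config("config must name census_path and survey_path")
  }
  list(census = utils::read.csv(config$census_path, stringsAsFactors = FALSE),
       survey = utils::read.csv(config$survey_path, stringsAsFactors = FALSE))
}

validate_survey <- function(survey) {
  missing_cols <- setdiff(SURVEY_COLUMNS, names(survey))
  if (length(missing_cols)) {
    stop_validation(
      sprintf("survey table is missing column(s): %s",
              paste(missing_cols, collapse = ", ")),
      columns = missing_cols)
  }
  invisible(survey)
}

#' Prepare the analysis dataset
#'
#' Applies, in order: schema validation, the birth-cohort filter, bracket
#' validity, PHQ complete-case exclusion, and the exposure join. Every
#' exclusion step is logged with the number of rows removed.
#'
#' @param survey Survey data.frame (see the survey CSV schema).
#' @param census Fluoridation census data.frame.
#' @param config A [study_config()].
#' @return A list with `data` (scored, coded, exposure-joined rows) and
#'   `exclusions` (a data.frame audit trail).
#' @export
prepare_study_data <- function(survey, census, config = study_config()) {
  validate_survey(survey)
  steps <- list()
  note <- function(step, before, after) {
    steps[[length(steps) + 1L]] <<- data.frame(
      step = step, removed = before - after, remaining = after)
  }

  n0 <- nrow(survey)
  keep <- !is.na(survey$birth_year) &
    survey$birth_year >= config$birth_cohort[1] &
    survey$birth_year <= config$birth_cohort[2]
  survey <- survey[keep, , drop = FALSE]
  note("birth cohort filter", n0, nrow(survey))

  n1 <- nrow(survey)
  ok_bracket <- !is.na(survey$teeth_bracket) &
    survey$teeth_bracket %in% tooth_brackets()
  survey <- survey[ok_bracket, , drop = FALSE]
  note("valid tooth-loss bracket", n1, nrow(survey))

  n2 <- nrow(survey)
  scores <- phq8_score(survey[paste0("phq", 1:8)],
                       mapping = config$day_mapping,
                       cutoff = config$caseness_cutoff)
  survey <- survey[scores$complete, , drop = FALSE]
  scores <- scores[scores$complete, , drop = FALSE]
  note("complete PHQ-8 items", n2, nrow(survey))

  n3 <- nrow(survey)
  cov_ok <- stats::complete.cases(survey[c("wave", "gender", "state",
                                           "county_id")])
  survey <- survey[cov_ok, , drop = FALSE]
  scores <- scores[cov_ok, , drop = FALSE]
  note("complete covariates", n3, nrow(survey))

  if (!nrow(survey)) {
    dentiv_stop("dentiv_empty_frame_error",
                "no respondents remain after exclusions",
                exclusions = do.call(rbind, steps))
  }

  z <- compute_exposure(census, survey)$exposure_z
  data <- survey
  data$exposure_z <- z
  data$phq_total <- scores$total
  data$phq_case <- as.numeric(scores$probable_major_depression)
  for (j in 1:8) data[[paste0("item", j, "_score")]] <- scores[[paste0("item", j)]]
  data$age <- data$wave - data$birth_year

  list(data = data, exclusions = do.call(rbind, steps))
}

# covariate design matrix: intercept + contrasts, reference level = first
# lexicographically; constant factors are dropped (stratified subsets)
covariate_design <- function(design, birth_year_terms = "factor") {
  df <- data.frame(row = seq_len(nrow(design)))
  if (birth_year_terms == "factor") {
    df$birth_year <- factor(design$birth_year)
  } else {
    df$birth_year_trend <- as.numeric(design$birth_year)
  }
  df$wave <- factor(design$wave)
  df$gender <- factor(design$gender)
  df$state <- factor(design$state)
  terms <- names(df)[-1]
  keep <- vapply(terms, function(v) {
    !is.factor(df[[v]]) || nlevels(droplevels(df[[v]])) > 1L
  }, logical(1))
  terms <- terms[keep]
  if (!length(terms)) {
    return(matrix(1, nrow(design), 1L, dimnames = list(NULL, "(Intercept)")))
  }
  form <- stats::as.formula(paste("~", paste(terms, collapse = " + ")))
  stats::model.matrix(form, droplevels(df))
}

#' Build an analysis frame from prepared data
#'
#' @param data The `data` element of [prepare_study_data()].
#' @param outcome `"total"`, `"caseness"`, or `"item1"`..`"item8"`.
#' @param treatment `"continuous"`, `"any_loss"` or `"edentulous"`; the
#'   edentulous contrast restricts the frame to respondents with at least
#'   one lost tooth.
#' @param coding A [tooth_coding()] used when `treatment = "continuous"`.
#' @param config A [study_config()] (covariate parameterisation, cluster).
#' @return An [analysis_frame()]; the rows dropped by the edentulous
#'   restriction are recorded in the `n_excluded_contrast` attribute.
#' @export
build_frame <- function(data, outcome = "total", treatment = "continuous",
                        coding = midpoint_coding(),
                        config = study_config()) {
  n_drop <- 0L
  if (treatment == "continuous") {
    t <- code_continuous(data$teeth_bracket, coding)
  } else {
    t <- code_binary(data$teeth_bracket, treatment)
    drop_rows <- is.na(t)
    n_drop <- sum(drop_rows)
    data <- data[!drop_rows, , drop = FALSE]
    t <- t[!drop_rows]
  }
  y <- switch(outcome,
              total = data$phq_total,
              caseness = data$phq_case,
              {
                col <- paste0(outcome, "_score")
                if (!col %in% names(data)) {
                  stop_config(sprintf("unknown outcome '%s'", outcome))
                }
                data[[col]]
              })
  X <- covariate_design(data, config$birth_year_terms)
  cluster <- if (config$se_type == "cluster") {
    if (config$cluster_on == "county") data$county_id else data$state
  }
  frame <- analysis_frame(
    y = y, t = t, z = data$exposure_z, X = X,
    outcome_scale = if (outcome == "caseness") "probability" else "score",
    cluster = cluster)
  attr(frame, "n_excluded_contrast") <- n_drop
  frame
}

#' Assemble the main analysis frame from raw inputs
#'
#' Convenience wrapper: [prepare_study_data()] then [build_frame()] for
#' the main analysis (mid-point-coded treatment, PHQ-8 total outcome).
#' The exclusion log is attached as the `exclusions` attribute.
#'
#' @inheritParams prepare_study_data
#' @return An [analysis_frame()].
#' @export
assemble_frame <- function(survey, census, config = study_config()) {
  prep <- prepare_study_data(survey, census, config)
  frame <- build_frame(prep$data, "total", "continuous", config$coding, config)
  attr(frame, "exclusions") <- prep$exclusions
  frame
}
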