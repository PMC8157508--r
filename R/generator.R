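# Synthetic population generator.
#
# Emulates the study's data structure: a staggered county-level
# fluoridation rollout (census table), cohort-specific childhood exposure,
# and survey respondents whose tooth loss and depression share an
# unobserved confounder, with a KNOWN causal effect wired in so estimator
# recovery can be tested.
#
# Structural model per respondent i:
#   Z_i  = childhood fluoride exposure (ages 5-14 accumulation, in [0, 1])
#   U_i  ~ N(0, 1)                          unobserved confounder
#   L_i  = h_i + pi * Z_i + x_i'cT + gT * U_i + eT_i   latent tooth loss
#   T*_i = clamp(round(L_i), 0, 28)         true lost-teeth count
#   bracket_i = none / 1-5 / 6+ not all / all, from T*_i
#   D_i  = alpha + beta_i * T*_i + x_i'cY + gY * U_i + eY_i   latent depression
#   PHQ item j: score ~ Binomial(3, lambda_j * clamp(D_i, 0, 24)), then a
#   day count drawn uniformly inside that score's day band.
#
# h_i (individual susceptibility) is uniform on a range WIDER than the
# dental arch. That choice is load-bearing: under a locally flat latent
# distribution the bracket mid-points are exactly the within-bracket
# conditional means of T*, so the mid-point-coded treatment differs from
# T* by mean-zero noise that is uncorrelated with any function of the
# observed data -- mid-point coding is then exactly consistent for beta,
# and the omitted-variable bias of OLS has a closed form (see truth.R).
# The item construction makes E[scored total | D] = clamp(D, 0, 24), so
# the configured beta lives on the scored-outcome scale.

#' Generator configuration
#'
#' Defaults define the package's reference synthetic study: a comfortably
#' strong instrument (first-stage F in the tens at n = 5000, the same
#' qualitative regime as a well-identified fluoridation natural
#' experiment), a true causal effect of 0.15 PHQ-8 points per lost tooth,
#' and confounding calibrated so the expected OLS bias is about +0.05.
#'
#' @param n_counties Number of counties (> 0).
#' @param n_respondents Number of survey respondents (> 0).
#' @param birth_year_range Inclusive cohort span; default 1940-1978.
#' @param rollout_year_range Census span; default 1945-1992.
#' @param coverage_shape Beta(shape1, shape2) parameters for each county's
#'   post-adoption coverage proportion.
#' @param coverage_trajectory `"constant"` (county jumps to its coverage at
#'   adoption) or `"ramp"` (linear ramp over `ramp_years`).
#' @param ramp_years Ramp length in years when `coverage_trajectory="ramp"`.
#' @param n_states Number of states counties are nested in; default
#'   `min(12, n_counties)`.
#' @param true_beta Causal effect, PHQ-8 points per lost tooth.
#' @param beta_male_shift Additive shift of `true_beta` for male
#'   respondents (0 = homogeneous effect); hook for heterogeneous-effect
#'   recovery tests.
#' @param first_stage_pi Latent teeth per unit instrument (<= 0: fluoride
#'   exposure prevents tooth loss).
#' @param confounder_gamma_T Teeth per unit confounder.
#' @param confounder_gamma_Y PHQ points per unit confounder.
#' @param susceptibility_range Support of the uniform individual
#'   susceptibility; must extend several noise SDs beyond \[0, 28\] (see
#'   the consistency note above).
#' @param noise_sd_T,noise_sd_latentY Positive noise SDs of the tooth and
#'   depression equations.
#' @param alpha_Y Baseline latent depression.
#' @param covariate_effects Named list of covariate shifts: `gender_T`,
#'   `birth_year_T`, `state_amplitude_T` on the tooth side; `gender_Y`,
#'   `birth_year_Y`, `state_amplitude_Y`, `wave_Y` on the depression side.
#'   Gender effects apply to male respondents; birth-year effects are per
#'   year, centred on the cohort midpoint.
#' @param item_loadings Eight nonnegative PHQ item loadings summing to 1;
#'   equal loadings spread depression evenly over the items.
#' @param prop_male Probability a respondent is male.
#' @param seed Integer seed; all generator randomness derives from it.
#' @return An object of class `generator_config`.
#' @export
generator_config <- function(n_counties = 120L,
                             n_respondents = 5000L,
                             birth_year_range = c(1940L, 1978L),
                             rollout_year_range = c(1945L, 1992L),
                             coverage_shape = c(5, 2),
                             coverage_trajectory = c("constant", "ramp"),
                             ramp_years = 5L,
                             n_states = NULL,
                             true_beta = 0.15,
                             beta_male_shift = 0,
                             first_stage_pi = -9,
                             confounder_gamma_T = 3.5,
                             confounder_gamma_Y = 4.35,
                             susceptibility_range = c(-15, 51),
                             noise_sd_T = 1,
                             noise_sd_latentY = 1,
                             alpha_Y = 10,
                             covariate_effects = list(),
                             item_loadings = rep(1 / 8, 8),
                             prop_male = 0.387,
                             seed = 1L) {
  coverage_trajectory <- match.arg(coverage_trajectory)
  if (!is_count(n_counties)) stop_config("`n_counties` must be a positive integer")
  if (!is_count(n_respondents)) stop_config("`n_respondents` must be a positive integer")
  if (is.null(n_states)) n_states <- min(12L, n_counties)
  if (!is_count(n_states) || n_states > n_counties) {
    stop_config("`n_states` must be a positive integer <= n_counties")
  }
  birth_year_range <- check_year_pair(birth_year_range, "birth_year_range")
  rollout_year_range <- check_year_pair(rollout_year_range, "rollout_year_range")
  if (!(is.numeric(coverage_shape) && length(coverage_shape) == 2L &&
        all(coverage_shape > 0))) {
    stop_config("`coverage_shape` must be two positive Beta parameters")
  }
  if (!is_count(ramp_years)) stop_config("`ramp_years` must be a positive integer")
  for (nm in c("true_beta", "beta_male_shift", "first_stage_pi",
               "confounder_gamma_T", "confounder_gamma_Y", "alpha_Y")) {
    if (!is_scalar_num(get(nm))) stop_config(sprintf("`%s` must be a finite number", nm))
  }
  if (first_stage_pi > 0) {
    stop_config("`first_stage_pi` must be <= 0 (fluoride exposure prevents tooth loss)")
  }
  if (!(is_scalar_num(noise_sd_T) && noise_sd_T > 0) ||
      !(is_scalar_num(noise_sd_latentY) && noise_sd_latentY > 0)) {
    stop_config("noise SDs must be positive")
  }
  if (!(is.numeric(susceptibility_range) && length(susceptibility_range) == 2L &&
        diff(susceptibility_range) > 0)) {
    stop_config("`susceptibility_range` must be an increasing pair")
  }
  if (!(is.numeric(item_loadings) && length(item_loadings) == 8L &&
        all(item_loadings >= 0) && abs(sum(item_loadings) - 1) < 1e-8)) {
    stop_config("`item_loadings` must be 8 nonnegative weights summing to 1")
  }
  if (!is_prob(prop_male)) stop_config("`prop_male` must be a probability")
  if (!is_count(abs(seed) + 1)) stop_config("`seed` must be an integer")

  ce_default <- list(gender_T = 0.5, birth_year_T = -0.04,
                     state_amplitude_T = 0.5,
                     gender_Y = -0.6, birth_year_Y = 0.01,
                     state_amplitude_Y = 0.3, wave_Y = 0.1)
  unknown <- setdiff(names(covariate_effects), names(ce_default))
  if (length(unknown)) {
    stop_config(sprintf("unknown covariate effect(s): %s",
                        paste(unknown, collapse = ", ")))
  }
  ce_default[names(covariate_effects)] <- covariate_effects

  structure(list(
    n_counties = as.integer(n_counties),
    n_respondents = as.integer(n_respondents),
    birth_year_range = birth_year_range,
    rollout_year_range = rollout_year_range,
    coverage_shape = as.numeric(coverage_shape),
    coverage_trajectory = coverage_trajectory,
    ramp_years = as.integer(ramp_years),
    n_states = as.integer(n_states),
    true_beta = true_beta,
    beta_male_shift = beta_male_shift,
    first_stage_pi = first_stage_pi,
    confounder_gamma_T = confounder_gamma_T,
    confounder_gamma_Y = confounder_gamma_Y,
    susceptibility_range = as.numeric(susceptibility_range),
    noise_sd_T = noise_sd_T,
    noise_sd_latentY = noise_sd_latentY,
    alpha_Y = alpha_Y,
    covariate_effects = ce_default,
    item_loadings = as.numeric(item_loadings),
    prop_male = prop_male,
    seed = as.integer(seed)
  ), class = "generator_config")
}

#' @export
print.generator_config <- function(x, ...) {
  cat(sprintf(
    "Synthetic study config: %d respondents, %d counties in %d states, cohorts %d-%d\n",
    x$n_respondents, x$n_counties, x$n_states,
    x$birth_year_range[1], x$birth_year_range[2]))
  cat(sprintf("  true beta = %g PHQ pts/tooth, first-stage pi = %g, gamma = (%g, %g), seed %d\n",
              x$true_beta, x$first_stage_pi, x$confounder_gamma_T,
              x$confounder_gamma_Y, x$seed))
  invisible(x)
}

state_ids <- function(config) sprintf("S%02d", seq_len(config$n_states))

county_table <- function(config) {
  data.frame(
    county_id = sprintf("C%03d", seq_len(config$n_counties)),
    state = state_ids(config)[rep_len(seq_len(config$n_states),
                                      config$n_counties)],
    stringsAsFactors = FALSE
  )
}

#' Generate a fluoridation census
#'
#' One row per (county, year) across the rollout span. Each county draws an
#' adoption year uniformly from the span and a post-adoption coverage from
#' the configured Beta distribution; coverage is 0 before adoption and
#' either constant or linearly ramping after.
#'
#' @param config A [generator_config()].
#' @return A census data.frame (`county_id`, `year`,
#'   `proportion_fluoridated`) with a `counties` attribute recording each
#'   county's state, adoption year and coverage.
#' @export
generate_census <- function(config) {
  stopifnot(inherits(config, "generator_config"))
  set.seed(config$seed)
  counties <- county_table(config)
  span <- config$rollout_year_range
  years <- span[1]:span[2]
  counties$adoption_year <- sample(years, config$n_counties, replace = TRUE)
  counties$coverage <- stats::rbeta(config$n_counties,
                                    config$coverage_shape[1],
                                    config$coverage_shape[2])
  grid <- expand.grid(year = years,
                      county_idx = seq_len(config$n_counties))
  since <- grid$year - counties$adoption_year[grid$county_idx] + 1L
  frac <- if (config$coverage_trajectory == "constant") {
    as.numeric(since >= 1L)
  } else {
    pmin(1, pmax(0, since) / config$ramp_years)
  }
  census <- data.frame(
    county_id = counties$county_id[grid$county_idx],
    year = grid$year,
    proportion_fluoridated = counties$coverage[grid$county_idx] * frac,
    stringsAsFactors = FALSE
  )
  attr(census, "counties") <- counties
  census
}

# day band for each item score under the default BRFSS day mapping
score_day_band <- function(mapping = phq8_day_mapping()) {
  b <- mapping$breaks
  rbind(c(0, b[1] - 1L), c(b[1], b[2] - 1L), c(b[2], b[3] - 1L), c(b[3], 14L))
}

#' Generate survey respondents and the truth record
#'
#' Draws respondents (county, birth year, wave, gender, strata), computes
#' their childhood fluoride exposure with the same accumulation rule as
#' [compute_exposure()], and simulates tooth loss, the reported bracket and
#' the eight PHQ item day counts from the structural model. Returns the
#' survey table, a [TruthRecord][truth_record] holding the generating
#' parameters and the analytically expected OLS bias (never consumed by the
#' estimation functions), and a latent diagnostics table for tests.
#'
#' @param config A [generator_config()].
#' @param census A census from [generate_census()] (or any census whose
#'   year span covers the configured rollout span).
#' @return A list with elements `respondents`, `truth`, `latent`.
#' @export
generate_respondents <- function(config, census) {
  stopifnot(inherits(config, "generator_config"))
  validate_census(census)
  span <- config$rollout_year_range
  if (min(census$year) > span[1] || max(census$year) < span[2]) {
    stop_integrity("census year span does not cover the configured rollout span")
  }
  counties <- attr(census, "counties")
  if (is.null(counties)) {
    counties <- data.frame(county_id = unique(census$county_id),
                           stringsAsFactors = FALSE)
    counties$state <- state_ids(config)[rep_len(seq_len(config$n_states),
                                                nrow(counties))]
  }
  n <- config$n_respondents
  ce <- config$covariate_effects

  set.seed(config$seed + 1L)
  idx <- sample.int(nrow(counties), n, replace = TRUE)
  birth_year <- sample(seq.int(config$birth_year_range[1],
                               config$birth_year_range[2]), n, replace = TRUE)
  wave <- sample(c(2006L, 2008L, 2010L), n, replace = TRUE)
  male <- stats::rbinom(n, 1L, config$prop_male)
  income <- sample(c("lt50k", "ge50k"), n, replace = TRUE)
  dental <- sample(c("visit_within_year", "no_recent_visit"), n,
                   replace = TRUE, prob = c(0.6, 0.4))

  resp <- data.frame(
    respondent_id = sprintf("R%06d", seq_len(n)),
    birth_year = birth_year,
    wave = wave,
    gender = ifelse(male == 1L, "male", "female"),
    state = counties$state[idx],
    county_id = counties$county_id[idx],
    stringsAsFactors = FALSE
  )

  z <- compute_exposure(census, resp)$exposure_z

  by_mid <- mean(config$birth_year_range)
  state_fx <- function(amp) {
    s <- seq(-amp, amp, length.out = config$n_states)
    s[match(counties$state[idx], state_ids(config))]
  }
  shift_T <- config$first_stage_pi * z +
    ce$gender_T * male +
    ce$birth_year_T * (birth_year - by_mid) +
    state_fx(ce$state_amplitude_T)
  offset_Y <- config$alpha_Y +
    ce$gender_Y * male +
    ce$birth_year_Y * (birth_year - by_mid) +
    state_fx(ce$state_amplitude_Y) +
    ce$wave_Y * (wave - 2008) / 2

  u <- stats::rnorm(n)
  h <- stats::runif(n, config$susceptibility_range[1],
                    config$susceptibility_range[2])
  latent_T <- h + shift_T + config$confounder_gamma_T * u +
    stats::rnorm(n, sd = config$noise_sd_T)
  t_star <- pmin(28L, pmax(0L, as.integer(round(latent_T))))
  bracket <- cut(t_star, breaks = c(-0.5, 0.5, 5.5, 27.5, 28.5),
                 labels = tooth_brackets())
  bracket <- as.character(bracket)

  beta_i <- config$true_beta + config$beta_male_shift * male
  d <- offset_Y + beta_i * t_star + config$confounder_gamma_Y * u +
    stats::rnorm(n, sd = config$noise_sd_latentY)

  d24 <- pmin(24, pmax(0, d))
  band <- score_day_band()
  items <- matrix(0L, n, 8L, dimnames = list(NULL, paste0("phq", 1:8)))
  for (j in 1:8) {
    p <- pmin(1, config$item_loadings[j] * d24 / 3)
    sc <- stats::rbinom(n, 3L, p)
    lo <- band[sc + 1L, 1L]
    hi <- band[sc + 1L, 2L]
    items[, j] <- lo + as.integer(floor(stats::runif(n) * (hi - lo + 1L)))
  }

  resp$teeth_bracket <- bracket
  resp <- cbind(resp, as.data.frame(items))
  resp$income_stratum <- income
  resp$dental_visit_stratum <- dental

  truth <- truth_record(config, z = z, male = male,
                        shift_T = shift_T, offset_Y = offset_Y,
                        design = data.frame(
                          birth_year = birth_year, wave = wave,
                          gender = resp$gender, state = resp$state,
                          stringsAsFactors = FALSE))

  latent <- data.frame(respondent_id = resp$respondent_id,
                       exposure_z = z, confounder_u = u,
                       t_star = t_star, latent_depression = d)

  list(respondents = resp, truth = truth, latent = latent)
}

#' Generate the full synthetic study
#'
#' Convenience wrapper: census plus respondents plus truth.
#'
#' @param config A [generator_config()].
#' @return A list with `census`, `respondents`, `truth`, `latent`.
#' @export
simulate_study <- function(config = generator_config()) {
  census <- generate_census(config)
  gen <- generate_respondents(config, census)
  c(list(census = census), gen)
}

#' Write a synthetic study to disk
#'
#' Writes the census CSV, the survey CSV and the truth JSON sidecar.
#'
#' @param study A list from [simulate_study()].
#' @param dir Output directory (created if absent).
#' @return Invisibly, the paths written.
#' @export
write_study <- function(study, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- c(
    census = file.path(dir, "fluoridation_census.csv"),
    survey = file.path(dir, "survey.csv"),
    truth = file.path(dir, "truth.json")
  )
  utils::write.csv(study$census, paths[["census"]], row.names = FALSE)
  utils::write.csv(study$respondents, paths[["survey"]], row.names = FALSE)
  jsonlite::write_json(unclass(study$truth), paths[["truth"]],
                       auto_unbox = TRUE, digits = NA)
  invisible(paths)
}
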