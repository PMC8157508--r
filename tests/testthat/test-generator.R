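# Synthetic population generator: rollout structure, determinism, the
# structural model's noiseless limit, and the analytic truth record.

zero_effects <- list(gender_T = 0, birth_year_T = 0, state_amplitude_T = 0,
                     gender_Y = 0, birth_year_Y = 0, state_amplitude_Y = 0,
                     wave_Y = 0)

test_that("census is a step function of adoption year and coverage", {
  cfg <- generator_config(n_counties = 8, n_respondents = 10, seed = 3)
  census <- generate_census(cfg)
  counties <- attr(census, "counties")
  for (i in seq_len(nrow(counties))) {
    rows <- census[census$county_id == counties$county_id[i], ]
    rows <- rows[order(rows$year), ]
    pre <- rows$proportion_fluoridated[rows$year < counties$adoption_year[i]]
    post <- rows$proportion_fluoridated[rows$year >= counties$adoption_year[i]]
    expect_true(all(pre == 0))
    expect_true(all(post == counties$coverage[i]))
  }
  expect_equal(nrow(census), 8 * 48)  # one row per county-year, 1945-1992
  # ramp trajectory rises linearly to the coverage
  cfgr <- generator_config(n_counties = 2, n_respondents = 10,
                           coverage_trajectory = "ramp", ramp_years = 4,
                           seed = 3)
  cr <- generate_census(cfgr)
  cs <- attr(cr, "counties")
  rows <- cr[cr$county_id == cs$county_id[1], ]
  ay <- cs$adoption_year[1]
  got <- rows$proportion_fluoridated[match(ay + 0:3, rows$year)]
  want <- cs$coverage[1] * (1:4) / 4
  expect_equal(got[!is.na(got)], want[seq_along(got[!is.na(got)])])
})

test_that("invalid configurations are refused", {
  expect_error(generator_config(n_counties = 0), class = "dentiv_config_error")
  expect_error(generator_config(noise_sd_T = 0), class = "dentiv_config_error")
  expect_error(generator_config(first_stage_pi = 1),
               class = "dentiv_config_error")
  expect_error(generator_config(prop_male = 1.4),
               class = "dentiv_config_error")
  expect_error(generator_config(birth_year_range = c(1978, 1940)),
               class = "dentiv_config_error")
  expect_error(generator_config(item_loadings = rep(1, 8)),
               class = "dentiv_config_error")
})

test_that("generation is deterministic given config and seed", {
  cfg <- generator_config(n_respondents = 300, n_counties = 20, seed = 99)
  a <- simulate_study(cfg)
  b <- simulate_study(cfg)
  expect_identical(a$census, b$census)
  expect_identical(a$respondents, b$respondents)
  expect_identical(unclass(a$truth), unclass(b$truth))
  c <- simulate_study(generator_config(n_respondents = 300, n_counties = 20,
                                       seed = 100))
  expect_false(identical(a$respondents, c$respondents))
})

test_that("reported bracket is the deterministic function of true teeth", {
  st <- simulate_study(generator_config(n_respondents = 2000, seed = 5))
  t_star <- st$latent$t_star
  want <- ifelse(t_star == 0, "none",
                 ifelse(t_star <= 5, "one_to_five",
                        ifelse(t_star <= 27, "six_plus_not_all", "all")))
  expect_identical(st$respondents$teeth_bracket, want)
  expect_true(all(t_star >= 0 & t_star <= 28))
  # census/county integrity
  expect_true(all(st$respondents$county_id %in% st$census$county_id))
  short_census <- st$census[st$census$year >= 1950, ]
  expect_error(generate_respondents(generator_config(seed = 5), short_census),
               class = "dentiv_integrity_error")
})

test_that("noiseless limit: scored outcome rises by beta per true tooth", {
  cfg <- generator_config(
    n_respondents = 40000, n_counties = 40, true_beta = 0.15,
    confounder_gamma_T = 1e-6, confounder_gamma_Y = 0,
    noise_sd_T = 1e-6, noise_sd_latentY = 1e-6,
    covariate_effects = zero_effects, seed = 17)
  st <- simulate_study(cfg)
  prep <- prepare_study_data(st$respondents, st$census)
  # group mean of the scored total by true tooth count, away from the
  # clamping edges of the latent depression scale
  ts <- st$latent$t_star[match(prep$data$respondent_id,
                               st$respondents$respondent_id)]
  keep <- ts >= 2 & ts <= 26
  gm <- tapply(prep$data$phq_total[keep], ts[keep], mean)
  slope <- coef(lm(gm ~ as.numeric(names(gm))))[2]
  expect_equal(unname(slope), 0.15, tolerance = 0.01)
})

test_that("a null first stage leaves exposure uncorrelated with teeth", {
  cfg <- generator_config(n_respondents = 10000, first_stage_pi = 0,
                          seed = 23)
  st <- simulate_study(cfg)
  r <- cor(st$latent$exposure_z, st$latent$t_star)
  expect_lt(abs(r), 0.05)
})

test_that("exclusion restriction: instrument enters only through teeth", {
  st <- simulate_study(generator_config(n_respondents = 20000, seed = 31))
  lat <- st$latent
  d <- st$respondents
  X <- dentiv:::covariate_design(d)
  fit <- lm(lat$latent_depression ~ lat$exposure_z + lat$t_star + X - 1)
  ct <- summary(fit)$coefficients["lat$exposure_z", ]
  expect_lt(abs(ct["Estimate"]), 3 * ct["Std. Error"] + 1e-8)
})

test_that("truth record matches brute-force moments of the generator", {
  st <- simulate_study(generator_config(n_respondents = 50000, seed = 41))
  prep <- prepare_study_data(st$respondents, st$census)
  fr <- build_frame(prep$data, "total", "continuous")
  ols <- fit_ols(fr)
  # analytic expected OLS slope within 3 empirical SEs
  expect_lt(abs(ols$estimate - st$truth$ols_slope_expected), 3 * ols$se)
  # analytic coded first stage within 3 empirical SEs
  fs <- fit_first_stage(fr)
  expect_lt(abs(fs$estimate - st$truth$first_stage_pi_coded), 3 * fs$se)
  # mid-point coding is conditional-mean consistent by construction,
  # so the analytic IV slope sits at the true effect
  expect_equal(st$truth$iv_slope_expected, st$truth$true_beta,
               tolerance = 0.02)
  expect_equal(st$truth$true_beta, 0.15)
})

test_that("written study files round-trip through the pipeline", {
  dir <- withr::local_tempdir()
  st <- simulate_study(generator_config(n_respondents = 400,
                                        n_counties = 15, seed = 53))
  paths <- write_study(st, dir)
  expect_true(all(file.exists(paths)))
  census <- utils::read.csv(paths[["census"]])
  survey <- utils::read.csv(paths[["survey"]], stringsAsFactors = FALSE)
  truth <- jsonlite::read_json(paths[["truth"]])
  expect_equal(truth$true_beta, st$truth$true_beta)
  prep <- prepare_study_data(survey, census)
  expect_equal(nrow(prep$data), 400)
  fr <- build_frame(prep$data, "total", "continuous")
  expect_s3_class(fr, "analysis_frame")
})
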