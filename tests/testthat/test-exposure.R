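# Instrument construction: the ages 5-14 accumulation of county
# fluoridation proportions, rescaled to [0, 1].

test_that("exposure hits the hand-checkable bounds and mid case", {
  # full coverage in all ten ages -> 1
  z <- compute_exposure(census_for_ages(rep(1, 10)), one_respondent())
  expect_equal(z$exposure_z, 1.0)
  # no coverage -> 0
  z <- compute_exposure(census_for_ages(rep(0, 10)), one_respondent())
  expect_equal(z$exposure_z, 0.0)
  # coverage in five of the ten ages -> 0.5 (hand sum 5/10)
  z <- compute_exposure(census_for_ages(c(0, 0, 0, 0, 0, 1, 1, 1, 1, 1)),
                        one_respondent())
  expect_equal(z$exposure_z, 0.5)
})

test_that("years outside the census span use the boundary rule", {
  # census 1945-1992; county fully fluoridated throughout
  census <- data.frame(county_id = "A", year = 1945:1992,
                       proportion_fluoridated = 1)
  # born 1936: ages 5-14 are 1941-1950; 1941-1944 precede the census -> 0
  z <- compute_exposure(census, one_respondent(birth_year = 1936))
  expect_equal(z$exposure_z, 6 / 10)
  # born 1985: ages 5-14 are 1990-1999; years past 1992 carry the final value
  z <- compute_exposure(census, one_respondent(birth_year = 1985))
  expect_equal(z$exposure_z, 1.0)
  # final value is the county's own last observation, not 1:
  # ages 1990-1991 are observed at 1.0, 1992 at 0.4, and 1993-1999
  # carry the 1992 value forward
  census$proportion_fluoridated[census$year == 1992] <- 0.4
  z <- compute_exposure(census, one_respondent(birth_year = 1985))
  expect_equal(z$exposure_z, (2 * 1 + 8 * 0.4) / 10)
})

test_that("exposure is monotone in any single year's proportion", {
  set.seed(42)
  for (rep in 1:100) {
    props <- runif(10)
    base <- compute_exposure(census_for_ages(props),
                             one_respondent())$exposure_z
    j <- sample(10, 1)
    props2 <- props
    props2[j] <- min(1, props2[j] + runif(1, 0, 1 - props2[j]))
    bumped <- compute_exposure(census_for_ages(props2),
                               one_respondent())$exposure_z
    expect_gte(bumped, base)
    expect_equal(bumped - base, (props2[j] - props[j]) / 10)
  }
})

test_that("exposure is invariant to a common shift of all years", {
  set.seed(7)
  props <- runif(10)
  z0 <- compute_exposure(census_for_ages(props, birth_year = 1950),
                         one_respondent(1950))$exposure_z
  shifted <- census_for_ages(props, birth_year = 1950 + 13,
                             span = c(1945 + 13, 1992 + 13))
  z1 <- compute_exposure(shifted, one_respondent(1950 + 13))$exposure_z
  expect_equal(z0, z1)
})

test_that("exposure input validation", {
  census <- census_for_ages(rep(0.5, 10))
  # unknown county named in the error
  err <- expect_error(
    compute_exposure(census, one_respondent(county = "NOPE")),
    class = "dentiv_lookup_error")
  expect_match(conditionMessage(err), "NOPE")
  # malformed proportions
  bad <- census
  bad$proportion_fluoridated[1] <- 1.7
  expect_error(compute_exposure(bad, one_respondent()),
               class = "dentiv_validation_error")
  # duplicate (county, year)
  expect_error(compute_exposure(rbind(census, census[1, ]),
                                one_respondent()),
               class = "dentiv_validation_error")
  # missing (county, year) rows inside the span warn and count as 0
  sparse <- census[census$year %% 2 == 0, ]
  expect_warning(
    z <- compute_exposure(sparse, one_respondent()),
    class = "dentiv_missing_census_rows")
  expect_lte(z$exposure_z, 0.5)
})
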