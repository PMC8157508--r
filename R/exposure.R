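# Instrument construction: cumulative childhood fluoridation exposure.
#
# The instrument for one respondent is the mean of the county-level
# proportion of the population supplied fluoridated water over the ten
# calendar years in which the respondent was 5-14 years old (the
# post-eruptive enamel-maturation window), so it lies in [0, 1]: 0 means no
# childhood exposure to fluoridated water, 1 means full exposure in all ten
# years.

#' Validate a fluoridation census table
#'
#' A fluoridation census records, for each county and calendar year, the
#' proportion of the county population supplied with fluoridated drinking
#' water. At most one row per (county, year) is allowed and proportions
#' must lie in \[0, 1\].
#'
#' @param census A data.frame with columns `county_id`, `year`,
#'   `proportion_fluoridated`.
#' @return The census, invisibly, with `year` coerced to integer.
#' @export
validate_census <- function(census) {
  required <- c("county_id", "year", "proportion_fluoridated")
  missing_cols <- setdiff(required, names(census))
  if (length(missing_cols)) {
    stop_validation(
      sprintf("census is missing column(s): %s",
              paste(missing_cols, collapse = ", ")),
      columns = missing_cols
    )
  }
  p <- census$proportion_fluoridated
  if (!is.numeric(p) || anyNA(p) || any(p < 0 | p > 1)) {
    stop_validation("census proportions must be numeric in [0, 1]")
  }
  if (!is.numeric(census$year) || any(census$year != round(census$year))) {
    stop_validation("census years must be integers")
  }
  if (anyDuplicated(census[c("county_id", "year")])) {
    stop_validation("census has more than one row for some (county, year)")
  }
  census$year <- as.integer(census$year)
  invisible(census)
}

#' Compute childhood fluoride-exposure instrument
#'
#' For each respondent, accumulates the county proportion of people supplied
#' fluoridated water over the ten calendar years `birth_year + 5` through
#' `birth_year + 14` and divides by 10, giving an exposure score in
#' \[0, 1\]. Years before the first census year contribute 0 (the
#' pre-fluoridation baseline); years after the last census year contribute
#' the county's final observed value. Census rows absent for a (county,
#' year) inside the observed span are treated as proportion 0, with a
#' warning.
#'
#' @param census A fluoridation census data.frame (see [validate_census()]).
#' @param respondents A data.frame with columns `respondent_id`,
#'   `birth_year`, `county_id`.
#' @param age_window Inclusive age range accumulated; default `c(5, 14)`.
#' @return A data.frame with columns `respondent_id`, `exposure_z`.
#' @export
#' @examples
#' census <- data.frame(
#'   county_id = "A", year = 1945:1992,
#'   proportion_fluoridated = rep(c(0, 1), c(10, 38))
#' )
#' resp <- data.frame(respondent_id = 1, birth_year = 1945, county_id = "A")
#' compute_exposure(census, resp)  # ages 5-14 span 1950-1959, so z = 0.5
compute_exposure <- function(census, respondents, age_window = c(5L, 14L)) {
  census <- validate_census(census)
  req <- c("respondent_id", "birth_year", "county_id")
  missing_cols <- setdiff(req, names(respondents))
  if (length(missing_cols)) {
    stop_validation(
      sprintf("respondents table is missing column(s): %s",
              paste(missing_cols, collapse = ", ")))
  }
  age_window <- check_year_pair(age_window, "age_window")

  counties <- unique(census$county_id)
  unknown <- setdiff(unique(respondents$county_id), counties)
  if (length(unknown)) {
    stop_lookup(
      sprintf("respondent county/counties not in census: %s",
              paste(sort(unknown), collapse = ", ")),
      counties = unknown
    )
  }

  yr_min <- min(census$year)
  yr_max <- max(census$year)
  years <- yr_min:yr_max
  # county x year lookup; unobserved (county, year) cells inside the span = 0
  ci <- match(census$county_id, counties)
  yi <- match(census$year, years)
  lookup <- matrix(0, nrow = length(counties), ncol = length(years),
                   dimnames = list(counties, years))
  lookup[cbind(ci, yi)] <- census$proportion_fluoridated
  n_cells <- length(counties) * length(years)
  if (nrow(census) < n_cells) {
    dentiv_warn(
      "dentiv_missing_census_rows",
      sprintf(
        "%d (county, year) cell(s) missing from census span %d-%d; treated as proportion 0",
        n_cells - nrow(census), yr_min, yr_max))
  }

  rci <- match(respondents$county_id, counties)
  ages <- seq.int(age_window[1], age_window[2])
  z <- numeric(nrow(respondents))
  for (a in ages) {
    yr <- respondents$birth_year + a
    # boundary rule: 0 before the census span, last observed value after it
    yidx <- pmin(pmax(yr, yr_min), yr_max) - yr_min + 1L
    val <- lookup[cbind(rci, yidx)]
    val[yr < yr_min] <- 0
    z <- z + val
  }
  data.frame(
    respondent_id = respondents$respondent_id,
    exposure_z = z / length(ages)
  )
}
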