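# Independent brute-force oracles (dense normal equations / FWL residual
# ratio) and small fixture builders shared across the test files. The
# oracles deliberately avoid the package's QR path.

# least-squares coefficients via explicit normal equations
ols_oracle <- function(y, W) {
  drop(solve(crossprod(W), crossprod(W, y)))
}

# residualise v on X by explicit projection
resid_oracle <- function(v, X) {
  v - X %*% solve(crossprod(X), crossprod(X, v))
}

# just-identified 2SLS treatment coefficient as the
# Frisch-Waugh-Lovell residual ratio cov(z~, y~) / cov(z~, t~)
fwl_2sls_oracle <- function(y, t, z, X) {
  ry <- resid_oracle(y, X)
  rt <- resid_oracle(t, X)
  rz <- resid_oracle(z, X)
  sum(rz * ry) / sum(rz * rt)
}

# a randomised frame with covariate factors and a usable instrument
random_frame <- function(n = 400, seed = 1, binary_y = FALSE) {
  set.seed(seed)
  g <- factor(sample(c("female", "male"), n, replace = TRUE))
  s <- factor(sample(paste0("S", 1:4), n, replace = TRUE))
  w <- factor(sample(c(2006, 2008, 2010), n, replace = TRUE))
  X <- stats::model.matrix(~ g + s + w)
  z <- stats::runif(n)
  t <- 2 - 4 * z + rnorm(n) + 0.5 * (g == "male")
  y <- 1 + 0.8 * t + rnorm(n) + 0.3 * (s == "S2")
  if (binary_y) y <- as.numeric(y > stats::median(y))
  analysis_frame(y, t, z, X,
                 outcome_scale = if (binary_y) "probability" else "score")
}

# census with one county held at the given per-age proportions for a
# respondent born in `birth_year` (ages 5-14), zero elsewhere
census_for_ages <- function(props, birth_year = 1950,
                            span = c(1945, 1992), county = "A") {
  years <- span[1]:span[2]
  p <- numeric(length(years))
  p[match(birth_year + 5:14, years)] <- props
  data.frame(county_id = county, year = years, proportion_fluoridated = p)
}

one_respondent <- function(birth_year = 1950, county = "A") {
  data.frame(respondent_id = "r1", birth_year = birth_year,
             county_id = county)
}

# minimal valid survey table built from explicit columns
make_survey <- function(n, birth_year = 1950, bracket = "one_to_five",
                        days = 0, county = "C001", state = "S01",
                        wave = 2006, gender = "female") {
  phq <- matrix(days, n, 8, dimnames = list(NULL, paste0("phq", 1:8)))
  cbind(
    data.frame(respondent_id = sprintf("r%d", seq_len(n)),
               birth_year = birth_year, wave = wave, gender = gender,
               state = state, county_id = county, teeth_bracket = bracket,
               stringsAsFactors = FALSE),
    as.data.frame(phq))
}
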