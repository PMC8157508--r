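# The from-scratch estimation core, checked against exact algebraic cases,
# brute-force normal-equations / FWL oracles, and (as an independent
# implementation) lm() + sandwich covariances.

test_that("OLS reproduces exact linear relations", {
  n <- 60
  set.seed(1)
  X <- cbind(`(Intercept)` = 1, x = rnorm(n))
  t <- rnorm(n)
  fr <- analysis_frame(y = 2 * t, t = t, z = runif(n), X = X)
  fit <- fit_ols(fr, se_type = "classical")
  expect_equal(fit$estimate, 2, tolerance = 1e-12)
  expect_lt(fit$se, 1e-8)
  # constant outcome -> zero coefficient
  fr0 <- analysis_frame(y = rep(3, n), t = t, z = runif(n), X = X)
  expect_equal(fit_ols(fr0)$estimate, 0, tolerance = 1e-12)
})

test_that("OLS matches the hand-size normal-equations oracle", {
  y <- c(1, 3, 2, 5, 4, 6)
  t <- c(0, 1, 1, 2, 2, 3)
  x <- c(1, 0, 1, 0, 1, 0)
  X <- cbind(`(Intercept)` = 1, x = x)
  fr <- analysis_frame(y, t, z = runif(6), X = X)
  oracle <- ols_oracle(y, cbind(t, X))
  expect_equal(fit_ols(fr)$estimate, unname(oracle[1]), tolerance = 1e-12)
})

test_that("OLS agrees with lm() and sandwich HC1 covariance", {
  skip_if_not_installed("sandwich")
  fr <- random_frame(n = 300, seed = 5)
  fit_c <- fit_ols(fr, "classical")
  fit_r <- fit_ols(fr, "HC1")
  lmfit <- lm(fr$y ~ fr$t + fr$X - 1)
  expect_equal(fit_c$estimate, unname(coef(lmfit)[1]), tolerance = 1e-10)
  expect_equal(fit_c$se, sqrt(vcov(lmfit)[1, 1]), tolerance = 1e-10)
  expect_equal(fit_r$se,
               sqrt(sandwich::vcovHC(lmfit, type = "HC1")[1, 1]),
               tolerance = 1e-10)
})

test_that("first stage recovers exact relations and F = t^2", {
  n <- 200
  set.seed(2)
  X <- cbind(`(Intercept)` = 1, x = rnorm(n))
  z <- runif(n)
  t <- -0.5 * z + X %*% c(1, 0.3)
  fr <- analysis_frame(y = rnorm(n), t = drop(t), z = z, X = X)
  fs <- fit_first_stage(fr, "classical")
  expect_equal(fs$estimate, -0.5, tolerance = 1e-10)
  # noisy case: F is exactly the squared t ratio under either SE type
  fr2 <- random_frame(n = 250, seed = 9)
  for (se in c("classical", "HC1")) {
    fs2 <- fit_first_stage(fr2, se)
    expect_equal(fs2$f_statistic, (fs2$estimate / fs2$se)^2,
                 tolerance = 1e-12)
  }
  # degenerate instrument
  frz <- analysis_frame(y = rnorm(n), t = rnorm(n), z = rep(0.5, n), X = X)
  expect_error(fit_first_stage(frz),
               class = "dentiv_degenerate_instrument_error")
})

test_that("reduced form: null case and exact composition", {
  n <- 4000
  set.seed(3)
  X <- matrix(1, n, 1, dimnames = list(NULL, "(Intercept)"))
  z <- runif(n)
  # y independent of z -> coefficient indistinguishable from 0
  fr <- analysis_frame(y = rnorm(n), t = rnorm(n), z = z, X = X)
  rf <- fit_reduced_form(fr)
  expect_lt(abs(rf$estimate), 3 * rf$se)
  # noiseless chain t = pi z, y = beta t -> rho = beta * pi exactly
  t <- -0.5 * z
  fr2 <- analysis_frame(y = 2 * t, t = t, z = z, X = X)
  expect_equal(fit_reduced_form(fr2)$estimate, -1, tolerance = 1e-10)
})

test_that("2SLS equals the FWL residual-ratio oracle and the Wald identity", {
  for (seed in 1:5) {
    fr <- random_frame(n = 350, seed = seed)
    fit <- fit_2sls(fr)
    oracle <- fwl_2sls_oracle(fr$y, fr$t, fr$z, fr$X)
    expect_equal(fit$beta_2sls$estimate, oracle, tolerance = 1e-8)
    expect_equal(fit$beta_2sls$estimate * fit$pi_first_stage$estimate,
                 fit$rho_reduced_form$estimate, tolerance = 1e-10)
  }
  # instrument equals treatment, outcome = 2 * treatment
  n <- 100
  set.seed(4)
  z <- runif(n)
  X <- matrix(1, n, 1, dimnames = list(NULL, "(Intercept)"))
  fr <- analysis_frame(y = 2 * z, t = z, z = z, X = X)
  expect_equal(fit_2sls(fr)$beta_2sls$estimate, 2, tolerance = 1e-10)
})

test_that("2SLS covariance uses structural residuals", {
  # against the textbook sandwich computed densely from first principles
  fr <- random_frame(n = 400, seed = 13)
  fit <- fit_2sls(fr, "HC1")
  W <- cbind(fr$t, fr$X)
  Zm <- cbind(fr$z, fr$X)
  P <- Zm %*% solve(crossprod(Zm), t(Zm))
  Wh <- P %*% W
  bread <- solve(crossprod(Wh, W))
  b <- bread %*% crossprod(Wh, fr$y)
  e <- drop(fr$y - W %*% b)
  n <- length(e); k <- ncol(W)
  meat <- crossprod(Wh * e)
  V <- bread %*% meat %*% t(bread) * n / (n - k)
  expect_equal(fit$beta_2sls$estimate, unname(drop(b)[1]), tolerance = 1e-8)
  expect_equal(fit$beta_2sls$se, sqrt(V[1, 1]), tolerance = 1e-8)
})

test_that("weak and absent instruments are refused or flagged", {
  n <- 500
  set.seed(6)
  X <- matrix(1, n, 1, dimnames = list(NULL, "(Intercept)"))
  z <- runif(n)
  t <- rnorm(n)                      # no first stage at all
  fr <- analysis_frame(y = rnorm(n), t = t, z = z, X = X)
  fs <- fit_first_stage(fr)
  if (fs$f_statistic < 1) {
    err <- expect_error(fit_2sls(fr), class = "dentiv_weak_instrument_error")
    expect_true(is.numeric(err$f_statistic))
  } else {
    expect_warning(fit_2sls(fr), class = "dentiv_weak_instrument_warning")
  }
  # moderately weak first stage triggers the warning path
  t2 <- 0.08 * z + rnorm(n)
  fr2 <- analysis_frame(y = rnorm(n), t = t2, z = z, X = X)
  f2 <- fit_first_stage(fr2)$f_statistic
  if (f2 >= 1 && f2 < 10) {
    fit <- expect_warning(fit_2sls(fr2),
                          class = "dentiv_weak_instrument_warning")
    expect_true(fit$weak_instrument)
  }
})

test_that("rank deficiency is reported with the collinear column", {
  n <- 50
  set.seed(8)
  x <- rnorm(n)
  X <- cbind(`(Intercept)` = 1, a = x, b = 2 * x)
  fr <- analysis_frame(y = rnorm(n), t = rnorm(n), z = runif(n), X = X)
  err <- expect_error(fit_ols(fr), class = "dentiv_singularity_error")
  expect_match(conditionMessage(err), "collinear column\\(s\\): (a|b)")
})

test_that("linear-probability IV reports percentage points", {
  n <- 80
  set.seed(10)
  t <- rbinom(n, 1, 0.5)
  z <- t  # instrument equals the binary treatment
  fr <- analysis_frame(y = as.numeric(t), t = as.numeric(t), z = z,
                       outcome_scale = "probability")
  fit <- linear_probability_iv(fr)
  row <- iv_fit_row(fit, "perfect prediction")
  expect_equal(row$second_stage, 100, tolerance = 1e-8)
  expect_equal(row$outcome_scale, "percentage points")
  # unit conversion: a coefficient of 0.0081 prints as 0.81 pp
  expect_equal(dentiv:::scaled_triplet(
    list(estimate = 0.0081, se = 0.001, ci = c(lower = 0, upper = 0.01)),
    100)[["estimate"]], 0.81)
  # non-binary outcome refused
  fr_bad <- analysis_frame(y = rnorm(n), t = as.numeric(t), z = z)
  expect_error(linear_probability_iv(fr_bad),
               class = "dentiv_validation_error")
})

test_that("cluster-robust covariance matches the dense CR1 formula", {
  fr <- random_frame(n = 300, seed = 21)
  cl <- sample(paste0("c", 1:12), fr$n, replace = TRUE)
  fr$cluster <- cl
  fit <- fit_ols(fr, "cluster")
  W <- cbind(fr$t, fr$X)
  b <- ols_oracle(fr$y, W)
  e <- drop(fr$y - W %*% b)
  G <- rowsum(W * e, cl)
  ng <- nrow(G); n <- fr$n; k <- ncol(W)
  V <- solve(crossprod(W)) %*% crossprod(G) %*% solve(crossprod(W)) *
    ng / (ng - 1) * (n - 1) / (n - k)
  expect_equal(fit$se, sqrt(V[1, 1]), tolerance = 1e-10)
})

test_that("a stronger first stage tightens the 2SLS standard error", {
  ses <- sapply(c(-9, -18), function(pi) {
    reps <- sapply(1:20, function(i) {
      cfg <- generator_config(n_respondents = 2000, n_counties = 60,
                              first_stage_pi = pi, seed = 3000 + i)
      st <- simulate_study(cfg)
      prep <- prepare_study_data(st$respondents, st$census)
      fr <- build_frame(prep$data, "total", "continuous")
      fit <- suppressWarnings(fit_2sls(fr))
      fit$beta_2sls$se
    })
    median(reps)
  })
  expect_lt(ses[2], ses[1])
})
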