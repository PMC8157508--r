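# Truth record: the generating parameters persisted alongside each
# synthetic dataset, including the analytically expected OLS slope of the
# scored outcome on the mid-point-coded treatment. The estimation modules
# never read this record (one-way firewall); it exists for recovery tests.
#
# Derivation sketch. Latent tooth loss is L = s_i + h + gT*U + eT with h
# uniform on (h_lo, h_hi) and V = gT*U + eT normal, so the CDF of L has
# the closed form  F(c) = (sV / W) * [Psi(u_hi) - Psi(u_lo)]  with
# Psi(z) = z*Phi(z) + phi(z), which yields exact probabilities for every
# value of T* = clamp(round(L), 0, 28). A Stein identity gives
# E[U * g(T*)] = gT * sum over discontinuities of g of (jump x density),
# which covers the confounder-treatment covariance. The scored PHQ total
# satisfies E[S | D] = clamp(D, 0, 24), whose expectation over the normal
# depression noise is the censored-normal mean Lambda(m, sd). The expected
# OLS slope is then cov(S~, Tc~) / var(Tc~) with the conditional moments
# above and the empirical covariate design partialled out; its deviation
# from beta is the omitted-variable bias gamma_Y * cov(Tc~, U) / var(Tc~)
# plus (exactly computed, numerically tiny) scoring-censoring terms.

BRACKET_CUTS <- c(0.5, 5.5, 27.5)
BRACKET_JUMPS <- c(3, 13.5, 11.5)  # jumps of the mid-point code at the cuts

psi_int_phi <- function(z) z * stats::pnorm(z) + stats::dnorm(z)

# censored-normal mean: E[clamp(N(m, sd^2), lo, hi)]
censored_normal_mean <- function(m, sd, lo = 0, hi = 24) {
  zlo <- (lo - m) / sd
  zhi <- (hi - m) / sd
  m * (stats::pnorm(zhi) - stats::pnorm(zlo)) +
    sd * (stats::dnorm(zlo) - stats::dnorm(zhi)) +
    lo * stats::pnorm(zlo) + hi * (1 - stats::pnorm(zhi))
}

# Conditional moments of (Tc, T*, S) given each respondent's systematic
# parts. shift_T excludes h, U and eT; offset_Y excludes beta*T*, U and eY.
latent_tooth_moments <- function(config, shift_T, offset_Y, beta_vec) {
  h_lo <- config$susceptibility_range[1]
  h_hi <- config$susceptibility_range[2]
  W <- h_hi - h_lo
  sV <- sqrt(config$confounder_gamma_T^2 + config$noise_sd_T^2)
  gT <- config$confounder_gamma_T
  sD <- sqrt(config$confounder_gamma_Y^2 + config$noise_sd_latentY^2)

  cuts <- seq(0.5, 27.5, by = 1)              # T* = t  <=>  L in (t-.5, t+.5]
  n <- length(shift_T)
  Uhi <- outer(-shift_T, cuts, `+`)           # cut - shift
  Zhi <- (Uhi - h_lo) / sV
  Zlo <- (Uhi - h_hi) / sV
  Fc <- (sV / W) * (psi_int_phi(Zhi) - psi_int_phi(Zlo))  # n x 28 CDF at cuts
  p <- cbind(Fc[, 1], Fc[, -1, drop = FALSE] - Fc[, -28, drop = FALSE],
             1 - Fc[, 28])                     # n x 29, P(T* = 0..28)
  p[p < 0] <- 0                                # guard tiny negative roundoff

  tvals <- 0:28
  mcode <- code_continuous(
    as.character(cut(tvals, c(-0.5, 0.5, 5.5, 27.5, 28.5),
                     labels = tooth_brackets())))

  e_tc  <- drop(p %*% mcode)
  e_tc2 <- drop(p %*% mcode^2)
  e_ts  <- drop(p %*% tvals)
  e_tcts <- drop(p %*% (mcode * tvals))

  # densities of L at the three bracket cuts -> Stein terms for U
  dens <- sapply(BRACKET_CUTS, function(cc) {
    zhi <- (cc - shift_T - h_lo) / sV
    zlo <- (cc - shift_T - h_hi) / sV
    (stats::pnorm(zhi) - stats::pnorm(zlo)) / W
  })
  e_u_tc <- gT * drop(dens %*% BRACKET_JUMPS)

  # scoring-censoring correction: eps(m) = E[clamp(N(m, sD^2),0,24)] - m
  M <- outer(offset_Y, rep(1, 29)) + outer(beta_vec, tvals)
  eps <- censored_normal_mean(M, sD) - M
  e_eps <- rowSums(p * eps)
  e_eps_tc <- rowSums(p * eps * rep(mcode, each = n))

  e_s <- offset_Y + beta_vec * e_ts + e_eps
  e_s_tc <- offset_Y * e_tc + beta_vec * e_tcts +
    config$confounder_gamma_Y * e_u_tc + e_eps_tc

  list(e_tc = e_tc, var_tc = e_tc2 - e_tc^2, e_ts = e_ts,
       e_s = e_s, cov_s_tc = e_s_tc - e_s * e_tc,
       e_u_tc = e_u_tc,
       dcode_dmu = sum(BRACKET_JUMPS) / W)
}

#' Truth record for a synthetic dataset
#'
#' Computes the record persisted alongside generated data: the true causal
#' effect, the latent and coded first-stage strengths, and the analytically
#' expected OLS slope/bias of the scored PHQ total on the mid-point-coded
#' treatment given the realised covariate design (exact closed forms; see
#' the source header). Estimation functions never consume this object.
#'
#' @param config A [generator_config()].
#' @param z Respondent exposure values.
#' @param male 0/1 male indicators.
#' @param shift_T Tooth-equation systematic part (instrument + covariates).
#' @param offset_Y Depression-equation systematic part (intercept +
#'   covariates, excluding the treatment and confounder).
#' @param design data.frame of covariates (`birth_year`, `wave`, `gender`,
#'   `state`) used to partial the design out, as the estimator does.
#' @return An object of class `truth_record`.
#' @export
truth_record <- function(config, z, male, shift_T, offset_Y, design) {
  beta_vec <- config$true_beta + config$beta_male_shift * male
  mom <- latent_tooth_moments(config, shift_T, offset_Y, beta_vec)

  X <- covariate_design(design)
  qd <- qr(X)
  r_tc <- qr.resid(qd, mom$e_tc)
  r_s  <- qr.resid(qd, mom$e_s)
  r_z  <- qr.resid(qd, z)

  n <- length(z)
  var_tc_tilde <- mean(mom$var_tc) + sum(r_tc^2) / n
  cov_s_tc_tilde <- mean(mom$cov_s_tc) + sum(r_s * r_tc) / n
  ols_slope <- cov_s_tc_tilde / var_tc_tilde

  cov_tc_z <- sum(r_tc * r_z) / n   # within-i covariances with z vanish
  cov_s_z  <- sum(r_s * r_z) / n
  iv_slope <- if (abs(cov_tc_z) > .Machine$double.eps) cov_s_z / cov_tc_z else NA_real_

  structure(list(
    true_beta = config$true_beta,
    first_stage_pi = config$first_stage_pi,
    first_stage_pi_coded = config$first_stage_pi * mom$dcode_dmu,
    ols_slope_expected = ols_slope,
    ols_bias_expected = ols_slope - config$true_beta,
    iv_slope_expected = iv_slope,
    confounder_gamma_T = config$confounder_gamma_T,
    confounder_gamma_Y = config$confounder_gamma_Y,
    seed = config$seed
  ), class = "truth_record")
}

#' @export
print.truth_record <- function(x, ...) {
  cat("Synthetic-data truth record (never read by the estimator):\n")
  cat(sprintf("  true beta              %.4f PHQ pts/tooth\n", x$true_beta))
  cat(sprintf("  first stage (latent)   %.3f teeth per unit instrument\n",
              x$first_stage_pi))
  cat(sprintf("  first stage (coded)    %.3f\n", x$first_stage_pi_coded))
  cat(sprintf("  expected OLS slope     %.4f  (bias %+.4f)\n",
              x$ols_slope_expected, x$ols_bias_expected))
  invisible(x)
}
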