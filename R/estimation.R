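# From-scratch linear estimation core for the just-identified IV design:
# OLS, first stage, reduced form and 2SLS, with classical /
# heteroskedasticity-robust (HC1) / cluster-robust covariance, the
# single-instrument first-stage F, and the Wald identity
# beta_2sls = rho_reduced_form / pi_first_stage.
#
# 2SLS covariance uses STRUCTURAL residuals y - T*beta - X*gamma (the
# observed treatment, not its first-stage fitted values), the standard
# correction to the naive two-step variance.

Z_CRIT <- 1.959964  # 95% normal critical value

#' Assemble an analysis frame
#'
#' The frame is the estimation-ready table: outcome `y`, treatment `t`,
#' instrument `z` and the covariate design `X` (intercept plus
#' indicator/contrast columns). All vectors must be complete (the pipeline
#' applies complete-case exclusion upstream).
#'
#' @param y Numeric outcome (PHQ-8 total, 0/1 caseness, or one item score).
#' @param t Numeric treatment (coded number of lost teeth, or 0/1).
#' @param z Numeric instrument in \[0, 1\].
#' @param X Numeric covariate matrix including an intercept column; if
#'   `NULL`, an intercept-only design is used.
#' @param outcome_scale `"score"` or `"probability"`; probability-scale
#'   fits are reported in percentage points by [linear_probability_iv()].
#' @param cluster Optional cluster id vector (county or state) for
#'   cluster-robust covariance.
#' @return An object of class `analysis_frame`.
#' @export
analysis_frame <- function(y, t, z, X = NULL,
                           outcome_scale = c("score", "probability"),
                           cluster = NULL) {
  outcome_scale <- match.arg(outcome_scale)
  n <- length(y)
  if (is.null(X)) X <- matrix(1, n, 1L, dimnames = list(NULL, "(Intercept)"))
  X <- as.matrix(X)
  if (length(t) != n || length(z) != n || nrow(X) != n) {
    stop_validation("y, t, z and X must have the same number of rows")
  }
  if (anyNA(y) || anyNA(t) || anyNA(z) || anyNA(X)) {
    stop_validation("analysis frame must be complete-case (no missing cells)")
  }
  if (any(z < -1e-8 | z > 1 + 1e-8)) {
    stop_validation("instrument z must lie in [0, 1]")
  }
  if (!is.null(cluster) && length(cluster) != n) {
    stop_validation("`cluster` must have one id per row")
  }
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  structure(list(y = as.numeric(y), t = as.numeric(t), z = as.numeric(z),
                 X = X, n = n, outcome_scale = outcome_scale,
                 cluster = cluster),
            class = "analysis_frame")
}

#' @export
print.analysis_frame <- function(x, ...) {
  cat(sprintf(
    "Analysis frame: n = %d, %d covariate column(s), outcome scale '%s'\n",
    x$n, ncol(x$X), x$outcome_scale))
  invisible(x)
}

# Solve least squares via QR; error (naming columns) on rank deficiency.
qr_ls <- function(y, W) {
  qd <- qr(W)
  p <- ncol(W)
  if (qd$rank < p) {
    bad <- colnames(W)[qd$pivot[seq.int(qd$rank + 1L, p)]]
    dentiv_stop("dentiv_singularity_error",
                sprintf("design matrix is rank deficient; collinear column(s): %s",
                        paste(bad, collapse = ", ")),
                columns = bad)
  }
  coef <- qr.coef(qd, y)
  fitted <- drop(W %*% coef)
  list(coef = coef, fitted = fitted, residuals = y - fitted, qr = qd)
}

# Covariance of least-squares coefficients given residuals e.
# se_type: "classical" s^2 (W'W)^-1; "HC1" sandwich with n/(n-k) scaling;
# "cluster" CR1 with G/(G-1) * (n-1)/(n-k) scaling.
ls_vcov <- function(W, e, qd, se_type, cluster = NULL) {
  n <- nrow(W)
  k <- ncol(W)
  # (W'W)^-1 from the R factor (undo column pivoting)
  piv <- qd$pivot
  xtx_inv_piv <- chol2inv(qr.R(qd))
  xtx_inv <- matrix(0, k, k, dimnames = list(colnames(W), colnames(W)))
  xtx_inv[piv, piv] <- xtx_inv_piv
  if (se_type == "classical") {
    s2 <- sum(e^2) / (n - k)
    return(s2 * xtx_inv)
  }
  if (se_type == "HC1") {
    meat <- crossprod(W * e)
    return(xtx_inv %*% meat %*% xtx_inv * n / (n - k))
  }
  if (se_type == "cluster") {
    if (is.null(cluster)) {
      stop_config("cluster-robust covariance requested but the frame has no cluster ids")
    }
    We <- W * e
    G <- rowsum(We, group = cluster)
    ng <- nrow(G)
    meat <- crossprod(G)
    adj <- ng / (ng - 1) * (n - 1) / (n - k)
    return(xtx_inv %*% meat %*% xtx_inv * adj)
  }
  stop_config(sprintf("unknown se_type '%s'", se_type))
}

fit_linear <- function(y, W, focal, se_type, cluster = NULL,
                       resid_override = NULL) {
  ls <- qr_ls(y, W)
  e <- if (is.null(resid_override)) ls$residuals else resid_override
  V <- ls_vcov(W, e, ls$qr, se_type, cluster)
  est <- unname(ls$coef[focal])
  se <- sqrt(V[focal, focal])
  structure(list(
    estimate = est, se = se,
    ci = c(lower = est - Z_CRIT * se, upper = est + Z_CRIT * se),
    coefficients = ls$coef, vcov = V,
    residuals = ls$residuals, fitted = ls$fitted,
    focal = focal, se_type = se_type, n = length(y), df = length(y) - ncol(W)
  ), class = "dentiv_fit")
}

#' @export
print.dentiv_fit <- function(x, ...) {
  cat(sprintf("%s: %.4f (SE %.4f, 95%% CI %.4f to %.4f), n = %d, %s SEs\n",
              x$focal, x$estimate, x$se, x$ci[1], x$ci[2], x$n, x$se_type))
  invisible(x)
}

#' Ordinary least squares of the outcome on the treatment
#'
#' Regresses `y` on the treatment and covariates; the treatment coefficient
#' is the (confounded, under unobserved common causes) associational
#' estimate that the IV design is compared against.
#'
#' @param frame An [analysis_frame()].
#' @param se_type `"HC1"` (default), `"classical"` or `"cluster"`.
#' @return A `dentiv_fit` for the treatment coefficient.
#' @export
fit_ols <- function(frame, se_type = c("HC1", "classical", "cluster")) {
  se_type <- match.arg(se_type)
  W <- cbind(treatment = frame$t, frame$X)
  fit_linear(frame$y, W, "treatment", se_type, frame$cluster)
}

#' First-stage regression of treatment on the instrument
#'
#' Regresses the coded number of lost teeth on the fluoride-exposure
#' instrument and covariates. The single-excluded-instrument F statistic is
#' the squared t ratio of the instrument coefficient under the chosen
#' covariance estimator.
#'
#' @inheritParams fit_ols
#' @return A `dentiv_fit` with an extra `f_statistic` element.
#' @export
fit_first_stage <- function(frame, se_type = c("HC1", "classical", "cluster")) {
  se_type <- match.arg(se_type)
  if (stats::var(frame$z) <= 0) {
    dentiv_stop("dentiv_degenerate_instrument_error",
                "instrument has zero variance; first stage is undefined")
  }
  W <- cbind(instrument = frame$z, frame$X)
  fit <- fit_linear(frame$t, W, "instrument", se_type, frame$cluster)
  fit$f_statistic <- (fit$estimate / fit$se)^2
  fit
}

#' Reduced-form regression of the outcome on the instrument
#'
#' @inheritParams fit_ols
#' @return A `dentiv_fit` for the instrument coefficient.
#' @export
fit_reduced_form <- function(frame, se_type = c("HC1", "classical", "cluster")) {
  se_type <- match.arg(se_type)
  W <- cbind(instrument = frame$z, frame$X)
  fit_linear(frame$y, W, "instrument", se_type, frame$cluster)
}

#' Two-stage least squares (just-identified)
#'
#' Stage one regresses the treatment on the instrument and covariates;
#' stage two regresses the outcome on the first-stage fitted treatment and
#' the same covariates. Coefficient covariance is computed from structural
#' residuals (using the observed treatment). Refuses to report an estimate
#' when the first-stage F is below `f_refuse` (the instrument carries
#' essentially no information); warns when F is below `f_warn`, the
#' conventional weak-instrument bar.
#'
#' @inheritParams fit_ols
#' @param f_refuse Refusal threshold on the first-stage F; default 1.
#' @param f_warn Warning threshold on the first-stage F; default 10.
#' @return An object of class `iv_fit` bundling the second-stage, first-
#'   stage, reduced-form and OLS fits, the first-stage F and sample size.
#' @export
fit_2sls <- function(frame, se_type = c("HC1", "classical", "cluster"),
                     f_refuse = 1, f_warn = 10) {
  se_type <- match.arg(se_type)
  first <- fit_first_stage(frame, se_type)
  f <- first$f_statistic
  if (f < f_refuse) {
    dentiv_stop("dentiv_weak_instrument_error",
                sprintf(
                  "first-stage F = %.3f is below the refusal threshold %g; the instrument is too weak to report a 2SLS estimate",
                  f, f_refuse),
                f_statistic = f)
  }
  if (f < f_warn) {
    dentiv_warn("dentiv_weak_instrument_warning",
                sprintf("first-stage F = %.2f is below %g; the 2SLS estimate may be unreliable (weak instrument)",
                        f, f_warn))
  }
  reduced <- fit_reduced_form(frame, se_type)
  ols <- fit_ols(frame, se_type)

  W2 <- cbind(treatment = first$fitted, frame$X)
  ls2 <- qr_ls(frame$y, W2)
  structural_resid <- frame$y - drop(cbind(frame$t, frame$X) %*% ls2$coef)
  second <- fit_linear(frame$y, W2, "treatment", se_type, frame$cluster,
                       resid_override = structural_resid)
  second$residuals <- structural_resid

  structure(list(
    beta_2sls = second,
    pi_first_stage = first,
    rho_reduced_form = reduced,
    beta_ols = ols,
    f_first_stage = f,
    weak_instrument = f < f_warn,
    n = frame$n,
    se_type = se_type,
    outcome_scale = frame$outcome_scale,
    scale = 1
  ), class = "iv_fit")
}

#' Linear-probability IV for a binary outcome
#'
#' The same 2SLS estimator applied to a 0/1 outcome, with coefficient, SE
#' and CI reported in percentage points (x 100).
#'
#' @inheritParams fit_2sls
#' @return An `iv_fit` with `scale = 100`.
#' @export
linear_probability_iv <- function(frame,
                                  se_type = c("HC1", "classical", "cluster"),
                                  f_refuse = 1, f_warn = 10) {
  se_type <- match.arg(se_type)
  if (!all(frame$y %in% c(0, 1))) {
    stop_validation("linear-probability IV requires a 0/1 outcome")
  }
  fit <- fit_2sls(frame, se_type, f_refuse = f_refuse, f_warn = f_warn)
  fit$scale <- 100
  fit
}

scaled_triplet <- function(fit, scale) {
  c(estimate = fit$estimate * scale, se = fit$se * scale,
    lower = unname(fit$ci[1]) * scale, upper = unname(fit$ci[2]) * scale)
}

#' Tidy one-row summary of an `iv_fit`
#'
#' @param fit An `iv_fit`.
#' @param label Row label.
#' @return A one-row data.frame mirroring the study's result-table layout:
#'   first stage (estimate, CI, F), second stage, OLS, n.
#' @export
iv_fit_row <- function(fit, label = "") {
  s <- fit$scale
  fs <- scaled_triplet(fit$pi_first_stage, 1)     # first stage is on the teeth scale
  rf <- scaled_triplet(fit$rho_reduced_form, s)
  ss <- scaled_triplet(fit$beta_2sls, s)
  ol <- scaled_triplet(fit$beta_ols, s)
  data.frame(
    label = label, n = fit$n,
    first_stage = fs[["estimate"]], first_stage_lower = fs[["lower"]],
    first_stage_upper = fs[["upper"]], first_stage_f = fit$f_first_stage,
    reduced_form = rf[["estimate"]], reduced_form_lower = rf[["lower"]],
    reduced_form_upper = rf[["upper"]],
    second_stage = ss[["estimate"]], second_stage_lower = ss[["lower"]],
    second_stage_upper = ss[["upper"]],
    ols = ol[["estimate"]], ols_lower = ol[["lower"]],
    ols_upper = ol[["upper"]],
    outcome_scale = if (s == 100) "percentage points" else "PHQ-8 points",
    weak_instrument = fit$weak_instrument,
    stringsAsFactors = FALSE
  )
}

#' @export
print.iv_fit <- function(x, digits = 3, ...) {
  s <- x$scale
  unit <- if (s == 100) "pp" else "pts"
  line <- function(nm, f, sc) {
    v <- scaled_triplet(f, sc)
    cat(sprintf("  %-13s %8.*f  (95%% CI %.*f to %.*f)\n", nm,
                digits, v[["estimate"]], digits, v[["lower"]],
                digits, v[["upper"]]))
  }
  cat(sprintf("Two-stage least squares fit (n = %d, %s SEs, outcome in %s)\n",
              x$n, x$se_type, unit))
  line("First stage", x$pi_first_stage, 1)
  cat(sprintf("  %-13s %8.1f%s\n", "F-statistic", x$f_first_stage,
              if (x$weak_instrument) "  [weak instrument]" else ""))
  line("Reduced form", x$rho_reduced_form, s)
  line("Second stage", x$beta_2sls, s)
  line("OLS", x$beta_ols, s)
  invisible(x)
}
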