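---
title: "Methods: instrumenting tooth loss with childhood water fluoridation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: instrumenting tooth loss with childhood water fluoridation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dentiv)
```

## The design

Associations between oral health and depression are hopelessly confounded:
socioeconomic position, health behaviours and early-life environment drive
both, and depression itself degrades oral care. `dentiv` implements the
natural-experiment answer: community water fluoridation was introduced
county by county across the USA from 1945 onward, with the adoption year
and the served share of the population varying widely. Whether a person
spent ages 5–14 — when erupted permanent enamel still matures and benefits
most from fluoride — in a fluoridated county is therefore quasi-random
with respect to their adult mental health, yet shifts how many teeth they
retain decades later. Under the exclusion restriction (childhood water
fluoride affects depression only through dentition), two-stage least
squares (2SLS) on this variation identifies the causal effect of tooth
loss on depressive symptoms; it is a local average treatment effect among
"compliers", people whose tooth retention was changed by fluoridation.

The estimation frame is: outcome $Y$ (PHQ-8 total 0–24, the caseness
indicator $\mathbf 1\{\text{PHQ-8}\ge 10\}$, or a single item score),
treatment $T$ (coded teeth lost), instrument $Z \in [0,1]$, and covariates
$X$: indicators for year of birth, survey wave, gender and state, plus an
intercept. Estimates are reported per lost tooth; caseness results are
scaled to percentage points.

## Instrument construction

For a respondent born in year $b$ living in county $c$,

$$Z = \frac{1}{10}\sum_{a=5}^{14} p(c,\; b+a),$$

where $p(c,y)$ is the proportion of county $c$'s population supplied
fluoridated water in year $y$. The ten calendar years $b+5,\dots,b+14$
make the rescaling exact: $Z=1$ means full exposure throughout ages 5–14.
Boundary rules: years before the first census year contribute 0 (the
pre-fluoridation era), years after the last census year carry the county's
final observed value forward. A (county, year) cell absent from the census
inside its span is treated as proportion 0 with a warning — fluoridation
censuses list served populations, so absence is evidence of no
fluoridation, not missingness. Only the current county of residence is
observed, so childhood relocation is ignored; this misclassification is
plausibly non-systematic (people do not choose counties by fluoridation
status) but attenuates the first stage.

Two properties are enforced by tests: raising any single year's proportion
weakly increases $Z$, and shifting all birth years and census years by a
common constant leaves every exposure unchanged.

## Outcome scoring

PHQ-8 items arrive as day counts (0–14 days out of the past two weeks).
Each is converted to the familiar 0–3 category and summed to the 0–24
total; totals of 10 or more flag probable major depression. The day-count
conversion (0–1 → 0, 2–6 → 1, 7–11 → 2, 12–14 → 3) is the convention of
the surveillance survey that popularised the day-count format; because
survey documentation of this table is not always published alongside the
data, the mapping is a configurable threshold table
(`phq8_day_mapping()`), not a constant. Respondents missing any item are
flagged and excluded (complete-case analysis); no imputation is offered.

## Treatment coding

The survey's tooth-loss question has four brackets. The continuous
treatment assigns each bracket a value — by default the mid-points 0, 3,
16.5 and 28 of a 28-tooth dentition (wisdom teeth excluded, so "6 or more
but not all" spans 6–27). Two dichotomised contrasts are provided: any
loss vs full dentition, and edentulous vs at least one tooth remaining;
the latter is a comparison within people who lost at least one tooth, so
the "none" bracket is excluded from that frame (and the exclusion count
logged) rather than pooled. Sensitivity value sets — e.g. the mean, median
and mode of clinically examined tooth loss from an external validation
study — are user configuration, not package constants: hard-coding them
would invent data. Because the estimator is linear in $T$, recoding the
brackets by an affine transform rescales the 2SLS coefficient by exactly
the inverse slope; the tests exercise this end to end (halving all coded
values doubles the estimate).

## Estimation

The linear-algebra core is written from scratch on the QR decomposition
(this estimator *is* the package's subject; generic regression packages
serve only as independent cross-checks in the tests):

- **OLS** of $Y$ on $(T, X)$ — the confounded comparator.
- **First stage**: $T$ on $(Z, X)$, coefficient $\hat\pi$, and the
  single-excluded-instrument $F = (\hat\pi/\mathrm{SE}(\hat\pi))^2$ under
  the selected covariance estimator.
- **Reduced form**: $Y$ on $(Z, X)$, coefficient $\hat\rho$.
- **2SLS**: $Y$ on $(\hat T, X)$ with $\hat T$ the first-stage fitted
  values. The covariance uses *structural* residuals
  $Y - T\hat\beta - X\hat\gamma$ (observed $T$, not $\hat T$) — the
  standard correction without which two-step standard errors are wrong.

Just-identification gives the Wald identity
$\hat\beta_{2SLS}\,\hat\pi = \hat\rho$, asserted to $10^{-10}$ relative
tolerance on every fit. Over-identified GMM/LIML, nonlinear IV and survey
weights are out of scope.

Choices that the design left open, and how they were fixed:

- **Covariance estimator.** Heteroskedasticity-robust HC1 by default:
  a linear probability model is heteroskedastic by construction, and
  robust errors are the conservative convention for survey outcomes.
  Classical and cluster-robust (county or state, CR1) are options;
  clustering is not the default because the design's exposure already
  varies within county by cohort.
- **Year of birth.** One indicator per year (cohort fixed effects) by
  default, with a linear-trend option; indicators dominate in the
  natural-experiment literature and make no functional-form assumption on
  cohort trends.
- **Confidence intervals.** Normal approximation, $\pm 1.96\,$SE. At the
  sample sizes this design needs, $t$ vs normal is immaterial.
- **Weak instruments.** The fit refuses to report a 2SLS estimate when
  $F < 1$ (the instrument carries essentially no information; the error
  object carries the F value) and warns when $F < 10$, the conventional
  weak-instrument bar. Pipeline tables record the flag per row instead of
  emitting warnings.
- **Reference categories.** The lexicographically first level of each
  factor is dropped — an arbitrary but deterministic tie-break.

A rank-deficient design raises an error naming the collinear columns; a
zero-variance instrument raises a degenerate-instrument error.

## The synthetic population

The generator emulates the study's data structure end to end: a
fluoridation census with staggered adoption (adoption year uniform over
1945–1992, county coverage Beta(5, 2), constant after adoption by default
with a linear-ramp option — the within-county trajectory after adoption is
rarely documented, and constant is the simpler assumption), counties
nested in states, respondents born 1940–1978 surveyed in 2006/2008/2010
(ages 28–70), and the structural model

$$T^* = \mathrm{clamp}\big(\mathrm{round}(h + \pi Z + x'c_T + \gamma_T U + \varepsilon_T),\,0,\,28\big),
\qquad
D = \alpha + \beta T^* + x'c_Y + \gamma_Y U + \varepsilon_Y,$$

with $U \sim N(0,1)$ an unobserved confounder entering both equations,
the reported bracket a deterministic function of $T^*$, and PHQ item
day counts generated from $D$. The truth (β, π, the analytic OLS bias) is
persisted in a JSON sidecar that the estimation code never reads.

### Why the susceptibility distribution is uniform — and wide

The individual susceptibility $h$ is uniform on $(-15, 51)$, a range much
wider than the 0–28 dental arch. This is the generator's load-bearing
design choice. Bracket coding discards within-bracket information, and
midpoint coding is consistent for $\beta$ **only** when the midpoints are
the within-bracket conditional means of $T^*$ — otherwise the 2SLS
probability limit is $\beta \cdot \mathrm{cov}(\tilde T^*,\tilde Z)/
\mathrm{cov}(\tilde T_c,\tilde Z)$, which for a latent distribution
concentrated at low tooth counts is roughly half of $\beta$: a recovery
test against the wired-in effect would be testing the coding bias, not the
estimator. Under a latent distribution that is flat across the whole arch
(including the clamped tails), every bracket's conditional mean is exactly
its midpoint, the coded treatment differs from $T^*$ by mean-zero noise
uncorrelated with any function of the observed data, and midpoint 2SLS is
exactly consistent. The uniform must extend a few noise standard
deviations beyond $[0, 28]$ for every respondent so that local flatness
survives the instrument and covariate shifts; the tests verify the
conditional-mean property empirically.

The price is realism of the marginals: the synthetic population has mean
coded tooth loss around 14 with sizeable "none" and "all" shares, far
more dentally heterogeneous than a real survey population (mean coded
loss near 4.5). The generator is an estimator test bench, not a survey
emulator: passing recovery tests demonstrates that the estimation
machinery is correct under the design's assumptions, not that real
bracket coding is unbiased — indeed the coding-sensitivity analysis
exists precisely because it is not.

### Instrument strength

The default latent first-stage effect is $\pi = -9$ latent teeth per unit
exposure, i.e. about $-3.8$ coded teeth. A realistically small effect
(well under one tooth, as fluoridation studies find) is only identifiable
at population scale ($n \sim 10^5$, where it yields first-stage F in the
tens); at the desk-scale samples the test bench uses ($n$ = 2 000–20 000)
it would leave F near 4 — a weak instrument whose 2SLS estimates are
unusable for recovery and coverage testing. The default therefore scales
the effect so the synthetic study sits in the same *identification regime*
as a well-powered fluoridation design (F ≈ 15 at $n$ = 2 000, ≈ 40 at
5 000, ≈ 230 at 20 000) rather than matching the real-world coefficient.

### Confounding calibration

$\gamma_T = 3.5$ and $\gamma_Y = 4.35$ were set, once, so that the
analytic omitted-variable bias of OLS is $+0.05$ PHQ points per tooth —
a misleading positive bias of one third of the true effect
$\beta = 0.15$, large enough that confounded OLS and consistent 2SLS are
cleanly distinguishable in a few hundred replicates. The expected OLS
slope has a closed form under this generator (`truth.R`): the latent
tooth-count CDF is uniform-convolved-normal
($F(c) = (\sigma_V/W)[\Psi(u_{hi}) - \Psi(u_{lo})]$ with
$\Psi(z) = z\Phi(z) + \phi(z)$), giving exact bracket probabilities; a
Stein identity yields $\mathrm{cov}(T_c, U)$ as $\gamma_T$ times the sum
of code-jumps times latent densities at the bracket cuts; and the
scoring clamp enters through the censored-normal mean. These moments,
partialled against the realised covariate design, give the expected OLS
slope whose deviation from $\beta$ is stored as `ols_bias_expected` in
the truth record — the target the recovery tests compare against.

### PHQ item generation

Item $j$'s 0–3 score is drawn Binomial$(3, \lambda_j\,
\mathrm{clamp}(D,0,24)/3)$ with loadings $\lambda_j \ge 0$,
$\sum_j \lambda_j = 1$ (equal by default), then a day count is drawn
uniformly inside that score's day band, so the scoring module sees
realistic integer day counts. This construction makes
$E[\text{scored total}\mid D] = \mathrm{clamp}(D, 0, 24)$ *exactly*: the
configured $\beta$ lives on the scored-outcome scale, which a smooth
sigmoidal item link would not give without distorting every recovered
coefficient by its slope. The baseline $\alpha = 10$ centres $D$
mid-scale so the clamp is rarely active. Non-uniform loadings concentrate
the depression signal on chosen items — the hook used to test that
item-level analyses light up only the affected items.

### What the generator does not emulate

BRFSS sampling weights and nonresponse, real county geography and
populations, childhood relocation, within-county heterogeneity of water
systems, and realistic marginal distributions of tooth loss and PHQ
scores (see above). Passing tests say nothing about those features.

## The pipeline

`prepare_study_data()` applies, in order: schema validation, the
1940–1978 birth-cohort filter, bracket validity, PHQ complete-case
exclusion, covariate completeness, and the exposure join — logging row
counts at every step; the exclusion log rides along on every result
table, together with the coding values, day-mapping thresholds and SE
settings (a full audit trail). `run_main()` produces the six headline
analyses (three treatment codings × two outcomes), `run_stratified()`
the age / cohort / gender / income / dental-utilisation strata,
`run_sensitivity()` the alternative-coding re-runs, and
`run_item_level()` eight per-item fits. Every row carries its n and
first-stage F — no naked IV estimates. A stratum with a degenerate design
is marked unestimable and the run continues. No multiple-testing
adjustment is applied to stratified or per-item CIs; the reports say so.

Stratification thresholds are not universal constants and are therefore
explicit configuration with documented defaults: age splits at 50
(a typical sample-mean age for these cohorts surveyed 2006–2010), year
of birth at the 1959/1960 cohort midpoint, income at the $50 000 bracket
boundary, dental utilisation at a visit within the last year.

## Test-bench problem sizes

The acceptance-style checks run at sizes chosen to finish in minutes on
one core while leaving Monte-Carlo error well below the effects being
detected: oracle equivalence on 25 randomised frames up to $n = 1000$
(tolerance $10^{-8}$ relative, against dense normal-equations and
FWL-residual-ratio oracles built independently of the QR path); recovery
over 500 replicates at $n = 5000$; CI coverage over 1 000 replicates at
$n = 2000$ (accepting 93–97%); weak-instrument behaviour over 200
replicates at $n = 800$ with $\pi = 0$, where at least 99% of replicates
must be refused ($F<1$) or flagged ($F<10$); plus exact scoring, coding
and exposure contracts. The larger one-shot checks (conditional-mean
property, exclusion-restriction slope, analytic-vs-empirical OLS slope)
use single datasets of 20 000–50 000 rows.

## Known limitations

- The estimator supports exactly one excluded instrument; over-identified
  designs are refused rather than approximated.
- Bracket-coded treatments make real-data 2SLS a ratio of two
  coding-dependent quantities; the sensitivity runner quantifies, but
  cannot remove, that dependence.
- The linear probability model can predict outside [0, 1]; its
  coefficients remain valid average partial effects, which is all the
  caseness analysis interprets.
- Just-identified IV Wald intervals are mildly conservative at moderate
  first-stage strength: the coverage checks measure about 96–97% for the
  nominal 95% CI at $n$ = 2 000 (median F ≈ 20), tightening toward the
  nominal level as the first stage strengthens.
- Exposure misclassification from childhood relocation is not modelled;
  it biases the first stage toward zero and is partly why population-scale
  samples are needed with realistic instrument strength.
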