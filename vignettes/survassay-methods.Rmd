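---
title: "Statistical methods in survassay"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Statistical methods in survassay}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(survassay)
```

survassay analyzes lifespan assays — cohorts of organisms (worms, flies,
mice) observed at regular intervals until death, with subjects that
escape, desiccate or are otherwise lost recorded as right-censored. This
vignette describes the estimators and tests the package implements, the
conventions and tunable parameters behind them, what the synthetic
generator does and does not emulate, and the known limitations.

## Data model

A grouped lifespan table records, per observation time, the number of
deaths and the number of censored subjects. `survival_dataset()` stores
one labelled cohort; times must be strictly increasing (duplicate rows
are merged), and every row must carry at least one subject. A subject
censored at time $t$ is assumed to have been alive through $t$: it
leaves the risk set only after the deaths at $t$ are counted. Decimal
times are accepted — nothing in the machinery requires whole days —
though assays typically record integer days.

## Kaplan-Meier estimation and descriptive statistics

The survival function is estimated by the product-limit formula
$\hat S(t) = \prod_{t_j \le t} (1 - d_j / n_j)$ over the distinct death
times, with Greenwood's variance
$\hat S(t)^2 \sum_{j} d_j / (n_j(n_j - d_j))$. Where the curve reaches
zero the Greenwood variance is reported as 0 (the classical formula
degenerates there).

`summary_stats()` reports:

* **Restricted mean lifespan** — the area under the step function from 0
  to the last observed time (death or censoring). With no censoring this
  equals the arithmetic mean of the death times exactly. The truncation
  point `tau` is configurable.
* **Standard error** — the classic Kaplan-Meier area-variance
  $\sum_j A_j^2\, d_j / (n_j (n_j - d_j))$ with
  $A_j = \int_{t_j}^{\tau} \hat S$, with no finite-sample correction
  factor. A resampling alternative was considered and rejected: the
  closed form is deterministic, standard, and matches the convention of
  the mainstream survival software a reader will compare against.
* **95% CI** — normal approximation, mean ± 1.96 SE.
* **Ages at 25/50/75/90% mortality** — the smallest death time with
  $\hat S(t) \le 1 - q/100$, with no interpolation between event times
  (the data are step functions; interpolated ages would suggest
  precision the assay does not have). The age at 100% mortality is
  undefined when the longest-lived subject was censored, and is printed
  as "-".

`log_cumulative_hazard()` returns $y(t) = \ln(-\ln \hat S(t))$ at each
death time with $0 < \hat S(t) < 1$. The default transforms the
displayed KM estimate, so the curve is exactly consistent with the
survival plot; the Nelson-Aalen estimator
$y(t) = \ln \sum_{t_j \le t} d_j/n_j$ is available by option. Under
Gompertz mortality the curve is linear in $t$: the slope reads as the
age-dependent acceleration of mortality and the intercept as the
initial hazard.

## Tests for differences in lifespan length

**Log-rank (Mantel-Cox).** Observed minus expected deaths in group 1
over the pooled death times, normalized by the hypergeometric variance
$v_i = d_i (n_{1i}/n_i)(n_{2i}/n_i)(n_i - d_i)/(n_i - 1)$, referred to
$\chi^2_1$. Times with a single subject at risk contribute zero
variance. Optimal under proportional hazards; insensitive to
differences that preserve the mean, such as crossing curves.

**Fleming-Harrington $G(\rho, \gamma)$ weighted log-rank.** Each pooled
death time is weighted by
$\hat S(t-)^{\rho} (1 - \hat S(t-))^{\gamma}$, where $\hat S(t-)$ is
the left-continuous pooled KM estimate — the standard evaluation side,
which keeps the weight predictable (it depends only on deaths strictly
before $t$). $\rho > 0$ emphasises early deaths, $\gamma > 0$ late
deaths; $(0,0)$ reduces to the log-rank test identically. Weights can
degenerate (e.g. $\gamma > 0$ with a single event time); this raises an
error rather than returning a 0/0 statistic.

**Fisher's exact test at a mortality quantile.** At the first pooled
death time $t^*$ where pooled KM mortality reaches the target fraction
(default 90%), subjects are cross-classified alive/dead by group.
Subjects censored *before* $t^*$ have unknown status there and are
excluded from the table; subjects censored at or after $t^*$ were alive
at $t^*$ and count as alive. The two-sided p-value sums hypergeometric
probabilities of all tables no more probable than the observed one
(probability-mass ordering, not doubling). "First time at or after the
target" was chosen over "nearest time" as the deterministic reading of
"mortality at q%".

## Tests for differences in curve shape

**Kolmogorov-Smirnov (permutation).** The statistic is
$D = \sup_t |\hat S_1(t) - \hat S_2(t)|$ over pooled death times. The
p-value is by random relabelling of subjects: because subjects sharing
(time, status) are exchangeable, a relabelling is a random two-way
table with fixed margins, drawn with `stats::r2dtable` and evaluated by
vectorised matrix algebra over the pooled event times. The permutation
null is exact up to Monte Carlo error and remains valid under ties;
the classical asymptotic theory for the censored KS statistic does not
allow tied observations, so a warning is still attached whenever any
time carries more than one death. The permutation margins are passed in
a canonical order so the same seed gives byte-identical p-values when
the group labels are swapped.

**Neyman's smooth test.** The equality of the two curves is tested
against smooth alternatives in which the log hazard ratio is a
low-order polynomial in transformed time. Time is mapped through the
pooled Nelson-Aalen cumulative hazard rescaled to $[-1, 1]$ — an
intrinsic clock that spaces event times by information content — and
the basis is the Legendre polynomials of degree $0, \dots, d - 1$.
Degree 0 (constant) spans exactly the log-rank direction, so the score
statistic of dimension 1 *is* the log-rank statistic; this grounds the
interpretation of the selected dimension: $d^* = 1$ suggests a constant
hazard ratio, $d^* = 2$ a monotone change, $d^* = 3$ a convex/concave
(crossing) difference. The dimension is chosen by Schwarz's rule,
$d^* = \arg\max_d (T_d - d \log n_{\mathrm{events}})$, and the reported
statistic is $T_{d^*}$. The default p-value permutes the full
data-driven statistic (selection redone per permutation); a
$\chi^2_1$ asymptotic approximation is available by option. `max_dim`
defaults to 5 and is reduced with a warning when there are fewer pooled
death times.

**Chow test on hazard regressions.** Straight lines are fitted by least
squares to each log cumulative hazard curve and to the pooled points;
$F = \frac{(RSS_p - RSS_1 - RSS_2)/k}{(RSS_1 + RSS_2)/(N_1 + N_2 - 2k)}$
with $F(k, N_1 + N_2 - 2k)$ reference. The parameter count defaults to
$k = 3$, the convention carried by the lifespan web tools this package
interoperates with, even though a slope-and-intercept line has two mean
parameters (the third count can be read as the error variance). Because
the discrepancy is unexplained rather than derived, $k$ is exposed as
an argument instead of being silently corrected.

## Tests for differences in lifespan variance

These are the package's distinctive tests: two cohorts can share a mean
lifespan yet differ sharply in spread, and location tests miss that.

**Death-time reconstruction.** Moment-based comparisons need a death
time per subject, but censored subjects have none. Each censored
subject is redistributed over the death times after its censoring time,
proportionally to the KM conditional probability of dying in each later
interval: $w_j \mathrel{+}= (\hat S(t_{j-1}) - \hat S(t_j))/\hat S(c)$
for $t_j > c$. Conditional mass that falls beyond the last observed
death time has nowhere to go and is truncated with a warning rather
than silently dropped or spuriously assigned. This redistribution is
one defensible reading of "estimating the dead from the survival
function"; rescaling variances by inverse-probability weights would be
another, and the choice is documented here precisely because the
underlying method description does not fix it.

**Survival-time F-test.** The weighted sample variances of the two
reconstructed death-time samples form $F = s_1^2/s_2^2$, referred
two-sidedly to $F(\nu_1, \nu_2)$ with $\nu_g$ = round(total weight) − 1
(fractional-weight df corrections are deliberately out of scope). The
test assumes normal lifespans, so each reconstructed sample is checked
with the Shapiro-Wilk test (`stats::shapiro.test`, i.e. Royston's
approximation); if either p-value falls below 0.01 (configurable) a
warning marks the F-test as not applicable. The gate warns rather than
refuses: the variance ratio is still reported for transparency.

**Partial-slopes rank-sum test.** The partial slopes
$D_i = (y_{i+1} - y_i)/(t_{i+1} - t_i)$ of each log cumulative hazard
curve are compared with a two-sided Wilcoxon rank-sum test — exact by
enumeration when the combined count is at most 20 with no ties,
otherwise the tie-corrected normal approximation with continuity
correction (both via `stats::wilcox.test`). Slopes are per-interval
quantities, so the number of observed death times, not the number of
subjects, carries the information: at least six time points per curve
are required, and six to ten draw a low-power warning. Slopes are
computed between the curve's event times (death times); observation
times without deaths contribute no hazard increment and no slope.

**Normalized Chow test.** Centring each curve's times and values at
zero removes the intercept from the regression, so pooling the centred
points and fitting slope-only lines through the origin compares slopes
alone; vertical offsets between curves — different initial hazards —
no longer contribute. After centring, the slope is the only fitted
parameter, so the numerator parameter count defaults to $k = 1$; this
deliberately diverges from the un-normalized default $k = 3$, which
was never re-derived for the centred case, and both are configurable.

## Cox proportional-hazards regression

`fit_cox()` maximizes the Cox partial likelihood for
$h_i(t) = h_0(t)\exp(x_i'\beta)$ by Newton-Raphson from $\beta = 0$,
halving the step whenever it would decrease the likelihood, declaring
convergence when the score norm drops below `tol` (default 1e-9,
`max_iter` 50). Ties are handled by Breslow's approximation by default
— the simplest and the convention of legacy tools — with Efron's
available. Model SEs come from the inverse observed information; with
`robust = TRUE` the sandwich estimator is computed from per-subject
score residuals (Efron-weighted sub-steps when ties = "efron"),
matching the standard grouped-jackknife convention. Monotone
likelihoods (complete separation of risk) are detected when a
coefficient passes |β| > 20 and reported as an error, as are singular
information matrices from collinear covariates. The baseline hazard is
not estimated: the package reports coefficients, hazard ratios and
significance only.

## The synthetic lifespan generator

`simulate_lifespans()` draws death times from a Gaussian, Gompertz
(via `flexsurv::rgompertz`) or exponential model, optionally censors a
chosen fraction of subjects at a uniform time before their death (a
mechanism independent of lifespan, so censoring is non-informative),
and records times as whole days — the resolution of a real assay, and
the source of the tied observations the shape tests warn about.

`make_validation_triplet()` generates the three-cohort benchmark the
variance tests are validated on: A ~ Normal(20, 2²), B ~ Normal(20, 4²),
C ~ Normal(30, 4²) days. "Spread of 2 vs 4 days" is read as standard
deviation — the stated unit (days) is that of the SD, not the variance.
The default cohort size is 250, large enough that every test's
qualitative behaviour is stable across seeds.

What the generator does **not** emulate: heterogeneity/frailty mixtures,
informative censoring, interval censoring, cohort effects (plate or
incubator batches), and measurement error other than day-rounding.
Passing simulation tests therefore demonstrates correctness of the
statistical machinery under clean assumptions, not robustness to every
pathology of real assay data.

## Calibration findings and known limitations

The package's own simulation harness (see `tests/testthat/` and
`scripts/acceptance.R`) measures, under a null of two equal
Gaussian(20, 4) integer-day cohorts of 100 subjects:

* log-rank, KS (permutation), Neyman (permutation) and the survival-time
  F-test hold the 5% level to within Monte Carlo error;
* the **partial-slopes rank-sum test is conservative** (empirical level
  well below 5%): the slopes within one curve are mutually dependent
  and share a deterministic time trend, so the Wilcoxon null variance
  overstates the variability actually present between two curves from
  the same process;
* the **normalized Chow test is anticonservative** (empirical level
  well above 5%): log cumulative hazard points are cumulative, hence
  strongly autocorrelated, and the F reference assumes independent
  homoscedastic residuals.

Both tests still separate genuinely different variances with high power
(the A-vs-B benchmark), but their p-values should be read as
diagnostics, not calibrated error rates; for a calibrated variance
comparison the survival-time F-test is the one to quote. A related
finding: at the 250-subject benchmark size the log-rank test *also*
detects the A-vs-B variance difference in most replicates — its
insensitivity to pure variance differences is a small-sample
phenomenon, not an asymptotic one, because the early/late death
contributions cancel only approximately.

Numerical conventions collected in one place: percentile ages use
"first time at or below the survival threshold" with no interpolation;
permutation p-values use the add-one estimator $(1 + k)/(B + 1)$;
Greenwood variance is 0 where $S = 0$; weighted log-rank terms with one
subject at risk contribute zero variance; Chow tests clamp tiny
negative F (floating-point cancellation) to 0; p-values below 1e-10
print as "<1.0E-10", or "0.00E+00" in compatibility mode.

Simulation sizes used by the test-suite harness (1000 null replicates
at n = 100/group; 200 benchmark replicates at n = 250/group; permutation
count 399 in replicated runs, chosen so the achievable level of the
add-one p-value is exactly 20/400 = 0.05) are the package's validation
design; single analyses default to 2000 permutations.
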