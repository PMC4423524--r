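---
title: "Modelling initiation into injecting and the injector replacement rate"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling initiation into injecting and the injector replacement rate}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(efrinit)
library(dplyr)
```

## The problem

Injection drug use spreads behaviourally: almost every novice injector is
initiated in the presence of established injectors. Cross-sectional surveys of
injectors can therefore measure *incidence* indirectly, by asking respondents
two questions: how many times in the past year were you present when someone
injected for the first time, and how many **other** injectors (excluding you
and the novice) were present at the most recent such event?

`efrinit` implements the full analysis chain around those two questions: the
shared-responsibility initiation-rate statistic, a piecewise discrete-hazard
model of when injectors are first incarcerated (incarceration history is
strongly associated with initiation behaviour), and a discrete-time model of
the **replacement rate** — the expected number of initiations, weighted by
responsibility, over a whole injecting career. A replacement rate of 1 means
each injector is, on average, replaced by exactly one novice, the analogue of
a reproduction number of 1 in an epidemic model.

## The EFR statistic

Responsibility for an initiation attended by $k+1$ injectors is shared
equally, so a respondent present at $n$ initiations in the past year, with $m$
other injectors present at the most recent one, has an *equivalent of full
responsibility* (EFR) initiation rate of

$$\lambda_{\mathrm{EFR}} = \frac{n}{m + 1}$$

per annum (the $+1$ is the respondent; the novice never counts). This assumes
the others-present count at the most recent event is representative of the
respondent's past-year events. Subgroup rates are means of per-respondent
rates *including the zeros*, so they are interpretable as per-injector
per-annum incidence contributions. Equal sharing is not just convenient: if
full responsibility were instead assigned to a single uniformly chosen
attendee, the expected assigned share would again be $1/(k+1)$, so the equal
share is the coherent choice when nothing is known about the attendees (the
suite checks this by simulation).

Respondents present at at least one initiation but with a missing
others-present answer cannot contribute a responsibility share; they are
excluded from both the numerator and the denominator of their subgroup and
reported in `n_dropped_missing`. Respondents who did not inject in the past
year are retained by default (some of them initiate); `past_year_only = TRUE`
reproduces the sensitivity analysis that excludes them.

Uncertainty comes from a paired nonparametric bootstrap: respondents are
resampled with replacement within each subgroup, each carrying its
(initiations, others-present) pair jointly, with percentile intervals. We use
percentile rather than BCa intervals as the simplest defensible choice for a
mean-type statistic at these subgroup sizes. The default is 5,000 resamples
per subgroup.

```{r}
cohort <- generate_cohort(cohort_config(n_respondents = 2500, seed = 1))
efr_bootstrap(cohort$records, prison = "ever", n_boot = 500, seed = 1) %>%
  select(n_respondents, lambda_efr, ci_low, ci_high, log_lambda_var)
```

## Regression across subgroups

To assess how sex, career length and incarceration history shape
$\ln \lambda_{\mathrm{EFR}}$, the 12 sex $\times$ career-bin $\times$ prison
subgroup estimates are regressed on indicator terms (baselines: female, 0–5
years, never incarcerated) with weights equal to the bootstrap precisions
$1/\widehat{\mathrm{Var}}(\ln \lambda)$. The log-scale variance is computed
over replicates with positive $\lambda$ — zero replicates would make the log
infinite — and zero-heavy subgroups are flagged via `n_zero_replicates`.
Inference uses the $t$ distribution on $n - p = 12 - 5 = 7$ degrees of
freedom, matching ordinary weighted-least-squares practice. The fit is
delegated to `stats::lm()`; the test suite checks it against a direct
normal-equation solve to $10^{-10}$.

## First incarceration as a piecewise discrete hazard

The career year of first incarceration $X$ has per-annum probability $p_1$ in
career years 1–5, $p_2$ in 6–10 and $p_3$ thereafter, so

$$P(X > t) = (1-p_1)^{\min(t,5)} (1-p_2)^{\min(\max(t-5,0),5)}
             (1-p_3)^{\max(t-10,0)}.$$

We work throughout with this survival form: it makes the ever/never
likelihood coherent, with each respondent contributing $P(X \le t)$ (ever
incarcerated at career length $t$) or $P(X > t)$ (never). A respondent with
$t = 0$ and an incarceration history is an impossible observation under the
model (first incarceration happens in year 1 at the earliest) and is rejected
rather than silently dropped.

The likelihood is maximised by cyclic coordinate-wise 1-D optimisation
(`stats::optimize()` per coordinate, golden section with parabolic
interpolation) on $[10^{-6}, 1-10^{-6}]^3$, iterated to a $10^{-9}$ objective
tolerance with restarts from three points along the cube diagonal. The
likelihood is smooth and near-separable in the three rates, so 1-D cycling is
reliable; a dense 21³ grid search with local refinement guards it in the test
suite (agreement within $2 \times 10^{-3}$). Confidence intervals are profile
likelihood intervals at the $\chi^2_1(0.95)/2 \approx 1.92$ cutoff, found by
root bisection; a profile that stays above the cutoff all the way to the box
(e.g. when no respondent's career reaches a piece, leaving it unidentified)
reports the boundary and sets a flag. The pooled ("overall") fit pools
records rather than averaging sex-specific fits.

```{r}
fit <- fit_incarceration(cohort$records, sex = "M")
tidy(fit)
```

## The replacement rate

With per-annum cessation probability $c$ and an immediate quit probability
$q$ (novices who never become active injectors), career survival is
$P(IC > t) = (1-q)(1-c)^t$ and the expected career length is $(1-q)/c$.
Career years are indexed $t = 0, 1, 2, \dots$, with the 0–5 bin covering
$t \in \{0,\dots,5\}$: year 0 is the injector's first, already-active year.
The replacement rate is

$$R = \sum_x \sum_t \lambda_{\mathrm{EFR}}(t, x)\, P(IC > t)\, P(X = x),$$

where $\lambda_{\mathrm{EFR}}(t, x)$ is the ever-incarcerated rate for the
career bin of $t$ once $x \le t$ and the never-incarcerated rate before.
The default evaluator exchanges the sums,

$$R = (1-q) \sum_{t \ge 0} (1-c)^t \left[\lambda_{\mathrm{never}}(t) P(X>t) +
\lambda_{\mathrm{ever}}(t)\,(1 - P(X>t))\right],$$

computes $t = 0,\dots,10$ explicitly and sums the constant-rate tail
$t \ge 11$ in closed form as two geometric series (ratios $1-c$ and
$(1-c)(1-p_3)$), so $R$ is exact to floating point; the `tol` argument only
governs the optional truncated-series and triple-sum (`pmf_sum`) evaluation
routes, which the tests require to agree with the closed form to $10^{-10}$.
At $c = 0$ the career length, and hence $R$, diverges and the function
errors. Because $q$ enters only through $P(IC > t)$, $R = (1-q) f(p, c)$
exactly; $f$ is returned alongside $R$.

```{r}
scenarios <- c(0.05, 0.10, 0.15)
sapply(scenarios, function(cess) {
  replacement_rate(nesi_efr_lookup(), nesi_incarceration_rates(), cess)$R
})
```

Setting $R = 1$ and solving for the quit rate gives the closed form
$q' = 1 - (1-c)/R(p, c, c)$, where $R(p,c,c)$ is the replacement rate with
the quit rate set equal to the cessation rate. A negative $q'$ (possible when
$R < 1-c$) signals a population already below replacement; it is reported
unclamped with a flag rather than truncated, so that callers can distinguish
"no quitting needed" from "exactly at replacement".

```{r}
r <- replacement_rate(nesi_efr_lookup(), nesi_incarceration_rates(), 0.05)
quit_rate_for_unit_replacement(r, 0.05)
```

Uncertainty in $R$ is propagated by a joint bootstrap (`replacement_ci()`):
respondents are resampled, and both the EFR cell rates and the incarceration
MLE are recomputed per replicate before re-evaluating $R$. The survey data do
not pin down whether incarceration-rate uncertainty should be included, so
both modes are available (`uncertainty = "joint"` is the default;
`"efr_only"` holds the incarceration rates at their full-data MLE). Cells
with no respondents in the original data are treated as structurally absent
(rate 0); a replicate fails, is skipped and counted only if an
originally-occupied cell comes back empty.

The "overall" replacement rate combines pooled (non-sex-stratified) EFR rates
with pooled incarceration rates. Sex-specific rates require the full
sex $\times$ career $\times$ prison EFR table, which is only available from
respondent-level data; multi-stratum lookup tables are supported and are
combined with user-supplied respondent weights.

## The synthetic cohort generator

No public microdata exist for the survey this package is designed around, so
`generate_cohort()` produces seeded respondent tables with the same record
structure and known ground truth. Its defaults are calibrated once to the
published summary tables and are not meant to be tuned per analysis:

* **Demographics** — female 0.28, Greater Glasgow and Clyde 0.37, aged under
  35 0.55, past-year injector 0.85, matching the survey's marginal
  composition.
* **Career length** — truncated geometric with parameter 0.0623 (capped at 40
  years), chosen so that about 32% of careers fall in the 0–5 bin. This is a
  sampling knob, not an estimate: the survey's design (a predetermined cap on
  former injectors) makes the real career-length distribution unidentifiable,
  so the generator simply needs a plausible cross-sectional mix that
  exercises all three career bins.
* **Incarceration** — first-incarceration year drawn from the sex-specific
  piecewise process at the published maximum-likelihood rates (female
  0.07/0.06/0.04, male 0.19/0.05/0.03), with `ever_incarcerated` set by
  comparison with career length.
* **Initiation behaviour** — per (sex, career-bin, prison) cell, initiator
  status is Bernoulli with the published cell fraction and counts among
  initiators are 1 + geometric with the published cell mean (a one-parameter
  overdispersed count law with the long right tail seen in practice, range
  1–100). The published tables do not report the full 12-way
  sex-by-career-by-prison breakdown, so the six career × prison cells are
  replicated across sex; sex differences in the generator enter through
  incarceration.
* **Others present** — Poisson with mean 2.5 (the published overall mean is
  about 2.53), drawn independently of the initiation count. Real data show a
  mild positive association between the two; keeping them independent is a
  documented simplification, and nothing downstream assumes independence.
* **Missingness** — completely at random: 1.6% of initiators' others-present
  answers (about 7 in 450) and 1% of records have one demographic classifier
  blanked.

The ground-truth object returned with each cohort contains the cell-level
generating parameters, the population EFR rate
$p \cdot \bar{k} \cdot E[1/(N+1)]$ with $E[1/(N+1)] = (1 - e^{-\mu})/\mu$ for
Poisson others, and additionally the large-sample expectation of the
*estimator*: excluding missing-others initiators removes positive
contributions from both numerator and denominator, deflating the subgroup
mean by $(1-r)/(1 - p r)$ at missingness rate $r$. Recovery tests compare
estimates against the latter — the estimand of the procedure as specified —
not against the no-missingness rate.

What passing tests on synthetic cohorts do **not** show: robustness to
recruitment-site clustering, to informative missingness, to the real joint
distribution of counts and others present, or to recall bias in the past-year
counts. The generator emulates the record structure and the calibrated
marginal behaviour, nothing more.

## Numerical and design choices

* **Career-year indexing.** $t$ is 0-indexed with bin 0–5 covering
  $t \in \{0..5\}$. This convention reproduces the published overall
  replacement rates (4.8 / 2.7 / 1.9 at cessation 5/10/15% with quit =
  cessation) and is fixed; a 1-indexed reading does not reproduce them.
* **Survival reading of the hazard pieces.** The piecewise expressions are
  interpreted as the survival function $P(X > t)$ (with $P(X>0) = 1$), the
  only reading under which the ever/never likelihood terms are coherent.
* **Percentile bootstrap; log-variance weights.** Regression weights use the
  variance of $\ln \lambda$ over positive replicates; zero replicates are
  counted and flagged rather than imputed.
* **Profile CI cutoff** $\chi^2_1(0.95)/2 = 1.92$; box $[10^{-6},
  1-10^{-6}]$; flat profiles report box boundaries with `at_boundary = TRUE`.
* **Degenerate inputs.** Empty subgroups, all-zero bootstrap replicates,
  rank-deficient designs, $c = 0$, ever-incarcerated at $t = 0$, and
  malformed input rows all raise informative errors (or flagged `NA`s where
  the quantity is genuinely undefined) rather than silent results.
* **Determinism.** Every stochastic function takes an explicit seed;
  identical configurations produce byte-identical cohort files and report
  bundles (run logs deliberately contain no timestamps).

## Problem sizes used by the test suite

The suite favours analytic oracles (enumeration, closed forms, per-record
likelihood sums, normal equations) so that most checks are exact. The
simulation-based checks use: a 50,000-respondent cohort for calibration and
coverage of the 12 subgroup cells (5 seeds, 300 resamples per cell), 40
seeded cohorts of 2,500 for profile-CI coverage of the incarceration rates,
$10^6$ simulated careers for the Monte-Carlo check of the closed-form $R$,
and 12 seeded cohorts of 1,500 with 120 joint replicates for coverage of the
replacement-rate bootstrap. These sizes give Monte-Carlo error comfortably
inside the asserted tolerances while keeping the suite quick to run.

## Limitations

The model ignores the sex of novices (no data), calendar-time trends in
initiation, repeat incarcerations, injecting inside prison, and separates
neither death nor true desistence within "cessation". Replacement rates
inherit any reporting biases in the two survey questions; the quit-rate
inversion interprets a high $R$ as rapid novice desistence, which is one —
modelled, not observed — explanation among several.
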