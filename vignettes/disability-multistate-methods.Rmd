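---
title: "Modelling disability transitions and health expectancies in elderly panel cohorts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling disability transitions and health expectancies in elderly panel cohorts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(eldertrans)
```

## The model

`eldertrans` analyses panel surveys of older adults in which disability is
assessed at interview waves a few years apart and deaths between waves are
dated exactly by family report. The state space has three living states —
no disability (0), mild disability (1, help needed on an instrumental
activity of daily living while all basic activities are intact), severe
disability (2, help needed on any basic activity) — and death (3), the
single absorbing state.

The process is a continuous-time Markov chain with intensity matrix
$Q(z, a)$ whose off-diagonal entries follow a proportional-intensity
regression

$$q_{rs}(z, a) = \exp\{\log b_{rs} + \beta_{rs}^{\top} z(a)\},$$

where $z(a)$ collects age (centred, log-linear by default; 75–84 / 85+
band indicators as an alternative) and binary sex and region terms. The
default structure allows all six transitions among living states plus the
three living-to-death arrows; a `"no-jump"` structure forbidding direct
moves between no disability and severe disability is available, since
three-year panels rarely identify such jumps separately from two quick
steps. Baselines are rates per person-year at the reference profile, an
urban man at the centring age.

### Likelihood for interval-censored panels

States are observed only at waves, so a pair of living observations
($r$ at age $a_1$, $s$ at $a_2$) contributes $\log P_{rs}(a_1, a_2)$ with
$P = \exp\{Q \cdot (a_2 - a_1)\}$, the intensity being frozen at the
interval *midpoint* age. Freezing at the midpoint rather than the left
endpoint removes the first-order bias in the age slope that left-endpoint
freezing would introduce over three-year intervals. A death at exactly
known age $d$ after a last living observation in state $r$ at age $a$, the
state at death being unknown, contributes

$$\log \sum_{j \in \{0,1,2\}} P_{rj}(a, d)\, q_{j,\text{death}}(d),$$

with the death intensity evaluated at the death age itself. Subjects lost
after their last interview are right-censored there and contribute nothing
afterwards; subjects with a single interview and no death carry no
information and are excluded at ingestion, with a logged reason.

The likelihood core (C++, RcppArmadillo) computes $P$ by eigendecomposition
of $Q$ and the analytic score via the standard divided-difference identity
for the derivative of a matrix exponential; near-defective $Q$ (repeated
eigenvalues, ill-conditioned eigenvectors) falls back to an inversion-free
scaling-and-squaring exponential with block-matrix (Frechet) derivatives.
Rates are capped at 1000/person-year purely as a line-search guard.
Per-subject contributions are sorted by value before summation, which makes
the total log-likelihood bit-identical under subject relabelling or
reordering. Maximisation uses BFGS with the analytic score; the covariance
is the inverse observed information, obtained by central differencing of
the score. Starting values are crude interval rates — transition counts
over person-time in the origin state, floored at $10^{-4}$/year — on the
log scale.

## Life tables and health expectancies

Annual transition probabilities are $P(a, a+1)$ under the fitted
age-varying model, computed piecewise with $Q$ frozen on subintervals of at
most 0.5 years (midpoint age). Expected years in state $s$ starting from
state $r$ at index age $a$ are

$$e_{rs}(a) = \int_a^{A} P_{rs}(a, u)\, du,$$

evaluated by the trapezoidal rule on a 0.25-year grid up to the cap
$A = 115$ years. Both defaults are validated by the grid-convergence
invariant (halving the step moves every expectancy by well under 0.5%);
survival beyond 115 is negligible for intensities of realistic magnitude,
and the estimator warns when the living probability at the cap exceeds 1%.
Total life expectancy is $\mathrm{TLE}_r = \sum_s e_{rs}$; the reported
ND/MD/SD years and PND/PMD/PSD percentages follow, with AD = MD + SD.
Population-averaged rows weight the per-initial-state expectancies by the
empirical distribution of living states among baseline interviews within
±2.5 years of the index age in the stratum. Display rounding is one
decimal for percentages and two for years; computation keeps full
precision.

Confidence intervals use the percentile bootstrap with B = 499 subject
resamples and full refits of the whole pipeline (model fit, initial
distribution, integration), not the delta method. Replicate failures are
counted and a failure rate above 20% flags the interval as unreliable. A
single user seed is expanded into logged per-replicate substreams.

## Disability onset (Cox models)

For the onset analysis, mild and severe disability are combined into one
event. Subjects disability-free at entry are followed to the first wave
observed disabled (event, at the interval's right endpoint) or censored at
their last disability assessment — including those who die disability-free,
since death dates carry no disability assessment. Time-since-entry is the
time scale with entry age as a covariate; the alternative midpoint-event
convention is a known ambiguity of wave data and the right endpoint was
chosen as the conservative, reproducible reading. Four nested adjustment
sets are fitted (univariate; + age, sex, region; + education, marital
status, smoking, drinking, exercise, expenses, medical service; + diabetes,
heart disease, stroke), each covariate carrying an explicit `"missing"`
level so that no record is dropped. Ties are handled by Breslow's
approximation by default — wave-synchronised event times are heavily tied,
and Breslow is the simplest reproducible choice — with Efron selectable.
The partial-likelihood fit itself is delegated to `survival::coxph`; tests
verify it against a brute-force grid maximisation of the Breslow partial
likelihood.

## Multiple imputation

Missing baseline covariates are imputed by predictive mean matching:
each incomplete variable is put on a numeric working coding (0/1
indicators; 0/1/2 for the education grades), regressed by least squares on
entry age and the other covariates, and each missing entry receives the
observed value of a donor drawn uniformly from the k = 5 nearest predicted
scores — so imputed values are always legal observed categories. One sweep
over the variables is the default (missing predictors are initialised by
marginal draws; more chained sweeps are configurable). Five completed
datasets are produced and downstream result tables are pooled by the plain
entrywise mean. This mean-pooling reports no between-imputation variance
component and is therefore *not* Rubin's rules; it is retained deliberately
as the simple sensitivity-analysis convention, and flagged as such.

## The synthetic cohort generator

The generator is the test substrate: it simulates continuous-time
trajectories under a known intensity model (Gillespie algorithm with rates
frozen over 0.1-year micro-steps to honour age dependence — the freezing
error is bounded by the same grid-convergence checks), samples them at
waves at entry + 0, 3, 6, 9, 12 years, applies per-wave dropout (8% by
default), dates deaths exactly only when a later attended contact exists to
report them, and deletes covariate items at small per-item rates
(0.01%–0.4%, the order observed in large elderly surveys). Entry ages are
uniform on 65–95, and entry-state and covariate frequencies by sex and
region echo published CLHLS descriptive magnitudes (e.g. ~56% of urban men
disability-free at entry). The default true intensities reproduce the
qualitative phenomena of elderly disability dynamics — incidence and
mortality rising log-linearly with age, recovery declining with age, female
excess disability incidence with male excess mortality, a rural recovery
advantage — at realistic magnitudes, without claiming to equal any
particular fitted values. What the generator does *not* emulate: survey
weights and household sampling, proxy-response effects, wave-specific
questionnaire changes, and any non-Markov dependence on disability history.
Passing tests therefore validate the estimators under the model's own
assumptions, not the assumptions themselves.

A `calibration_scenario()` is provided for parameter-recovery experiments.
Its design differs from the survey-emulation defaults because its purpose
differs: estimator validation wants every parameter identifiable, so rates
(0.06–0.15/person-year) are balanced to give each arrow adequate expected
events over five waves, entry is young (65–68) to accumulate person-time,
covariates are balanced Bernoulli(0.5), dropout is off, and age is centred
at 71 — the person-time centre of the follow-up window, where baseline
estimates are anchored in the data-dense region rather than extrapolated.
These choices were fixed by a Fisher-information power analysis before any
recovery experiment was run. At n = 2000 with three-year interval censoring
and unknown state at death, per-parameter standard errors plateau around
0.09–0.14; recovery is therefore assessed per parameter class (the share of
parameter-by-replicate errors within 0.15 for baselines, 0.2 for covariate
effects), not as a joint bound over all 28 parameters, which no design of
this size can meet.

## Numerical choices and degenerate inputs

- Transition matrices are validated row-stochastic to $10^{-10}$;
  violations raise an internal-consistency error rather than propagate.
- A zero-probability observed path (impossible under the chosen structure)
  yields a $-\infty$ contribution with a diagnostic naming the offending
  transition pair.
- A wave recording both a living state and a death age, a death at or
  before the last interview, and unknown state codes are hard input
  errors; non-monotone interview ages exclude the subject with a logged
  diagnostic.
- Ties among predicted scores in PMM are broken stably by record order;
  with fewer than k observed donors the pool shrinks to those available.
- Bootstrap refits start from the full-data estimates; a replicate that
  fails to converge is counted as a failure, never silently kept.
- Empty descriptive strata report N = 0 rows; percentages always use
  nonmissing denominators.

## Problem sizes used in the test-suite experiments

Simulation experiments in the tests and acceptance script use: 20
replicates of n = 2000 subjects for parameter recovery; 50 replicates of
n = 400 for the null-effect Wald coverage check; 10^5 trajectories for
occupancy oracles and 2–3×10^5 for one-year frequency and path-probability
oracles; B = 60 bootstrap resamples where only interval behaviour (not the
published B = 499 default) is under test. These sizes give Monte-Carlo
error comfortably inside each check's tolerance.

## Known limitations

- The Markov assumption: future transitions depend only on the current
  state and age, not on disability history; no frailty or random effects.
- Exact transition times between living states are never modelled — only
  panel snapshots — so within-interval trajectories are identified by the
  model, not the data.
- Mean pooling of imputation results understates imputation uncertainty
  relative to Rubin's rules.
- The onset Cox analysis treats the first disabled wave as the event time
  (right endpoint), which overstates onset times by up to one wave gap.
- Proxy-answered ADL items are treated identically to self-reports.
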