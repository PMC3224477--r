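---
title: "Current survival measures for remission–relapse histories"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Current survival measures for remission–relapse histories}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The clinical model

Modern therapy for chronic-phase chronic myeloid leukaemia turns the
disease into a sequence of remissions and relapses: a patient starts
therapy, may achieve a complete cytogenetic remission, may lose it, may
regain it with a second-line drug, and so on, with death possible from any
state. Four states describe a patient at any moment: on therapy without
remission, in remission, in relapse, and dead. Observation ends at death
or at right censoring.

`currentsurv` represents such a history as a long table of events
(`achieve`, `lose`, `death`, `censor`) with times from therapy initiation.
Validation (`as_event_history()`) enforces what the model implies:
transitions strictly alternate starting with an achievement, there is
exactly one terminal event per patient and it comes last, and times
strictly increase within a patient. Tied within-patient times are
*rejected* rather than ordered by convention: the continuous-time model
assigns them probability zero, the literature defines no ordering for
them, and silently choosing one would move real probability mass. For the
same reason a death recorded at exactly the time of a loss is refused
rather than classified.

## The measures and their estimators

Two quantities describe the *current* (rather than first-event) status of
the cohort:

* **CCI(t)** — the probability of being alive and in any remission at
  time *t* after therapy initiation. With $I_i$, $I_i^{*}$ and
  $I_i^{**}$ the cumulative incidence functions of achieving the $i$-th
  remission, losing it, and dying while in it,
  $\mathrm{CCI}(t) = \sum_{i=1}^{r} \big[ I_i(t) - I_i^{*}(t) -
  I_i^{**}(t) \big]$.
* **CLFS(t)** — the probability that a patient who achieved a first
  remission is alive and in any remission at time *t* after that
  achievement. With $S_1^{*}$ the Kaplan–Meier survival against first
  loss or death in first remission and, for $i \ge 2$, $S_i$ and
  $S_i^{*}$ the survival against the $i$-th achievement (or earlier
  death) and the $i$-th loss (or earlier death), all on the reset clock,
  $\mathrm{CLFS}(t) = S_1^{*}(t) + \sum_{i=2}^{r}\big[ S_i^{*}(t) -
  S_i(t) \big]$.

The depth $r$ is always taken from the data — it grows with follow-up —
but can be overridden downwards for sensitivity analyses (`r =` argument).

Each cumulative incidence component is assembled from the two scalar
primitives every survival analyst knows: the Nelson–Aalen cause-specific
hazard increment $c_{ij}/n_{ij}$ and the all-cause Kaplan–Meier factor
evaluated *just before* the jump. The loss and death-in-remission
components of the same depth share one all-cause survival factor by
construction; this is what makes the telescoping sum estimate a state
occupation probability. Censored observations tied with an event time stay
in the risk set at that time (the standard convention; nothing in the
model dictates otherwise).

Assumptions: observations are independent and identically distributed and
censoring is independent of the state process and transition times. The
component estimators assume nothing Markovian: the Aalen–Johansen form is
consistent for state occupation probabilities of non-Markov processes
under independent censoring, which is why a semi-Markov generator is the
right stress test (below). Under *dependent* censoring the estimates are
biased; inverse-probability-of-censoring weighting would be the remedy and
is out of scope here.

### Why the curves may leave [0, 1]

CCI and CLFS are linear combinations of separately estimated monotone
curves. Nothing constrains the combination: under heavy censoring the
estimate can dip below 0, exceed 1, or rise again (a late re-achievement
genuinely raises the leukaemia-free fraction — non-monotonicity is
correct, not an artefact). The package reports raw values and warns when
the unit interval is left; it never clips, because clipping would hide
exactly the instability a user should see. Point estimates at late times
should be read together with the at-risk count (`at_risk()`,
`compare_markov()$n_risk`): the direct and the Markov estimators are known
to drift apart once fewer than about ten patients remain under
observation, and no truncation rule is imposed.

## The Markov multi-state comparator

Unrolling each remission/relapse episode into its own state gives a
progressive (acyclic) multi-state model; summing the occupation
probabilities of all remission states yields the same target quantity.
`cci_markov()` estimates it by the product-integral of the matrix of
Nelson–Aalen transition-hazard increments over observed transition times.
By default death is a single absorbing state ($2r + 2$ states): the
remission-state occupation probabilities are identical to those obtained
with stage-specific death states, and the matrices stay small.
`progressive_states(r, split_death = TRUE)` builds the stage-specific
variant (nine states at depth two) for users who want the bookkeeping made
explicit. Each accumulated matrix is row-stochastic by construction; the
test suite checks this to $10^{-10}$.

## Bootstrap confidence intervals

Analytic standard errors for these linear combinations exist in principle
but are notoriously unpleasant; the package follows the feasible route:

* **Procedure II (default, the only one for multi-state curves):**
  resample whole patient histories with replacement. The patient is the
  independent unit; resampling anything finer would break the dependence
  between a patient's successive remissions.
* **Procedure I** (`resample_efron1()`): separate resampling from the
  Kaplan–Meier estimates of the event-time and censoring-time
  distributions, taking pairwise minima with indicators. This construction
  is only well defined for a single endpoint, so the package exposes it
  for single-endpoint curves only rather than inventing a multi-state
  extension. When a Kaplan–Meier curve does not reach zero the missing
  mass lies beyond follow-up; such draws cannot win the minimum and a
  message is emitted, and if both draws fall beyond follow-up the
  observation is recorded as censored at the largest observed time.

Intervals are *point-wise* nearest-rank (type 1) percentiles across the
`B` replicate curves at each grid time — the simplest defensible
percentile rule, stable and invariant to replicate ordering. Defaults:
`level = 0.95`; `B` is chosen by the caller (the validation harness uses
500; an overnight analysis can afford 10,000). A resample can be
degenerate — e.g. no patient with a remission when the statistic is CLFS;
such replicates are recorded as missing, and more than 1% missing aborts
with a diagnostic rather than quietly reporting a band computed on a
biased subset.

## The synthetic-data generator

`sim_scenario()` / `simulate_cohort()` emulate the structure the
estimators are built for: Weibull sojourn times for
diagnosis→remission, remission→relapse and relapse→remission transitions
with the clock restarting at every state entry (semi-Markov), one Weibull
death clock running from therapy initiation that truncates the transition
sequence, and independent uniform censoring on a 0–10-year window. Setting
every shape to 1 (`markov_scenario()`) makes the process Markov, which is
the regime where the direct and the multi-state estimators should — and in
the tests do — almost coincide.

Design choices worth making explicit:

* **A single death clock from origin**, not per-state death hazards:
  transitions simulated after the drawn death time are simply discarded.
  A per-state competing death hazard would be a reasonable extension but
  is deliberately not the default.
* **Default parameters are illustrative**, not fitted to any patient-level
  data (none are published for this disease setting at event level). They
  were chosen once, on a months scale, to reproduce cohort-level
  magnitudes reported for first-line TKI therapy: roughly 63% of patients
  in first remission by 12 months, about a quarter of first remissions
  lost within three years, most relapses regaining remission within a
  year, and a low death hazard. Shapes are mildly non-exponential
  (0.9–1.3) so that the default process is genuinely semi-Markov.
* **Ties are guarded**: sojourns are redrawn in the probability-zero event
  of a non-positive draw, so simulated cohorts always pass validation.
* A `max_depth` safeguard (default 100 remissions) aborts runaway
  scenarios loudly instead of looping.

What the generator does *not* emulate: dependent censoring, covariates,
interval-censored response assessments (remission times are treated as
exactly observed), per-state death rates, and real-world assessment
schedules. Passing the simulation tests therefore demonstrates correctness
of the estimators under independent censoring and semi-Markov dynamics —
not robustness to violations of those assumptions in clinical data.

## The validation harness and the problem sizes used

`true_curve()` approximates the process's true CCI/CLFS by direct state
counting on a large fully observed cohort (default 10,000 trajectories,
exact transition times, no censoring). `evaluate_mad()` summarises, per
grid time, the median absolute deviation of an estimator from that truth
across replicate censored cohorts; `evaluate_coverage()` reports the
fraction of replicates whose percentile interval contains the truth plus
its binomial Monte Carlo standard error.

The packaged validation (test suite and `scripts/acceptance.R`) runs at
sizes chosen to give informative Monte Carlo precision on a single CPU
within minutes: 200 replicate cohorts, sample sizes 100 and 1,000,
B = 500 bootstrap resamples, truth from 10,000–20,000 trajectories, a
yearly grid over ten years. At these sizes the observed behaviour matches
what theory predicts: the MAD at n = 1,000 sits near $1/\sqrt{10}$ of the
MAD at n = 100, empirical coverage of the nominal 95% intervals stays in
the low-to-mid 90s over years 1–5, and the direct and Markov estimators
differ by well under 0.02 on Markov cohorts of 1,000 while enough patients
remain at risk. The harness exposes `reps`, `B` and `n_curves` so any of
this can be rerun at larger scale.

## Numerical conventions

* Curves are stored exactly at their jump times; evaluation is
  right-continuous with last-value carry-forward and no interpolation or
  smoothing. The default evaluation grid of an estimator is the union of
  its component jump times, which is lossless.
* All estimator values are finite products and sums of small rationals, so
  unit tests compare them to hand-derived values at absolute tolerance
  $10^{-12}$; stochastic checks state their Monte Carlo tolerance
  explicitly.
* Every stochastic function takes an explicit integer `seed`; the same
  seed reproduces cohorts, bands and reports byte for byte.
* Time units are whatever the data declare (months throughout the
  defaults) and are never converted implicitly. Delayed entry / left
  truncation is unsupported: the origin is always therapy initiation.

## Known limitations

* No analytic standard errors, no bias-corrected or studentized bootstrap
  intervals — plain percentiles only.
* No covariate adjustment and no two-sample tests comparing current
  curves; both are natural next steps but separate problems.
* The counting diagnostic `occupied_fraction()` is exact only for fully
  observed cohorts; under censoring it is biased and should be used only
  to sanity-check uncensored simulations.
* Percentile bands need not bracket the point estimate in pathological
  resamples; the package enforces only `lower <= upper`.
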