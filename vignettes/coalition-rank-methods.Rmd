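---
title: "Methods: coalition dynamics, rank trajectories and paternity"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: coalition dynamics, rank trajectories and paternity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

This vignette is the package's own account of the models it implements, the
choices that were genuinely open, and what its synthetic-data tests do and
do not demonstrate.

## Dominance ratings

Dominance strength is scored by sequential Elo-rating. After each decided
contest the winner gains and the loser loses
$k\,(1 - E(R_w - R_l))$ points, where $E$ maps the pre-contest rating
difference to the winner's expected success. Two expected-score functions
are implemented, both satisfying $E(0) = 1/2$ and $E(d) + E(-d) = 1$:

* `logistic-400`: $E(d) = 1/(1 + 10^{-d/400})$ — the chess convention;
* `normal-cdf`: $E(d) = \Phi(d / 200\sqrt{2})$ — common in the
  animal-dominance literature.

The rating method is conventional and its update formulas are not restated
by the field papers that use it, so both standard variants are selectable
(`elo_params()`); the test suite exercises both. Defaults are a start value
of 1000 and $k = 100$ — usual values for macaque hierarchies, where single
decided contests are informative. Conventions that needed fixing:

* **Within-day order.** Interactions on the same day are processed in
  recorded order (a stable sort); this is deterministic and matches how
  field data are logged.
* **Day-0 rating.** The rating "on the day of" an event is the value after
  all dyadic interactions of that day. The coalition event itself never
  feeds the rating update: only dyadic agonism does. This avoids building
  the predictor (coalition membership) into the response (future rating)
  mechanically. Including coalitions as participant-versus-target wins
  would be a sensitivity analysis, deliberately not the default, since the
  field protocol this mirrors is silent on the point.
* **Carry-forward.** Ratings are step functions: `rating_at()` returns the
  last update on or before the query date, and the start value before any
  contest. Offsets after a male emigrates are *absent*, never imputed —
  once the reference group no longer contains the male, neither his rating
  nor its standardization is defined.

Standardization (`standardize_ratings()`) is a min–max map to $[0, 1]$
among all males present in the group on the reference date (not only event
members), requiring at least two males and a non-degenerate rating range.

## Coalition metrics

A coalition is simultaneous aggression by at least two participants against
a target. Configuration is the rank relation of target to participants:
all participants strictly above the target gives *all-down*, all strictly
below gives *all-up*, anything else *bridging*. Exact ties are
measure-zero with continuous ratings; when one occurs the tied participant
counts as "not lower" (tie + lower participant is bridging, tie + higher is
all-down) and a warning is raised. Classification depends only on rating
order, so it is invariant under strictly monotone transforms — a property
the suite checks directly.

Feasibility is $f = \sum_i s_i - s_t$ on the standardized scale. All-down
and bridging events necessarily have $f > 0$ (some participant outranks the
target); only all-up events can have $f < 0$. Multi-target events are
classified and scored against the highest-rated target and flagged
(`multi_target`), a convention the single-target-shaped metrics require;
the flag lets downstream users exclude them.

## Model tables

Each event contributes one row per involved male per future offset
$\Delta t \in \{10, 20, \dots, 120\}$ days — twelve future time points —
while the male remains resident. The response is the raw Elo rating at the
future date. The day-0 rating enters only as the "current rank" control:
with min–max standardized responses the bounds would move with group
composition, whereas raw ratings keep the response scale stable (a
standardized-response variant would be a one-line change in
`build_rank_dataset()`). Day 0 itself is never a response row; treating the
event day as both baseline and outcome would make the current-rank control
circular.

Numeric predictors are z-scored *on the assembled table* (mean 0, SD 1,
checked to $10^{-10}$), so model predictions at 0 are predictions at the
sample mean — the convention the prediction figures rely on.

Controls:

* **Hierarchy stability** (`stability_index()`): over a window (default 30
  days) ending at the reference date, one minus the mean, across
  consecutive day-pairs, of the fraction of male dyads whose ordinal rank
  order flips. 1 means frozen ranks; 0 means complete daily reversal. The
  index the original field literature uses is defined in material not
  restated here; this inversion-count definition lives on the same
  $[0, 1]$ scale, is transparent and testable (a brute-force recount
  oracle verifies it), and sits behind its own function so a weighted
  variant can be swapped in.
* **Male competition** (`competition_index()`): the co-resident adult male
  headcount — the simplest defensible reading; a males-per-fertile-female
  variant would need female data the schema does not carry.
* **Aggression rate** (`aggression_rate()`): focal events per focal hour
  over the window; zero effort yields a flagged missing value, never a
  zero rate.
* **Autocorrelation term** (`add_autocorrelation_term()`): a two-pass
  construction — fit the model once, then give each row the weighted mean
  of the same male's residuals at the other offsets of the same event,
  weights $\propto 1/(1 + |\Delta t_i - \Delta t_j|/10)$. The exact term
  used in the motivating analysis is unspecified, so the term is optional
  (`autocorrelation` in `pipeline_config()`); the pipeline default enables
  it.

The paternity table has one row per candidate male × infant; candidates are
the males present on at least one day of the 11-day window centred on the
estimated conception date, and their rating is the mean of daily
standardized ratings over the days present. Conception events are analysed
individually — aggregating into time blocks would blur a hierarchy this
dynamic.

## Inference

Both mixed models are fitted with `lme4`, by maximum likelihood whenever a
likelihood-ratio test is involved (REML only for variance-component
reporting). The rank model's fixed effects comprise
role × configuration × feasibility (with all lower-order terms),
role × time-distance, and the controls; the informed null keeps the
controls and the *identical* random structure and drops every term
containing a main predictor — a 13-df comparison under the default
specification. The random structure is crossed intercepts for male and
event with uncorrelated slopes for time distance (by male and by event) and
feasibility (by male); that set is the largest that stays identifiable at
the synthetic scale. When it is not identifiable (singular fit), slopes are
dropped in a documented order — feasibility-by-male, then
time-by-event, then time-by-male — and `rank_lrt()` forces the null onto
whatever structure the full model settled on, preserving nesting. The
reduction is recorded on the fit object.

The LRT statistic is $2\,\Delta\ell$ floored at zero with df equal to the
difference in fixed-effect parameter counts (verified in tests against an
independent design-matrix column count); comparing a model with itself is
allowed and returns $\chi^2 = 0$, $p = 1$.

The paternity model is a binomial GLMM of the per-candidate sire indicator
on the window-mean standardized rating — the raw $[0, 1]$ scale, so the
slope is log-odds per unit standardized rating — with a male random
intercept, maximized with adaptive Gauss–Hermite quadrature (10 nodes by
default; tests verify the likelihood against direct numerical integration
to $10^{-3}$ on a three-male toy). Absolute fixed-effect estimates above
15 log-odds trigger a complete-separation error rather than a silently
absurd fit.

Bootstrap bands are parametric: simulate responses from the fitted model,
refit, predict at the population level (random effects zero, z-scored
covariates at 0, factors at reference). Failed refits are dropped and
counted; more than 20% failing is an error. Percentile bands from
maximum-likelihood fits undercover mildly at small group counts (ML
variance components are biased low); the coverage test therefore asserts
substantial-majority coverage rather than exact 95%, and users wanting
calibrated bands should increase group counts or use REML variance inputs.

## The synthetic-data generator

The generator is first-class, tested code, and its defaults *are* the
study conditions every recovery check runs under:

* **Population**: 2 groups × 12 adult males (within the plausible 7–18
  band), 730 study days, per-male daily emigration probability 0.001 with
  each exit paired to a new identity's entry (headcount constant; no
  return migration — a simplification), entry ages uniform on 8–20 years.
* **Latent strength**: per-male baseline $\sim N(0, 1)$ plus a stationary
  AR(1) drift (coefficient 0.97, stationary SD 0.3), in dimensionless
  strength units. Latent strength is the generative truth; Elo ratings are
  downstream *estimates* of it, so recovery tests compare against injected
  effects, never against latent strength directly.
* **Contests**: each co-resident dyad interacts with probability 0.15 per
  day; the winner is drawn with probability
  $\mathrm{logistic}((s_i - s_j)/\tau)$, $\tau = 0.5$. These values give a
  clear but imperfect hierarchy — adjacent males upset each other
  regularly — and interaction volumes comparable to intensive field
  observation of a despotic macaque.
* **Coalitions**: events at 0.08 per group-day (≈ 115 events in two
  years); configuration drawn from the 0.6875 / 0.1875 / 0.125
  all-down / bridging / all-up mixture; participant count from a truncated
  geometric on $\{2..6\}$ with mean ≈ 2.2 (the printed mean/median/range
  pin down no distribution, so the simplest monotone one is used); one
  target per event. Members are selected by the *current rating order* of
  a running Elo maintained inside the generator, so the drawn
  configuration is exactly what a downstream analysis reclassifies from
  ratings. From the event day the target's strength drops by
  $\delta_T \cdot g(f)$ and each participant's rises by $\delta_P$
  (defaults 1.0 and 0.5 strength units), decaying linearly to zero over
  120 days; $g(f) = \max(0, 1 + 0.5 f)$ for all-up events makes target
  damage increase with feasibility, $g = 1$ otherwise. Contest outcomes
  after an event are re-drawn under the perturbed strengths — that is the
  only channel through which injected effects reach the observable record,
  exactly as rank consequences reach field data through subsequent
  contests.
* **Conceptions**: 19 conception events; candidates are the males present
  during the 11-day window; per-candidate sire indicators are independent
  Bernoulli with logit $\alpha + \beta s + b_{male}$
  ($\beta = 1.43$, $\alpha = -3$ giving about one sire per infant,
  $b_{male} \sim N(0, 0.2^2)$). A single-sire constraint is deliberately
  *not* imposed: the fitted model is an unconditional binomial GLMM, and
  conditioning the generator on exactly one sire would turn it into a
  conditional-logit process whose slope the GLMM would not recover
  unbiasedly. The cost is that a synthetic infant can have zero or two
  "sires"; the summary table records the first.

Determinism: every stage takes an integer seed, and stage seeds derive from
a master seed through a polynomial rolling hash, so a fixed seed reproduces
every table byte for byte.

What the generator does **not** emulate: female behaviour and reproductive
state, kin structure, observation error in outcome recording, undecided
contests, seasonal variation, or strategic partner choice. Passing
recovery tests therefore show that *if* rank consequences and
rank-dependent siring of the assumed forms exist, the pipeline detects and
quantifies them — not that real crested macaque data satisfy those forms.

## Problem sizes and numerical notes

* The recovery and property checks run on: one default-scale study (two
  years, ≈ 100–120 events) for sign-and-decay and feasibility properties;
  a 600-day, zero-injection study (> 300 events) for the null-injection
  and mixture-realization checks; 500 null simulations at the 128-event /
  28-male scale (intercept-only random structure, for per-fit speed) for
  LRT type-I calibration; and 200 replicate cohorts for paternity-slope
  recovery. These sizes were chosen to match the scale of the motivating
  study while keeping each check self-contained.
* With 19 conceptions × 12 candidates per cohort, the ML/quadrature
  logistic slope has a small upward finite-sample bias (on the order of
  5% at a true slope of 1.43) — a well-known property of logistic ML with
  few events, not a defect of the fitting routine; the recovery study
  reports the raw mean, so its expectation sits slightly above the
  generating value.
* Events drawn on days where the group's ratings are still completely
  undifferentiated (before any contest) are skipped — no rank order
  exists to select members by.
* `configuration_share_table()` rounds percentages half away from zero, so
  a 12.5% share prints as 13 and descriptive tables match printed-style
  percentages.
* Tied ratings in classification warn and resolve as described above;
  degenerate standardization (fewer than two males, or all ratings equal)
  is an error, not a silent `NaN`.

## Known limitations

* The stability and competition indices are transparent stand-ins on the
  documented scales, not reconstructions of unpublished formulas.
* The full model's fixed-effect set yields a 13-df full-vs-null
  comparison; richer published specifications (more interactions among
  controls) would change the df, and `rank_model_spec()` exposes the terms
  for that reason.
* Whether real analyses of this kind include coalitionary aggression as a
  rating input is often unstated; the default here excludes it, and a
  sensitivity path would add the events as participant-versus-target wins.
* The bootstrap is parametric; resampling events or males would be
  alternatives when model misspecification is the worry.
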