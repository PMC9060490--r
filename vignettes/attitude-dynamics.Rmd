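---
title: "Modelling the dynamics of vaccination attitudes in panel surveys"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling the dynamics of vaccination attitudes in panel surveys}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vaxpanel)
library(dplyr)
```

## The problem

Cross-sectional surveys of vaccination attitudes invite a static
reading: if 17% of respondents oppose voluntary vaccination at any one
time, one is tempted to treat 17% of the population as "the opponents".
A multi-wave panel breaks that reading. Following the same respondents
across waves shows opposition to be fluid — many respondents who oppose
vaccination in one wave are undecided or willing in the next — so the
set of opponents at any moment is much larger than the set of people
who oppose vaccination *persistently*. `vaxpanel` implements the full
analytical chain for such data: a consistency taxonomy over attitude
trajectories, a Markov model of attitude switching with its long-run
equilibrium, a measurement-error model that bounds how much persistent
opposition could be hiding behind noisy responses, crowding-out
tabulations contrasting voluntary with mandated regimes, and
regressions asking who the persistent opponents are.

Attitudes are measured per wave on a five-point Likert scale, 0 ("not
agree at all") to 4 ("fully agree"), separately for *voluntary* and
*mandated* (enforced) vaccination. Levels 0–1 are collapsed to
`opposed`, 2 to `undecided`, 3–4 to `willing`.

## The panel data model

A panel is a long-format table, one row per respondent × wave:
`id`, `wave`, `vol_likert`, `man_likert`, `vax_status`
(`unvaccinated`/`once`/`twice`, non-decreasing over waves), plus
arbitrary covariate columns. Respondents vaccinated twice at a wave
carry missing attitude levels there — they were no longer asked.
Missing values are empty cells, never sentinel codes. `read_panel()`
takes a column map, so deposited data with foreign headers loads
without editing the file.

Two policies exist for the vaccinated-twice, and the right one depends
on the analysis. For population shares (the willing slice of a wave,
uptake predictions) they count as willing: being fully vaccinated is
the strongest expression of willingness. For switching tables and
transition estimation they are excluded, since no stated attitude was
observed. Both are explicit `vaccinated =` arguments with defaults
matching the respective analysis. Respondents vaccinated once keep
their stated levels — the data give no reason to overrule a stated
attitude.

## Consistency and switching

`classify_consistency()` labels a complete trajectory
`consistently_opposed` / `consistently_undecided` /
`consistently_willing` when the collapsed category is identical in
every wave, and `inconsistent` otherwise; the classes are exhaustive
and mutually exclusive. `consistency_shares()` adds the per-wave
opposed shares and their unweighted mean — the "average cross-section"
figure that a static reading would quote. The mean is taken over the
panel's own waves (not over any larger refreshment cross-sections); the
per-wave shares are reported so either convention can be formed.

`switching_table()` conditions on a category at one wave and tabulates
the destination categories at another. Destination counts always sum
to the origin count, and population-normalised shares decompose the
conditioning share exactly — an identity the code asserts on raw
counts, not on rounded percentages.

## The Markov model and its equilibrium

`estimate_transitions()` computes the maximum-likelihood row-stochastic
matrix over the five Likert states (or the three collapsed ones):
`P[i, j]` is the observed fraction of respondents moving from state
`i` to state `j` between the two waves. Unobserved origin states get a
flagged self-loop row by default (a uniform row, and Laplace
`alpha`-smoothing, are available; the default imputes no movement
rather than inventing churn). `stationary_distribution()` solves
`πP = π, Σπ = 1` by replacing one balance equation with the
normalisation constraint — exact linear algebra, tolerance 1e-10 on
the residual — and cross-checks against power iteration from the
uniform start (up to 1e6 iterations). Reducible chains with more than
one closed communicating class (the identity matrix is the extreme
case) have no unique stationary vector; the solver detects the closed
classes by Boolean transitive closure and refuses with a diagnostic
naming them.

The stationary distribution is a thought experiment, not a forecast:
it answers "where would the population settle if today's switching
rates persisted?". `project_chain()` makes the transient path to that
equilibrium explicit. Uncertainty is offered by respondent-level
bootstrap (`bootstrap_stationary()`) rather than delta-method
intervals, because resampling whole respondents is the resampling unit
the panel defines.

A structural property worth stating: holding the other rows fixed,
increasing the opposed-to-willing switching rate weakly decreases the
stationary opposed share. With much traffic out of opposition and
little into it, the long-run opposed fraction is necessarily small —
the test suite checks this monotonicity numerically on a grid.

## The random-misreport model

Could the small consistently-opposed share be an artefact of noisy
responding rather than genuine attitude change? The misreport model
makes the most hostile version of that hypothesis precise: suppose
attitudes never change, but with probability μ a respondent picks one
of the K = 5 Likert items uniformly at random. A random pick lands in
the opposed set (m = 2 of 5 levels) with probability m/K = 0.4. Then a
truly opposed respondent records opposition in one wave with
probability 1 − 0.6μ, and anyone else with probability 0.4μ. Two
observed moments — the consistent-opposed share c over W = 3 waves and
the mean single-wave opposed share a — give two equations in the true
invariant opposed fraction x and the error rate μ:

    x (1 − 0.6 μ)^3 + (1 − x)(0.4 μ)^3 = c
    x (1 − 0.6 μ)   + (1 − x) 0.4 μ    = a

`solve_error_model()` eliminates x through the linear second equation
(x = (a − 0.4μ)/(1 − μ), μ < 1), scans the residual of the cubic first
equation on a 1e5-point grid in μ ∈ [0, 1 − 1e-9], and refines each
sign change by bisection to a 1e-12 residual. All admissible roots in
the unit square are returned; if several exist the reported primary
solution is the smallest-μ root — the most conservative attribution of
response error — with an explicit ambiguity flag (across the interior
of the unit square the forward–inverse round-trip tests find the root
to be unique in practice). μ = 1 is excluded because x is undefined
there. The geometry generalises: `error_model_spec(K, m, waves)`
replaces the 0.4/0.6 constants by m/K and 1 − m/K.

Because the model attributes *all* change to noise, the solved x is an
upper bound on hard-core opposition, and the package's print method
says so. With the observed voluntary-regime shares c = 0.033 and
a = 0.169 the system solves to x ≈ 0.059, μ ≈ 0.322; with the
enforced-regime shares c = 0.165, a = 0.332 it gives x ≈ 0.302,
μ ≈ 0.307. `simulate_error_model_population()` forward-simulates the
same measurement process so the closed forms and the solver can be
checked against Monte-Carlo frequencies.

## Crowding-out and the naive uptake prediction

`crowding_table()` cross-tabulates, within one wave, the mandated-regime
response of respondents in a given voluntary-regime category: would the
undecided-if-voluntary become willing or opposed if vaccination were
enforced? The net attitude effect is the share becoming willing minus
the share becoming opposed. Shares default to the full-wave denominator
so the decomposition identity holds against the conditioning category's
population share. `naive_uptake_prediction()` is the static forecast:
the willing (levels 3–4) plus the already fully vaccinated, as a share
of the wave.

## Regressions: who are the persistent opponents?

`fit_attitude_model()` predicts either consistent opposition or the
move from opposition (wave 2) to willingness (wave 3), by
maximum-likelihood logit or a least-squares linear probability model.
Numeric predictors are standardised with the sample SD (n − 1);
categorical predictors enter as treatment-coded indicators,
unstandardised. Intervals are 95% Wald. Goodness of fit is Tjur's
coefficient of discrimination — the mean predicted probability among
observed positives minus that among observed negatives — which for a
linear probability model with intercept equals the fraction of
variance explained exactly (asserted to 1e-10 in the tests). The
pseudo-R² reported alongside logits is McFadden's.
`compare_attitude_models()` fits the full
(sociodemographics + beliefs) and sociodemographics-only models on the
identical estimation sample, enforced by construction, and reports
both Tjur values and their difference: the explanatory power of
beliefs over and above sociodemographics. Belief *changes* enter as
wave-3 minus wave-2 differences when requested.

## The synthetic-panel generator

`simulate_panel()` exists so every stage is testable against known
ground truth without any deposited microdata. Each respondent's latent
voluntary and mandated Likert trajectories follow first-order Markov
chains; observed responses equal the latent state except that, with
probability `misreport_rate`, they are replaced by a uniform draw over
the five levels — independently per wave and per regime by default,
with a `misreport_shared` switch coupling the two regimes' draws
(which of the two the misreport mechanism "really" is cannot be
settled from aggregates, so both are exposed). Respondents latently
willing at the final wave are vaccinated twice with
`uptake_probability`, and their final-wave attitude responses are then
censored, reproducing the ask-only-the-unvaccinated structure.
Covariate-dependent switching uses a multinomial-logit link: the log
of the baseline row is shifted by covariate-scaled coefficient
vectors and re-normalised. The mandated chain can be coupled to the
voluntary one (`regime_coupling`, `regime_offset`), defaulting to
independent chains.

The defaults describe a 2,018-respondent, three-wave panel in which
voluntary-regime opposition runs near 17% per wave but is fluid
(per-level stay probability 0.25 with strong upward drift), so only
about 3% stay opposed in all three waves; mandated-regime opposition
is larger (roughly a third per wave) and much stickier (stay 0.85),
leaving about 15% consistently opposed; and 90% of the finally willing
are vaccinated twice, putting the naive uptake prediction near 0.7.
These values were fixed once, as the realistic operating point for the
setting the package addresses, and the tests treat them as given.

What the generator does *not* emulate: panel attrition and refreshment
samples, post-stratification weights, item-specific response styles
(e.g. extreme-response bias), within-household clustering, or any
realistic joint covariate distribution. Passing tests therefore
demonstrate correctness of the estimators under the model's own
assumptions — first-order dynamics, uniform misreports — not that real
attitude data satisfy those assumptions.

## Numerical choices and degenerate inputs

* Stationary solve: linear system, residual tolerance 1e-10; power
  iteration cross-check tolerance 1e-11, cap 1e6 iterations.
* Misreport solver: 1e5-point grid, bisection to residual 1e-12;
  roots closer than 1e-8 in μ collapsed as duplicates; inputs outside
  (0, 1) or with c > a rejected.
* Empty origin states: self-loop with a flag, never silently uniform.
* Single-class outcomes (all opposed or none) are errors, not NaNs, in
  both `tjur_r2()` and the model fitters; logit non-convergence
  (separation) is a diagnostic error.
* Identity chains raise an error from `stationary_distribution()`
  because every distribution is stationary.
* All shares carry their integer counts; rounding happens only in
  print methods.

## Problem sizes used by the test suite

Deterministic identities are tested exactly. Stochastic recovery tests
use: transition-matrix recovery at 8,000 and 20,000 respondents;
misreport Monte-Carlo at 10^6 respondents; logit coefficient recovery
at 10,000; null-coverage at 25 replicates of 400. Joint 5×5 matrix
recovery is asserted with a Bonferroni-adjusted band holding the
per-comparison 3σ confidence across all 25 cells.

## Limitations

The Markov model is first-order and time-homogeneous within a wave
pair; the stationary distribution extrapolates a single pair's rates.
The misreport model is deliberately extreme (uniform misreports,
immutable true attitudes) and its solution is a bound, not an
estimate. Regression comparisons quantify association, not causal
effects of beliefs. None of the analyses apply survey weights; an
optional weight column is carried through the data model but all
reported defaults are unweighted.
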