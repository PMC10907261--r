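---
title: "Modeling the observational learning of empathy"
author: "empathylearn"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling the observational learning of empathy}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(empathylearn)
```

## The paradigm and the models

The package implements the computational machinery for an
observational-learning-of-empathy task. A participant first rates her own
feelings while watching painful and non-painful stimulation of a recipient
(baseline session, 18 painful + 12 non-painful trials). In the learning
session (4 blocks of 12 trials; 36 painful, 12 non-painful; one recipient
per two blocks) each trial has an observation phase — the participant
predicts, then sees, the empathy rating of a demonstrator — followed by a
self-rating phase in which she rates her own feelings. A generalization
session (new recipient, no demonstrator) mirrors the baseline. All ratings
live on a 0–100 scale.

The demonstrator is algorithmic: for painful trials her ratings are drawn
from a normal distribution centered on the participant's own baseline mean
shifted by +3 SD (high-empathy group) or −3 SD (low-empathy group) with
SD = 5, i.e. a ±15-point offset; non-painful trials are drawn around the
baseline non-painful mean without a shift. Draws are clipped to the scale
and rounded to integers (the SD checks in the tests use the pre-rounding
draws).

Two model layers describe the participant:

1. **Prediction layer.** Trial-wise predictions of the demonstrator's
   ratings follow a Rescorla–Wagner rule: `P[1] = p0`,
   `delta[t] = R[t] − P[t]`, `P[t+1] = P[t] + alpha * delta[t]`. The
   observational prediction error `delta[t]` is positive when the
   demonstrator rated more empathically than predicted.

2. **Empathy layer.** Empathy ratings on painful learning trials are a
   linear function of time-discounted cumulative prediction errors on top of
   the participant's baseline level `E0`:
   `E[t] = E0 + sum_of_weights * S(t)`, with
   `S(t) = sum_{tau <= t} gamma^(t − tau) * delta[tau]` restricted by sign.
   The candidate family nests three variants: a single weight on all errors
   (M1), separate weights for positive and negative errors (M2), and
   separate weight pairs for the first and second half of the learning
   session (M3, boundary at trial 24, where the recipient changes). `gamma`
   in [0, 1] sets the memory of the sum: 0 keeps only the latest error, 1
   weighs all equally. The trial-t error is included in `E[t]` because the
   observation phase precedes the self-rating phase within a trial.

The exact parameterization of the two simpler variants is a reconstruction:
the family is defined here as the natural ablations of the richest model
(drop the half split; then drop the sign split), with a single `gamma`
shared by signs and halves.

## Fitting and model comparison

Each model is fitted per participant by maximum a posteriori estimation
under an independent Gaussian likelihood of the observed ratings around the
model trajectory, minimizing the negative log posterior (LPP). Parameters
are optimized in an unconstrained space (logit transform for `alpha` and
`gamma`, log for the noise SDs) with multiple restarts; for the update
models the restarts include closed-form ridge solutions for the weights on
a coarse `gamma` grid, because the model is linear in the weights given the
discount. Priors are mildly regularizing: Beta(1.1, 1.1) on `alpha` and
`gamma`, Normal(0, 2) on weights, Normal(log 5, 1) on log noise SDs, and a
Normal(baseline mean, 10) prior on `p0`. `E0` is fixed to the participant's
mean baseline rating for painful videos rather than fitted; `p0` is a free
parameter with its prior centered on the same mean (the task gives the
participant no better anchor before the first observation).

Ratings are treated as continuous and unbounded inside the likelihood (no
truncation correction for the 0–100 scale); clipping applies only when the
simulator emits ratings. This is a documented simplification — it slightly
misprices trajectories that ride the scale limits.

Model evidence is approximated per fit by the Laplace approximation
(LAME): the log posterior at the mode plus `k/2 * log(2*pi)` minus half the
log determinant of the Hessian of the negative log posterior, the Hessian
computed by central finite differences (relative step 1e-4) in the
unconstrained space. A non-positive-definite Hessian is jittered and
flagged. Group-level comparison uses the random-effects variational
Dirichlet scheme with a uniform Dirichlet(1) prior; exceedance
probabilities are estimated from 1e5 Monte-Carlo draws of the fitted
Dirichlet. A fixed-effects comparison (summed log evidence, pairwise log
group Bayes factors) is provided as a diagnostic companion; the simple
(unprotected) exceedance probability is reported.

## The synthetic-data generator

Synthetic observers forward-run the two model layers with additive
Gaussian report noise (default SD 8 for both predictions and empathy
ratings; the fitting likelihood assumes exactly this observation model) and
clipping to the scale. Ground-truth sampling ranges for cohort studies are
`alpha ~ U(0.1, 0.7)`, `gamma ~ U(0.3, 0.95)`, active weights
`~ U(0.2, 1.0)` with the group-atypical sign fixed at 0 (high-group
observers weight positive, low-group observers negative errors), and
baseline levels `~ U(35, 65)`. Baseline ratings are drawn around the true
`E0`; the demonstrator algorithm is anchored to the *realized* baseline
means, as in the task. Generalization-session painful ratings persist at
the final learned empathy level, so the baseline-to-generalization change
score is causally coupled to the learning weights. Helping-time scores are
generated with their change coupled to the empathy change at a population
rank correlation of roughly 0.35, giving the correlation analyses a known
positive target.

One regime deserves emphasis. Because the Rescorla–Wagner learner
converges, prediction errors are transient: the discounted sum — and with
it the model's empathy trajectory — peaks within the first few trials and
then relaxes, unless learning is slow (small `alpha`, so errors stay
directional through the session) and the discount is memory-dominant
(`gamma` near 1, so earlier errors retain their weight and the sum
accumulates). Directed *within-session* empathy trends — rising in the
high group, falling in the low group, as the task produces empirically —
are a prediction of that slow-learning, memory-dominant corner only. The
direction-of-effect checks therefore simulate their cohorts with
`alpha ~ U(0.05, 0.15)`, `gamma ~ U(0.9, 0.98)`, weights `~ U(0.2, 0.8)`
and baseline levels `~ U(35, 55)` (headroom against the rating ceiling);
gradual empirical ramps in both predictions and ratings are themselves
evidence for exactly this regime. Outside it the learned change still
persists into the generalization session (the final empathy level carries
over), but the trial slope within the learning session is not
sign-determined.

What the generator does *not* emulate: habituation and drift, scale-use
idiosyncrasies (anchoring, rounding to multiples of 5), non-Gaussian and
heteroscedastic report noise, and any dependence of the learning rate on
block or recipient. Passing tests therefore validate the machinery under
its own assumptions, not the adequacy of those assumptions for real data.

## Recovery studies and their regimes

`recover_parameters()` simulates observers through the full pipeline
(including re-estimating prediction errors from noisy predictions) and
correlates true with recovered parameters; `recover_models()` simulates
cohorts from each generative regime and reports the cohort-level confusion
matrix and exceedance probabilities.

Recovery regimes are chosen so that each model's distinctive structure is
actually expressed in the data it generates — otherwise model recovery is
ill-posed:

* Report noise SDs are 5 in the recovery studies (the generator default of
  8 describes a somewhat noisier participant; 5 matches the scale of the
  demonstrator algorithm and the prior center of the fitted noise).
* The confusion study pairs positively-weighted observers with *neutral*
  (unshifted) demonstrators on an all-painful learning schedule. Under a
  shifted demonstrator, or with the low-rated non-painful trials
  interleaved in a single prediction series, painful-trial prediction
  errors are predominantly positive, so negative-error weights are never
  exercised and the single-weight and sign-split models become
  observationally equivalent.
* In the half-split regime the active influence is confined to the
  first-half weight (`w_active_second = c(0, 0)`): data generated with
  equal first- and second-half weights are literally sign-split data, and
  no method could attribute them to the half-split model. The first-half
  weight is also the one that empirically drives the overall empathy
  change.

With both halves active and drawn independently, the expected half
contrast (~0.27 on average) is frequently below the resolution that 18
trials per half at noise SD 5 afford, and the half-split model's evidence
advantage disappears for a sizable minority of subjects; the vignette
states this openly because it bounds what the selection machinery can do.

## Problem sizes and numerical choices

The shipped tests run the recovery studies at the study's own scale — 10
cohorts of 26 participants for model recovery and 50 subjects for
parameter recovery — and smaller cohorts (6–20 participants) elsewhere;
each participant costs one Rescorla–Wagner fit and up to three update-model
fits, well under a second together. Ten optimization restarts per fit are
the default; reduced counts are used in unit tests where only
qualitative behavior is asserted. Ties in the exceedance Monte-Carlo are
broken toward the first model (they occur with probability zero for
continuous draws). Degenerate inputs are handled explicitly: constant
prediction series flag the learning rate as unidentifiable, an absent PE
sign flags the corresponding weight as prior-dominated, and zero-variance
change scores flag correlations as undefined rather than returning a
number.

## Model-independent statistics

The behavioral checks deliberately replace linear mixed models with
per-participant OLS slopes plus group contrasts (Welch t tests), and a
pooled PE-to-change regression with participant-clustered robust standard
errors. This preserves directions and group contrasts while keeping every
participant's contribution transparent; p-values are not exchangeable with
those of a random-intercept mixed model, and an external mixed-model pass
can be applied to the tidy trial CSV if needed. The trial-wise empathy
change is defined between consecutive painful trials, aligned with the
prediction error of the later trial.

## Known limitations

* Evidence is Laplace-approximated, not sampled; strongly non-Gaussian
  posteriors (e.g. `gamma` pinned at a boundary) are approximated through
  the transform and flagged only via the Hessian check.
* The exceedance probability is unprotected; a Bayes-omnibus-risk
  correction is a possible extension.
* Only painful-trial empathy ratings are modeled by default; non-painful
  trials can be included with a flag but the demonstrator manipulation does
  not target them.
* The Rescorla–Wagner prediction series runs, by default, as a single
  process over painful and non-painful trials in presentation order (the
  demonstrator rates both). This has a consequence worth knowing: because
  non-painful demonstrator ratings sit far below painful ones, the single
  prediction state is dragged between the two levels, and painful-trial
  prediction errors come out predominantly positive in *both* groups under
  the published mixed schedule — the low-empathy group then receives
  little of its negative learning signal. Simulations that need directed
  negative signals should either use an all-painful learning schedule
  (`trial_schedule_spec(pain_per_block = 12)`, as the model-recovery
  confusion study does) or the `prediction_series = "painful_only"` option
  (as the direction-of-effect checks do), which tracks painful trials
  alone and anchors non-painful predictions at the baseline non-painful
  mean (defensible because the pain-intensity cue precedes each
  prediction).

## A short end-to-end run

```{r example, eval = FALSE}
config <- default_run_config(seed = 1)
config$cohort$n_per_group <- 5   # keep the vignette light
res <- run_all(config)
res$selection$random_effects
res$stats$report
```
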