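# empathylearn

Computational modeling of the **observational learning of empathy**: how a
person's empathy for another's pain shifts after watching a demonstrator
react more (or less) empathically than expected.

The package is aimed at behavioral/computational researchers who want to
(i) simulate the three-session observational-learning-of-empathy paradigm
with fully known ground truth, (ii) fit its two model layers to trial-wise
data, (iii) compare candidate models at the group level, and (iv) verify
the whole machinery by parameter- and model-recovery studies.

## The models

**Prediction layer.** During learning, the participant predicts the
demonstrator's empathy rating on each painful trial. Predictions follow a
Rescorla–Wagner rule

    P[1]    = p0
    d[t]    = R[t] - P[t]            (observational prediction error)
    P[t+1]  = P[t] + alpha * d[t]

where `R[t]` is the demonstrator's rating and `alpha` the learning rate.
`d[t] > 0` means the demonstrator was more empathic than expected.

**Empathy layer.** The participant's own empathy ratings on painful trials
are a linear function of time-discounted cumulative prediction errors on
top of the baseline level `E0` (the mean baseline rating for painful
videos):

    S_sign(t) = sum_{tau <= t} gamma^(t - tau) * d[tau]   (sign-restricted)
    E[t]      = E0 + W * S(t)

The candidate family nests three variants: one weight on all errors (M1),
separate weights for positive and negative errors (M2), and separate
weight pairs for the first and second half of the learning session (M3,
the family's richest member). `gamma` in [0, 1] sets the memory of the
sum: 0 keeps only the latest error, 1 weighs all errors equally.

Each model is fitted per participant by MAP (minimizing the negative log
posterior, LPP) under a Gaussian likelihood, model evidence is
approximated per fit by the Laplace approximation (LAME), and group-level
comparison uses random-effects Bayesian model selection with exceedance
probabilities (XP). Model-independent checks (learning-trend contrasts, a
participant-clustered PE-to-empathy-change regression, and the
empathy-change vs. helping-time Spearman correlation) are included.

The demonstrator is algorithmic: painful-trial ratings are drawn from
Normal(baseline mean ± 3·5, SD 5) for the high/low-empathy group and
non-painful ratings from Normal(baseline non-painful mean, SD 5), clipped
to the 0–100 scale and rounded.

## Worked example

Simulate a small cohort whose empathy updating follows the
sign-/half-split model (influence confined to the first-half weight), fit
all three candidates to every participant, and ask which model the group
evidence favors:

```r
library(empathylearn)

config <- default_run_config(seed = 1)
config$cohort$n_per_group <- 5          # 5 high + 5 low participants
config$priors$pred_noise_sd <- 5
config$priors$empathy_noise_sd <- 5
config$priors$w_active_second <- c(0, 0)

res <- run_all(config)
res$selection$random_effects
#> Random-effects Bayesian model selection
#>                        M1_single M2_signsplit M3_signsplit_halfsplit
#> expected frequency        0.1190       0.1922                 0.6888
#> exceedance probability    0.0053       0.0198                 0.9748
```

The generating model (M3) wins with exceedance probability 0.97: the
probability that the half-split model is the most frequent
data-generating model in this cohort. Supporting numbers from the same
run:

```r
mean(res$fit$rw_params$alpha)           #> 0.376  (mean fitted learning rate)
res$stats$pe_regression$slope           #> 0.11   (PE -> empathy-change slope)
res$stats$helping$overall$rho           #> 0.6    (empathy change vs helping)
```

A positive pooled slope means trials on which the demonstrator rated
higher than predicted are followed by upward shifts in the participant's
own empathy rating; the Spearman rho links each participant's
baseline-to-generalization empathy change to the change in time they are
willing to spend helping the recipient.

Recovery harnesses are one call each:

```r
recover_parameters(n_subjects = 50, seed = 5)$correlations
recover_models(n_cohorts = 3, n_per_cohort = 12, seed = 21)$confusion
```

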