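# Shared fixtures built in code: small observers, participants and cohorts
# used across the unit tests. Reduced restart counts keep individual tests
# fast; the full defaults are exercised in the acceptance suite.

quick_observer <- function(group = "high", alpha = 0.4, gamma = 0.8,
                           w1_pos = 0.6, w1_neg = 0, w2_pos = 0.3,
                           w2_neg = 0, noise = 5, ...) {
  ground_truth_observer(alpha = alpha, p0 = 50, gamma = gamma,
                        empathy_t0 = 50, w1_pos = w1_pos, w1_neg = w1_neg,
                        w2_pos = w2_pos, w2_neg = w2_neg,
                        pred_noise_sd = noise, empathy_noise_sd = noise,
                        group = group, ...)
}

quick_participant <- function(seed = 1, ...) {
  simulate_participant(quick_observer(...), seed = seed)
}

quick_priors <- function(noise = 5) {
  observer_priors(pred_noise_sd = noise, empathy_noise_sd = noise)
}

# slow-learning, memory-dominant regime: prediction errors stay directional
# through the session only when learning is gradual (small alpha) and
# earlier errors retain their weight (gamma near 1); only then does the
# model imply directed within-session empathy trends
direction_priors <- function(noise = 5) {
  observer_priors(alpha = c(0.05, 0.15), gamma = c(0.9, 0.98),
                  w_active = c(0.2, 0.8), level = c(35, 55),
                  pred_noise_sd = noise, empathy_noise_sd = noise)
}

# schedule with many painful learning trials, for Monte-Carlo draws
big_pain_schedule <- function(n_blocks = 1000, seed = 1) {
  generate_schedule(trial_schedule_spec(
    n_learning_blocks = n_blocks, trials_per_block = 10, pain_per_block = 10,
    n_recipients_learning = 2, seed = seed))
}

# brute-force discounted sum, independent of the package recursion
loop_discounted_sum <- function(pe, gamma, t, sign) {
  keep <- switch(sign,
                 all = rep(TRUE, length(pe)),
                 pos = pe > 0,
                 neg = pe < 0)
  sum(gamma^(t - seq_len(t)) * ifelse(keep, pe, 0)[seq_len(t)])
}
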