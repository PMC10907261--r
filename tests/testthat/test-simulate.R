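test_that("null observer emits empathy_t0 on every painful learning trial", {
  obs <- quick_observer(w1_pos = 0, w2_pos = 0, noise = 5)
  obs$empathy_noise_sd <- 0
  pd <- simulate_participant(obs, seed = 2)
  learn_pain <- pd$trials$session == "learning" & pd$trials$pain == "painful"
  expect_true(all(pd$trials$empathy_rating[learn_pain] == obs$empathy_t0))
})

test_that("full updating (alpha = 1, no noise) copies the last rating forward", {
  obs <- quick_observer(alpha = 1)
  obs$pred_noise_sd <- 0
  pd <- simulate_participant(obs, seed = 3)
  learn <- pd$trials[pd$trials$session == "learning", ]
  expect_equal(learn$prediction[-1], learn$demonstrator_rating[-nrow(learn)])
  # painful-only series: the copy happens within the painful subsequence
  pd2 <- simulate_participant(obs, seed = 3, prediction_series = "painful_only")
  lp <- pd2$trials[pd2$trials$session == "learning" &
                     pd2$trials$pain == "painful", ]
  expect_equal(lp$prediction[-1], lp$demonstrator_rating[-nrow(lp)])
})

test_that("positive first-half weight raises learning empathy above baseline", {
  # high-group demonstrators sit ~15 points above baseline, so positive PEs
  # dominate and a positive weight must push mean learning empathy upwards
  wins <- 0L
  for (s in 1:20) {
    pd <- quick_participant(seed = s)
    learn_pain <- pd$trials$session == "learning" & pd$trials$pain == "painful"
    wins <- wins + (mean(pd$trials$empathy_rating[learn_pain]) > 50)
  }
  expect_gte(wins, 18L)
})

test_that("no emitted rating leaves the 0-100 scale for extreme parameters", {
  for (s in 1:5) {
    obs <- ground_truth_observer(alpha = 0.9, p0 = 95, gamma = 1,
                                 empathy_t0 = 90, w1_pos = 3, w2_pos = 3,
                                 pred_noise_sd = 30, empathy_noise_sd = 30,
                                 group = "high")
    pd <- simulate_participant(obs, seed = s)
    vals <- unlist(pd$trials[, c("demonstrator_rating", "prediction",
                                 "empathy_rating")])
    expect_true(all(vals[!is.na(vals)] >= 0 & vals[!is.na(vals)] <= 100))
  }
})

test_that("ratings are present exactly where the session defines them", {
  pd <- quick_participant(seed = 4)
  tr <- pd$trials
  is_learn <- tr$session == "learning"
  expect_true(all(!is.na(tr$demonstrator_rating[is_learn])))
  expect_true(all(is.na(tr$demonstrator_rating[!is_learn])))
  expect_true(all(!is.na(tr$prediction[is_learn])))
  expect_true(all(is.na(tr$prediction[!is_learn])))
  expect_true(all(!is.na(tr$empathy_rating)))
})

test_that("cohorts have the requested composition and are seed-reproducible", {
  cohort <- simulate_cohort(n_per_group = 3, priors = quick_priors(),
                            seed = 7)
  expect_equal(nrow(cohort$participants), 6L)
  expect_equal(as.integer(table(cohort$participants$group)), c(3L, 3L))
  cohort2 <- simulate_cohort(n_per_group = 3, priors = quick_priors(),
                             seed = 7)
  expect_identical(cohort$trials, cohort2$trials)
  expect_identical(cohort$participants, cohort2$participants)
  cohort3 <- simulate_cohort(n_per_group = 3, priors = quick_priors(),
                             seed = 8)
  expect_false(identical(cohort$trials$empathy_rating,
                         cohort3$trials$empathy_rating))
})

test_that("zero-width priors share parameters but not noise draws", {
  pr <- observer_priors(alpha = c(0.4, 0.4), gamma = c(0.7, 0.7),
                        w_active = c(0.5, 0.5), level = c(50, 50))
  cohort <- simulate_cohort(n_per_group = 1, priors = pr, seed = 1)
  p <- cohort$participants
  expect_equal(p$alpha[1], p$alpha[2])
  expect_equal(p$gamma[1], p$gamma[2])
  tr <- split(cohort$trials$empathy_rating, cohort$trials$participant_id)
  expect_false(identical(tr[[1]], tr[[2]]))
})

test_that("high-group observers see larger average painful-trial PEs than low", {
  for (s in 1:5) {
    args <- list(alpha = 0.4, gamma = 0.8, w1_pos = 0.5, w2_pos = 0.3)
    hi <- simulate_participant(do.call(quick_observer, c(args, group = "high")),
                               seed = s)
    lo_obs <- do.call(quick_observer, c(args, group = "low"))
    lo_obs$w1_pos <- lo_obs$w2_pos <- 0
    lo_obs$w1_neg <- 0.5; lo_obs$w2_neg <- 0.3
    lo <- simulate_participant(lo_obs, seed = s)
    expect_gt(mean(hi$truth$pe_painful), mean(lo$truth$pe_painful))
  }
})

test_that("degenerate prior ranges are a configuration error", {
  expect_error(observer_priors(alpha = c(0.7, 0.1)), "lower <= upper")
  expect_error(simulate_cohort(n_per_group = 0), "positive")
})
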