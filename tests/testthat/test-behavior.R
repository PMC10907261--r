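test_that("per-participant slopes equal the closed-form OLS solution", {
  set.seed(61)
  ols_slope <- function(x, y) {
    sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)
  }
  for (i in 1:10) {
    y <- runif(36, 0, 100)
    x <- sort(sample(1:48, 36))
    trials <- data.frame(participant_id = c("A", "B"), group = c("g1", "g2"),
                         session = "learning", trial_index = rep(x, each = 2),
                         pain = "painful", prediction = NA_real_,
                         empathy_rating = NA_real_)
    trials <- trials[order(trials$participant_id), ]
    trials$empathy_rating <- c(y, y * 0.5 + 10)
    trials$trial_index <- c(x, x)
    # need >= 2 per group: add jittered copies so slopes are not constant
    t2 <- trials
    t2$participant_id <- paste0(t2$participant_id, "2")
    t2$empathy_rating <- pmin(100, pmax(0, t2$empathy_rating + rnorm(nrow(t2))))
    res <- fit_trends(rbind(trials, t2), "empathy")
    expect_equal(res$slopes$slope[res$slopes$participant_id == "A"],
                 ols_slope(x, y), tolerance = 1e-10)
  }
  # an exact line gives its slope exactly
  lin <- data.frame(participant_id = "L", group = "g1", session = "learning",
                    trial_index = 1:36, pain = "painful",
                    prediction = NA_real_,
                    empathy_rating = 10 + 0.5 * (1:36))
  lin2 <- lin; lin2$participant_id <- "L2"
  res <- fit_trends(rbind(lin, lin2), "empathy")
  expect_equal(res$slopes$slope, c(0.5, 0.5), tolerance = 1e-10)
})

test_that("trend statistics are invariant to participant ordering", {
  cohort <- simulate_cohort(n_per_group = 4, priors = quick_priors(), seed = 3)
  tr <- cohort$trials
  res1 <- fit_trends(tr, "empathy")
  set.seed(1)
  ids <- sample(unique(tr$participant_id))
  tr2 <- do.call(rbind, lapply(ids, function(id) tr[tr$participant_id == id, ]))
  res2 <- fit_trends(tr2, "empathy")
  expect_equal(sort(res1$slopes$slope), sort(res2$slopes$slope))
  expect_equal(res1$group_test$p.value, res2$group_test$p.value)
})

test_that("an absent series raises an explicit error", {
  cohort <- simulate_cohort(n_per_group = 2, priors = quick_priors(), seed = 4)
  tr <- cohort$trials
  tr$prediction <- NA_real_  # no-prediction design
  expect_error(fit_trends(tr, "prediction"), "absent")
  expect_s3_class(fit_trends(tr, "empathy"), "trend_result")
})

test_that("simulated groups show opposite empathy trends", {
  cohort <- simulate_cohort(n_per_group = 10, priors = direction_priors(),
                            seed = 8, prediction_series = "painful_only")
  res <- fit_trends(cohort$trials, "empathy")
  expect_gt(res$group_means[["high"]], 0)
  expect_lt(res$group_means[["low"]], 0)
})

test_that("zero-weight cohorts show no group trend difference", {
  pr <- observer_priors(w_active = c(0, 0), pred_noise_sd = 5,
                        empathy_noise_sd = 5)
  pvals <- sapply(1:3, function(s) {
    cohort <- simulate_cohort(n_per_group = 6, priors = pr, seed = 200 + s)
    fit_trends(cohort$trials, "empathy")$group_test$p.value
  })
  expect_true(all(pvals > 0.01))
})

test_that("PE-to-change regression recovers coupling, nulls and attenuation", {
  make_delta <- function(seed, halve = FALSE, study = "human") {
    pr <- quick_priors()
    if (halve) pr$w_active <- pr$w_active / 2
    cohort <- simulate_cohort(n_per_group = 6, priors = pr, seed = seed)
    pe_tables <- lapply(cohort$data, function(pd) {
      data.frame(trial_index = pd$truth$painful_trial_index,
                 pe = pd$truth$pe_painful)
    })
    names(pe_tables) <- sapply(cohort$data,
                               function(pd) pd$trials$participant_id[1])
    d <- pe_delta_table(cohort$trials, pe_tables)
    d$study <- study
    d$participant_id <- paste(study, d$participant_id)
    d
  }
  human <- make_delta(300)
  res <- pe_change_regression(human)
  expect_gt(res$slope, 0)
  expect_lt(res$p_value, 0.01)

  # zero weights: slope indistinguishable from zero
  pr0 <- observer_priors(w_active = c(0, 0), pred_noise_sd = 5,
                         empathy_noise_sd = 5)
  cohort0 <- simulate_cohort(n_per_group = 6, priors = pr0, seed = 301)
  pe0 <- lapply(cohort0$data, function(pd) {
    data.frame(trial_index = pd$truth$painful_trial_index,
               pe = pd$truth$pe_painful)
  })
  names(pe0) <- sapply(cohort0$data, function(pd) pd$trials$participant_id[1])
  res0 <- pe_change_regression(pe_delta_table(cohort0$trials, pe0))
  expect_lt(abs(res0$slope), 2 * res0$se)

  # computer demonstrators with halved weights attenuate the slope
  computer <- make_delta(302, halve = TRUE, study = "computer")
  both <- rbind(human, computer)
  both$study <- factor(both$study, levels = c("human", "computer"))
  res_i <- pe_change_regression(both, interaction = "study")
  expect_lt(res_i$interaction[1, "Estimate"], 0)
  expect_error(pe_change_regression(human[human$participant_id ==
                                            human$participant_id[1], ]),
               "2 participants")
})

test_that("empathy change vs helping correlation behaves at the extremes", {
  set.seed(70)
  n <- 20
  chg <- data.frame(participant_id = sprintf("P%02d", 1:n),
                    group = rep(c("high", "low"), each = n / 2),
                    empathy_change = rnorm(n, 0, 6))
  # monotone transform gives rho = 1
  chg$helping_change <- chg$empathy_change^3 / 50
  res <- change_vs_helping(chg)
  expect_equal(res$overall$rho, 1)
  # independent scores: permutation distribution centered at zero
  rhos <- replicate(200, {
    chg$helping_change <- sample(chg$helping_change)
    change_vs_helping(chg)$overall$rho
  })
  expect_lt(abs(mean(rhos)), 0.1)
  # zero variance flagged
  chg$helping_change <- 0
  expect_true(is.na(change_vs_helping(chg)$overall$rho))
  expect_error(change_vs_helping(chg[1:3, ]), "at least 5")
})

test_that("helping scores in simulated cohorts track empathy change", {
  # the generator couples helping change to empathy change around rho 0.35
  cohort <- simulate_cohort(n_per_group = 26, priors = quick_priors(),
                            seed = 90)
  chg <- change_scores_from_trials(cohort$trials)
  chg <- merge(chg, cohort$participants[, c("participant_id", "pre_helping",
                                            "post_helping")],
               by = "participant_id")
  chg$helping_change <- chg$post_helping - chg$pre_helping
  res <- change_vs_helping(chg)
  expect_gt(res$overall$rho, 0.1)
  expect_lt(res$overall$rho, 0.8)
})
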