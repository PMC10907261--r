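test_that("discounted sums match hand-computed values", {
  # delta = [10, -5], gamma = 0.5: at t = 2 the positive sum is 10 * 0.5,
  # the negative sum is just -5
  expect_equal(discounted_pe_sums(c(10, -5), 0.5, t = 2, sign = "pos"), 5)
  expect_equal(discounted_pe_sums(c(10, -5), 0.5, t = 2, sign = "neg"), -5)
  expect_equal(discounted_pe_sums(c(10, -5), 0.5, t = 2, sign = "all"), 0)
})

test_that("discount extremes keep only the last PE or weigh all equally", {
  pe <- c(4, -2, 0, 7, -9)
  expect_equal(discounted_pe_sums(pe, 0, sign = "all"), pe)
  expect_equal(discounted_pe_sums(pe, 1, t = 5, sign = "pos"), 11)
  expect_equal(discounted_pe_sums(pe, 1, t = 5, sign = "neg"), -11)
  expect_error(discounted_pe_sums(pe, 0.5, t = 6), "out of range")
})

test_that("discounted sums equal a brute-force loop on random series", {
  set.seed(77)
  for (i in 1:100) {
    pe <- rnorm(sample(5:40, 1), 0, 8)
    gamma <- runif(1)
    t <- sample(seq_along(pe), 1)
    for (sgn in c("all", "pos", "neg")) {
      expect_equal(discounted_pe_sums(pe, gamma, t = t, sign = sgn),
                   loop_discounted_sum(pe, gamma, t, sgn),
                   tolerance = 1e-12)
    }
  }
})

test_that("the sums satisfy the one-step recursion exactly", {
  set.seed(5)
  pe <- rnorm(30, 0, 6)
  for (gamma in c(0, 0.37, 1)) {
    for (sgn in c("pos", "neg", "all")) {
      s <- discounted_pe_sums(pe, gamma, sign = sgn)
      d <- switch(sgn, all = pe, pos = pmax(pe, 0), neg = pmin(pe, 0))
      expect_equal(s[-1], gamma * s[-length(s)] + d[-1], tolerance = 1e-12)
    }
  }
})

test_that("predict_empathy reproduces hand-worked trajectories", {
  spec <- update_model_spec("M3_signsplit_halfsplit", half_boundary = 24)
  params <- update_params(
    weights = c(W1_pos = 0.5, W1_neg = 0, W2_pos = 0, W2_neg = 0),
    gamma = 1, empathy_t0 = 50)
  expect_equal(predict_empathy(spec, params, c(10, 10), trial_index = c(1, 2)),
               c(55, 60))
  # all-zero weights leave the baseline untouched
  params0 <- update_params(
    weights = c(W1_pos = 0, W1_neg = 0, W2_pos = 0, W2_neg = 0),
    gamma = 0.5, empathy_t0 = 42)
  expect_equal(predict_empathy(spec, params0, rnorm(20)), rep(42, 20))
})

test_that("the models nest: M2 with equal weights is M1, M3 with equal halves is M2", {
  set.seed(12)
  pe <- rnorm(36, 0, 7)
  idx <- 1:36
  e1 <- predict_empathy(update_model_spec("M1_single"),
                        update_params(c(W = 0.4), 0.7, 50), pe, idx)
  e2 <- predict_empathy(update_model_spec("M2_signsplit"),
                        update_params(c(W_pos = 0.4, W_neg = 0.4), 0.7, 50),
                        pe, idx)
  e3 <- predict_empathy(update_model_spec("M3_signsplit_halfsplit"),
                        update_params(c(W1_pos = 0.4, W1_neg = 0.4,
                                        W2_pos = 0.4, W2_neg = 0.4), 0.7, 50),
                        pe, idx)
  expect_equal(e1, e2)
  expect_equal(e2, e3)
  expect_error(
    predict_empathy(update_model_spec("M1_single"),
                    update_params(c(W_pos = 1, W_neg = 1), 0.7, 50), pe, idx),
    "weight set")
})

test_that("noiseless model data are recovered to high accuracy", {
  set.seed(9)
  pe <- rnorm(36, 2, 8)
  idx <- seq(1, 47, length.out = 36)
  spec <- update_model_spec("M3_signsplit_halfsplit")
  true_par <- update_params(
    weights = c(W1_pos = 0.6, W1_neg = 0.2, W2_pos = 0.3, W2_neg = 0.5),
    gamma = 0.8, empathy_t0 = 50)
  y <- predict_empathy(spec, true_par, pe, idx)
  fit <- fit_update_model(y, pe, spec, update_priors(empathy_t0 = 50),
                          trial_index = idx, seed = 4)
  expect_equal(unname(fit$map_params$weights),
               unname(true_par$weights), tolerance = 1e-2)
  expect_equal(fit$map_params$gamma, 0.8, tolerance = 1e-2)
  expect_gt(fit$r2, 0.999)
})

test_that("first-half weight is recovered on average from noisy data", {
  set.seed(22)
  sched <- generate_schedule(trial_schedule_spec(seed = 22))
  spec <- update_model_spec("M3_signsplit_halfsplit")
  est <- replicate(25, {
    pe <- rnorm(36, 3, 8)
    idx <- sort(sample(1:48, 36))
    y <- predict_empathy(spec, update_params(
      weights = c(W1_pos = 0.6, W1_neg = 0, W2_pos = 0.3, W2_neg = 0),
      gamma = 0.8, empathy_t0 = 50), pe, idx) + rnorm(36, 0, 5)
    fit_update_model(y, pe, spec, update_priors(empathy_t0 = 50),
                     trial_index = idx, n_starts = 5,
                     seed = sample.int(1e6, 1))$map_params$weights[["W1_pos"]]
  })
  expect_lt(abs(mean(est) - 0.6), 0.15)
})

test_that("log likelihood at the MAP is monotone in model richness", {
  pd <- quick_participant(seed = 19)
  fp <- fit_participant(pd$trials, n_starts = 6, seed = 5)
  ll <- sapply(fp$updates, function(f) f$loglik)
  expect_true(ll[["M2_signsplit"]] >= ll[["M1_single"]] - 1e-6)
  expect_true(ll[["M3_signsplit_halfsplit"]] >= ll[["M2_signsplit"]] - 1e-6)
})

test_that("a missing PE sign flags the corresponding weight", {
  pe <- abs(rnorm(20, 5, 2))  # strictly positive
  y <- 50 + cumsum(pe) * 0.1
  fit <- fit_update_model(y, pe, update_model_spec("M2_signsplit"),
                          update_priors(empathy_t0 = 50), seed = 2,
                          n_starts = 4)
  expect_true("W_neg_unidentifiable" %in% fit$flags)
})

test_that("weight-change correlation behaves under coupling, nulls and ties", {
  set.seed(30)
  # heterogeneous true weights with low noise couple weight and change
  n <- 14
  fits <- vector("list", n)
  change <- numeric(n)
  for (i in seq_len(n)) {
    w <- runif(1, 0.1, 1.2)
    pe <- rnorm(36, 3, 8)
    idx <- sort(sample(1:48, 36))
    spec <- update_model_spec("M3_signsplit_halfsplit")
    y <- predict_empathy(spec, update_params(
      weights = c(W1_pos = w, W1_neg = 0, W2_pos = w / 2, W2_neg = 0),
      gamma = 0.8, empathy_t0 = 50), pe, idx) + rnorm(36, 0, 2)
    fits[[i]] <- fit_update_model(y, pe, spec, update_priors(empathy_t0 = 50),
                                  trial_index = idx, n_starts = 4, seed = i)
    change[i] <- mean(tail(y, 12)) - 50
  }
  wc <- weight_change_correlation(fits, change, group = "high")
  expect_gte(wc$rho, 0.5)
  # permuted change scores kill the association
  set.seed(31)
  rhos <- replicate(20, weight_change_correlation(
    fits, sample(change), group = "high")$rho)
  expect_lt(abs(mean(rhos)), 0.3)
  # degenerate inputs
  expect_error(weight_change_correlation(fits[1:3], change[1:3], "high"),
               "at least 5")
  wc0 <- weight_change_correlation(fits, rep(1, n), group = "high")
  expect_true(is.na(wc0$rho) && wc0$flag == "zero_variance")
})
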