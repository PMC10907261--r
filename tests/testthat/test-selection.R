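test_that("Laplace evidence matches numerical integration on a conjugate Gaussian", {
  # y_i ~ N(mu, s^2) with known s and a N(m0, t0^2) prior on mu: the log
  # marginal likelihood is available by 1-D quadrature, and the log
  # posterior is exactly quadratic so the Laplace approximation is exact
  set.seed(44)
  for (rep in 1:5) {
    n <- sample(5:30, 1)
    s <- runif(1, 2, 8); m0 <- runif(1, 30, 70); t0 <- runif(1, 3, 15)
    y <- rnorm(n, 50, s)
    logpost <- function(mu) {
      sum(dnorm(y, mu, s, log = TRUE)) + dnorm(mu, m0, t0, log = TRUE)
    }
    # analytic posterior mode
    prec <- n / s^2 + 1 / t0^2
    mu_hat <- (sum(y) / s^2 + m0 / t0^2) / prec
    H <- fd_hessian(function(th) -logpost(th[1]), mu_hat)
    lame <- laplace_evidence(logpost(mu_hat), mu_hat, H)
    scale <- logpost(mu_hat)
    oracle <- log(stats::integrate(
      function(mu) exp(sapply(mu, logpost) - scale),
      mu_hat - 10 * sqrt(1 / prec), mu_hat + 10 * sqrt(1 / prec))$value) + scale
    expect_lt(abs(as.numeric(lame) - oracle), 0.1)
  }
})

test_that("zero free parameters reduce the evidence to the log likelihood", {
  ll <- -123.45
  expect_equal(as.numeric(laplace_evidence(ll, numeric(0), matrix(0, 0, 0))), ll)
})

test_that("an irrelevant extra parameter pays an Occam penalty", {
  # a dummy parameter that never touches the likelihood changes the true
  # marginal likelihood by exactly zero (its proper prior integrates to 1,
  # and the Gaussian case makes the Laplace approximation exact) -- the
  # implementation must reproduce that identity
  set.seed(55)
  y0 <- rnorm(12, 50, 5)
  nlp1 <- function(th) {
    -sum(dnorm(y0, th[1], 5, log = TRUE)) - dnorm(th[1], 50, 10, log = TRUE)
  }
  nlp2 <- function(th) nlp1(th[1]) - dnorm(th[2], 0, 2, log = TRUE)
  f1 <- nlminb(50, nlp1)
  f2 <- nlminb(c(50, 0), nlp2)
  l1 <- laplace_evidence(-f1$objective, f1$par, fd_hessian(nlp1, f1$par))
  l2 <- laplace_evidence(-f2$objective, f2$par, fd_hessian(nlp2, f2$par))
  expect_equal(as.numeric(l2), as.numeric(l1), tolerance = 1e-4)

  # an irrelevant but data-informed parameter (a covariate unrelated to y)
  # narrows its posterior below the prior and pays a genuine complexity
  # penalty: mean LAME strictly lower across 50 synthetic fits
  gap <- numeric(50)
  for (i in 1:50) {
    y <- rnorm(12, 50, 5)
    x <- rnorm(12, 0, 3)
    nlpa <- function(th) {
      -sum(dnorm(y, th[1], 5, log = TRUE)) - dnorm(th[1], 50, 10, log = TRUE)
    }
    nlpb <- function(th) {
      -sum(dnorm(y, th[1] + th[2] * x, 5, log = TRUE)) -
        dnorm(th[1], 50, 10, log = TRUE) - dnorm(th[2], 0, 2, log = TRUE)
    }
    fa <- nlminb(50, nlpa)
    fb <- nlminb(c(50, 0), nlpb)
    la <- laplace_evidence(-fa$objective, fa$par, fd_hessian(nlpa, fa$par))
    lb <- laplace_evidence(-fb$objective, fb$par, fd_hessian(nlpb, fb$par))
    gap[i] <- as.numeric(lb) - as.numeric(la)
  }
  expect_lt(mean(gap), 0)
  expect_gte(mean(gap < 0), 0.7)  # chance fit gains flip a minority of cases
})

test_that("a non-positive-definite Hessian is regularized with a warning", {
  H <- diag(c(1, -0.5))
  expect_warning(ev <- laplace_evidence(-10, c(0, 0), H), "positive definite")
  expect_true(is.finite(as.numeric(ev)))
  expect_true(attr(ev, "regularized"))
})

test_that("BMS is symmetric under equal evidence and certain under strong evidence", {
  lme_eq <- matrix(-100, nrow = 26, ncol = 2,
                   dimnames = list(NULL, c("A", "B")))
  bms <- bms_random_effects(lme_eq, n_samples = 1e5, seed = 3)
  expect_equal(unname(bms$exceedance_probability[["A"]]), 0.5,
               tolerance = 0.04)
  expect_equal(sum(bms$exceedance_probability), 1, tolerance = 1e-9)
  expect_equal(sum(bms$expected_frequencies), 1, tolerance = 1e-9)

  lme_strong <- cbind(A = rep(-100, 26), B = rep(-110, 26))
  bms2 <- bms_random_effects(lme_strong, n_samples = 1e5, seed = 3)
  expect_gte(bms2$exceedance_probability[["A"]], 0.999)
})

test_that("two-model exceedance matches the analytic Dirichlet tail", {
  # for K = 2 the XP is P(x > 0.5) under Beta(alpha1, alpha2): compare the
  # Monte-Carlo estimate against pbeta
  set.seed(6)
  lme <- cbind(A = rnorm(15, -100, 3), B = rnorm(15, -101, 3))
  bms <- bms_random_effects(lme, n_samples = 2e5, seed = 11)
  a <- bms$dirichlet_alpha
  analytic <- 1 - stats::pbeta(0.5, a[["A"]], a[["B"]])
  expect_equal(unname(bms$exceedance_probability[["A"]]), analytic,
               tolerance = 0.01)
})

test_that("XP is invariant to per-participant constants and reproducible", {
  set.seed(10)
  lme <- matrix(rnorm(26 * 3, -120, 4), 26, 3,
                dimnames = list(NULL, c("M1", "M2", "M3")))
  b1 <- bms_random_effects(lme, n_samples = 5e4, seed = 9)
  shifted <- lme + matrix(rep(rnorm(26, 0, 50), 3), 26, 3)
  b2 <- bms_random_effects(shifted, n_samples = 5e4, seed = 9)
  expect_equal(b1$exceedance_probability, b2$exceedance_probability,
               tolerance = 1e-9)
  b3 <- bms_random_effects(lme, n_samples = 5e4, seed = 9)
  expect_identical(b1$exceedance_probability, b3$exceedance_probability)
  expect_error(bms_random_effects(lme[1, , drop = FALSE]), "2 participants")
  expect_error(bms_random_effects(lme[, 1, drop = FALSE]), "2 models")
})

test_that("fixed-effects comparison is shift invariant and ranks single fits", {
  lme <- matrix(c(-10, -12, -11, -9), 2, 2, dimnames = list(NULL, c("A", "B")))
  fx <- fixed_effects_comparison(lme)
  expect_equal(unname(fx$total_log_evidence), c(-22, -20))
  expect_equal(fx$log_bayes_factors["B", "A"], 2)
  fx2 <- fixed_effects_comparison(lme + 7)
  expect_equal(fx$log_bayes_factors, fx2$log_bayes_factors)
  single <- fixed_effects_comparison(matrix(c(-5, -9), 1, 2,
                                            dimnames = list(NULL, c("A", "B"))))
  expect_equal(unname(which.max(single$total_log_evidence)), 1L)
})

test_that("fixed- and random-effects schemes agree on well-separated evidence", {
  set.seed(2)
  lme <- cbind(M1 = rnorm(20, -110, 2), M2 = rnorm(20, -100, 2),
               M3 = rnorm(20, -120, 2))
  bms <- bms_random_effects(lme, n_samples = 5e4, seed = 2)
  fx <- fixed_effects_comparison(lme)
  expect_equal(names(which.max(bms$exceedance_probability)),
               names(which.max(fx$total_log_evidence)))
})
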