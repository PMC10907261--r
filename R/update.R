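#' Empathy-update model specification
#'
#' The candidate family models a participant's trial-wise empathy ratings as
#' a linear function of time-discounted cumulative observational prediction
#' errors on top of the baseline empathy level:
#' \itemize{
#'   \item \code{M1_single}: one weight on the discounted sum of all PEs.
#'   \item \code{M2_signsplit}: separate weights on the discounted sums of
#'     positive and negative PEs.
#'   \item \code{M3_signsplit_halfsplit}: as M2, but with separate weight
#'     pairs for the first and second half of the learning session.
#' }
#'
#' @param model_id One of \code{"M1_single"}, \code{"M2_signsplit"},
#'   \code{"M3_signsplit_halfsplit"}.
#' @param half_boundary Learning-session trial index ending the first half
#'   (default 24, the end of block 2, where the recipient changes).
#' @param include_nonpain Model empathy ratings of non-painful trials too
#'   (default FALSE: the demonstrator manipulation targets painful trials).
#' @return An object of class \code{update_model_spec}.
#' @export
update_model_spec <- function(model_id = c("M3_signsplit_halfsplit",
                                           "M1_single", "M2_signsplit"),
                              half_boundary = 24L,
                              include_nonpain = FALSE) {
  model_id <- match.arg(model_id)
  if (half_boundary < 1L) stop("'half_boundary' must be positive", call. = FALSE)
  structure(list(model_id = model_id,
                 half_boundary = as.integer(half_boundary),
                 include_nonpain = isTRUE(include_nonpain)),
            class = "update_model_spec")
}

model_weight_names <- function(model_id) {
  switch(model_id,
         M1_single = "W",
         M2_signsplit = c("W_pos", "W_neg"),
         M3_signsplit_halfsplit = c("W1_pos", "W1_neg", "W2_pos", "W2_neg"),
         stop("unknown model_id", call. = FALSE))
}

#' Empathy-update model parameters
#'
#' @param weights Named numeric vector matching the model's weight set
#'   (\code{W}; \code{W_pos}/\code{W_neg}; or
#'   \code{W1_pos}/\code{W1_neg}/\code{W2_pos}/\code{W2_neg}).
#' @param gamma Discount factor in [0, 1].
#' @param empathy_t0 Baseline empathy rating (model intercept).
#' @param sigma_emp Gaussian noise SD (> 0).
#' @return An object of class \code{update_params}.
#' @export
update_params <- function(weights, gamma, empathy_t0, sigma_emp = 5) {
  assert_unit_interval(gamma, "gamma")
  if (sigma_emp <= 0) stop("'sigma_emp' must be positive", call. = FALSE)
  if (is.null(names(weights)) || any(!nzchar(names(weights)))) {
    stop("'weights' must be a named vector", call. = FALSE)
  }
  structure(list(weights = weights, gamma = gamma,
                 empathy_t0 = empathy_t0, sigma_emp = sigma_emp),
            class = "update_params")
}

#' Time-discounted cumulative prediction-error sums
#'
#' Computes \eqn{S(t) = \sum_{\tau \le t} \gamma^{t-\tau} \delta_\tau}
#' restricted to strictly positive, strictly negative, or all prediction
#' errors. Zero prediction errors contribute to neither the positive nor the
#' negative sum. With \eqn{\gamma = 0} only the current trial's error
#' survives; with \eqn{\gamma = 1} all preceding errors weigh equally.
#' Internally the sums satisfy the recursion
#' \eqn{S(t) = \gamma S(t-1) + \delta_t(\mathrm{sign})}.
#'
#' @param pe_series Numeric vector of prediction errors.
#' @param gamma Discount in [0, 1].
#' @param t Optional trial index; if supplied the scalar \eqn{S(t)} is
#'   returned, otherwise the full trajectory.
#' @param sign \code{"all"}, \code{"pos"} or \code{"neg"}.
#' @return Scalar or vector of discounted sums.
#' @export
discounted_pe_sums <- function(pe_series, gamma, t = NULL,
                               sign = c("all", "pos", "neg")) {
  sign <- match.arg(sign)
  assert_unit_interval(gamma, "gamma")
  d <- switch(sign,
              all = pe_series,
              pos = ifelse(pe_series > 0, pe_series, 0),
              neg = ifelse(pe_series < 0, pe_series, 0))
  n <- length(d)
  s <- numeric(n)
  acc <- 0
  for (i in seq_len(n)) {
    acc <- gamma * acc + d[i]
    s[i] <- acc
  }
  if (is.null(t)) return(s)
  if (t < 1L || t > n) stop("'t' out of range", call. = FALSE)
  s[t]
}

#' Model-implied empathy trajectory
#'
#' Evaluates the linear discounted-PE model for a given parameter set. The
#' prediction error of trial \eqn{t} is included in \eqn{E_t} (within a
#' trial the participant observes the demonstrator's rating before giving
#' their own). The output is not clipped: clipping applies only when
#' emitting simulated ratings, never inside fitting.
#'
#' @param spec An \code{\link{update_model_spec}}.
#' @param params An \code{\link{update_params}} whose weight set matches the
#'   model.
#' @param pe_series Prediction errors of the modeled trials, in order.
#' @param trial_index Learning-session trial indices of the modeled trials
#'   (used for the half split; defaults to sequential positions).
#' @return Numeric vector \eqn{E_t}, one per modeled trial.
#' @export
predict_empathy <- function(spec, params, pe_series,
                            trial_index = seq_along(pe_series)) {
  if (!inherits(spec, "update_model_spec")) {
    stop("'spec' must be an update_model_spec", call. = FALSE)
  }
  if (!inherits(params, "update_params")) {
    stop("'params' must be an update_params", call. = FALSE)
  }
  wanted <- model_weight_names(spec$model_id)
  if (!setequal(names(params$weights), wanted)) {
    stop(sprintf("weight set {%s} does not match model %s (expects {%s})",
                 paste(names(params$weights), collapse = ", "),
                 spec$model_id, paste(wanted, collapse = ", ")),
         call. = FALSE)
  }
  if (length(trial_index) != length(pe_series)) {
    stop("'trial_index' must align with 'pe_series'", call. = FALSE)
  }
  w <- params$weights
  g <- params$gamma
  t0 <- params$empathy_t0
  switch(spec$model_id,
    M1_single = t0 + w[["W"]] * discounted_pe_sums(pe_series, g, sign = "all"),
    M2_signsplit = t0 +
      w[["W_pos"]] * discounted_pe_sums(pe_series, g, sign = "pos") +
      w[["W_neg"]] * discounted_pe_sums(pe_series, g, sign = "neg"),
    M3_signsplit_halfsplit = {
      s_pos <- discounted_pe_sums(pe_series, g, sign = "pos")
      s_neg <- discounted_pe_sums(pe_series, g, sign = "neg")
      first <- trial_index <= spec$half_boundary
      t0 + ifelse(first, w[["W1_pos"]], w[["W2_pos"]]) * s_pos +
        ifelse(first, w[["W1_neg"]], w[["W2_neg"]]) * s_neg
    })
}

#' Priors for empathy-update model fitting
#'
#' Weights carry Normal(0, \code{weight_sd}) priors, \code{gamma} a
#' Beta(1.1, 1.1) prior through a logit transform, and \code{log(sigma_emp)}
#' a normal prior centered on log(5). The intercept \code{empathy_t0} is
#' fixed to the participant's mean baseline rating for painful videos rather
#' than fitted.
#'
#' @param empathy_t0 Fixed baseline empathy level (required).
#' @param weight_sd Prior SD of the weights.
#' @param gamma_shape1,gamma_shape2 Beta shapes for \code{gamma}.
#' @param log_sigma_mean,log_sigma_sd Normal prior on \code{log(sigma_emp)}.
#' @return An object of class \code{update_priors}.
#' @export
update_priors <- function(empathy_t0, weight_sd = 2,
                          gamma_shape1 = 1.1, gamma_shape2 = 1.1,
                          log_sigma_mean = log(5), log_sigma_sd = 1) {
  if (missing(empathy_t0) || !is.finite(empathy_t0)) {
    stop("'empathy_t0' must be supplied (baseline painful-trial mean)",
         call. = FALSE)
  }
  structure(list(empathy_t0 = empathy_t0, weight_sd = weight_sd,
                 gamma_shape1 = gamma_shape1, gamma_shape2 = gamma_shape2,
                 log_sigma_mean = log_sigma_mean, log_sigma_sd = log_sigma_sd),
            class = "update_priors")
}

# design matrix of discounted sums for a given gamma (columns in the order
# of model_weight_names)
update_design <- function(spec, pe_series, trial_index, gamma) {
  switch(spec$model_id,
    M1_single = matrix(discounted_pe_sums(pe_series, gamma, sign = "all"),
                       ncol = 1),
    M2_signsplit = cbind(discounted_pe_sums(pe_series, gamma, sign = "pos"),
                         discounted_pe_sums(pe_series, gamma, sign = "neg")),
    M3_signsplit_halfsplit = {
      s_pos <- discounted_pe_sums(pe_series, gamma, sign = "pos")
      s_neg <- discounted_pe_sums(pe_series, gamma, sign = "neg")
      first <- as.numeric(trial_index <= spec$half_boundary)
      cbind(first * s_pos, first * s_neg,
            (1 - first) * s_pos, (1 - first) * s_neg)
    })
}

#' MAP fit of an empathy-update model
#'
#' Fits the weights, discount factor and noise SD of one candidate model by
#' maximum a posteriori estimation under a Gaussian likelihood of the
#' observed empathy ratings around the model trajectory
#' (\code{\link{predict_empathy}}), with multi-start optimization. Starting
#' points include ridge-regression solutions for the weights on a coarse
#' grid of discount values (the model is linear in the weights given
#' \code{gamma}), which makes convergence fast and reliable.
#'
#' If the modeled trials contain no prediction error of a given sign, the
#' corresponding weight is prior-dominated and the fit is flagged (e.g.
#' \code{"W_neg_unidentifiable"}).
#'
#' @param empathy_ratings Observed empathy ratings of the modeled trials.
#' @param pe_series Observational prediction errors, aligned with the
#'   ratings.
#' @param spec An \code{\link{update_model_spec}}.
#' @param priors An \code{\link{update_priors}} (carries the fixed
#'   \code{empathy_t0}).
#' @param trial_index Learning-session trial indices of the modeled trials.
#' @param n_starts Number of optimization restarts.
#' @param seed Seed for the restart draws.
#' @param r2_method See \code{\link{fit_rw}}.
#' @return An object of class \code{update_fit}: \code{spec},
#'   \code{map_params}, \code{trajectory}, \code{lpp}, \code{lame},
#'   \code{r2}, \code{loglik} (log likelihood at the MAP) and \code{flags}.
#' @export
fit_update_model <- function(empathy_ratings, pe_series, spec, priors,
                             trial_index = seq_along(pe_series),
                             n_starts = 10L, seed = 1L,
                             r2_method = c("pearson", "rss")) {
  r2_method <- match.arg(r2_method)
  if (!inherits(spec, "update_model_spec")) {
    stop("'spec' must be an update_model_spec", call. = FALSE)
  }
  if (!inherits(priors, "update_priors")) {
    stop("'priors' must be an update_priors object", call. = FALSE)
  }
  y <- empathy_ratings
  if (length(y) != length(pe_series) || length(y) != length(trial_index)) {
    stop("ratings, PE series and trial indices must align", call. = FALSE)
  }
  if (length(y) < 10L) stop("need at least 10 modeled trials", call. = FALSE)

  wn <- model_weight_names(spec$model_id)
  k_w <- length(wn)
  t0 <- priors$empathy_t0
  flags <- character(0)
  if (!any(pe_series > 0) && any(grepl("pos", wn))) {
    flags <- c(flags, paste0(wn[grepl("pos", wn)], "_unidentifiable"))
  }
  if (!any(pe_series < 0) && any(grepl("neg", wn))) {
    flags <- c(flags, paste0(wn[grepl("neg", wn)], "_unidentifiable"))
  }
  if (spec$model_id == "M3_signsplit_halfsplit" &&
      (all(trial_index <= spec$half_boundary) ||
       all(trial_index > spec$half_boundary))) {
    stop("'half_boundary' must fall strictly inside the modeled trials",
         call. = FALSE)
  }

  # theta = (weights, logit gamma, log sigma)
  nlp <- function(theta) {
    w <- theta[seq_len(k_w)]
    g <- stats::plogis(theta[k_w + 1L])
    sigma <- exp(theta[k_w + 2L])
    X <- update_design(spec, pe_series, trial_index, g)
    e <- t0 + as.numeric(X %*% w)
    nll <- -sum(stats::dnorm(y, e, sigma, log = TRUE))
    lp <- sum(stats::dnorm(w, 0, priors$weight_sd, log = TRUE)) +
      log_prior_logit_beta(theta[k_w + 1L], priors$gamma_shape1,
                           priors$gamma_shape2) +
      stats::dnorm(theta[k_w + 2L], priors$log_sigma_mean,
                   priors$log_sigma_sd, log = TRUE)
    val <- nll - lp
    if (!is.finite(val)) val <- 1e10
    val
  }

  # ridge starts: solve the weights in closed form on a gamma grid
  gamma_grid <- c(0.2, 0.5, 0.8, 0.95)
  ridge_start <- function(g) {
    X <- update_design(spec, pe_series, trial_index, g)
    sig2 <- 25
    A <- crossprod(X) / sig2 + diag(1 / priors$weight_sd^2, k_w)
    w <- tryCatch(as.numeric(solve(A, crossprod(X, y - t0) / sig2)),
                  error = function(e) rep(0, k_w))
    resid_sd <- stats::sd(y - t0 - as.numeric(X %*% w))
    if (!is.finite(resid_sd) || resid_sd < 1) resid_sd <- 5
    c(w, stats::qlogis(g), log(resid_sd))
  }
  start_fun <- function(s) {
    if (s <= length(gamma_grid)) {
      ridge_start(gamma_grid[s])
    } else {
      c(stats::rnorm(k_w, 0, 0.5),
        stats::qlogis(stats::runif(1, 0.05, 0.95)),
        stats::rnorm(1, priors$log_sigma_mean, 0.5))
    }
  }
  best <- map_optimize(nlp, start_fun, n_starts = n_starts, seed = seed)
  theta <- best$par
  w_hat <- stats::setNames(theta[seq_len(k_w)], wn)
  gamma_hat <- stats::plogis(theta[k_w + 1L])
  sigma_hat <- exp(theta[k_w + 2L])
  params <- update_params(weights = w_hat, gamma = gamma_hat,
                          empathy_t0 = t0, sigma_emp = sigma_hat)
  traj <- predict_empathy(spec, params, pe_series, trial_index)

  H <- fd_hessian(nlp, theta)
  lame <- suppressWarnings(laplace_evidence(-best$objective, theta, H))
  if (isTRUE(attr(lame, "regularized"))) flags <- c(flags, "hessian_regularized")

  structure(list(
    spec = spec,
    map_params = params,
    trajectory = traj,
    lpp = best$objective,
    lame = as.numeric(lame),
    r2 = fit_r2(y, traj, r2_method),
    loglik = sum(stats::dnorm(y, traj, sigma_hat, log = TRUE)),
    n_trials = length(y),
    flags = flags,
    convergence = best$convergence,
    priors = priors
  ), class = "update_fit")
}

#' @export
print.update_fit <- function(x, ...) {
  cat(sprintf("Empathy-update model %s (%d trials)\n",
              x$spec$model_id, x$n_trials))
  w <- x$map_params$weights
  cat("  weights:", paste(sprintf("%s = %.3f", names(w), w), collapse = ", "), "\n")
  cat(sprintf("  gamma = %.3f, empathy_t0 = %.1f (fixed), sigma = %.2f\n",
              x$map_params$gamma, x$map_params$empathy_t0,
              x$map_params$sigma_emp))
  cat(sprintf("  LPP = %.2f, LAME = %.2f, r2 = %.3f\n", x$lpp, x$lame, x$r2))
  if (length(x$flags)) cat("  flags:", paste(x$flags, collapse = ", "), "\n")
  invisible(x)
}

#' Correlation between first-half weights and empathy change
#'
#' Spearman rank correlation between the group-relevant first-half weight
#' (\code{W1_pos} for high-empathy cohorts, \code{W1_neg} for low) and the
#' participants' empathy change scores (generalization minus baseline mean
#' for painful trials).
#'
#' @param fits List of \code{update_fit} objects, one per participant.
#' @param empathy_change_scores Numeric vector of change scores, aligned.
#' @param group \code{"high"} or \code{"low"}: selects the relevant weight.
#' @return List with \code{rho}, \code{p_value}, \code{n},
#'   \code{weight_name} and \code{flag} (\code{"zero_variance"} when the
#'   correlation is undefined).
#' @export
weight_change_correlation <- function(fits, empathy_change_scores,
                                      group = c("high", "low")) {
  group <- match.arg(group)
  if (length(fits) != length(empathy_change_scores)) {
    stop("one change score per fit is required", call. = FALSE)
  }
  if (length(fits) < 5L) stop("need at least 5 participants", call. = FALSE)
  model_id <- fits[[1]]$spec$model_id
  weight_name <- switch(model_id,
    M1_single = "W",
    M2_signsplit = if (group == "high") "W_pos" else "W_neg",
    M3_signsplit_halfsplit = if (group == "high") "W1_pos" else "W1_neg")
  w <- vapply(fits, function(f) f$map_params$weights[[weight_name]], numeric(1))
  if (stats::sd(w) == 0 || stats::sd(empathy_change_scores) == 0) {
    return(list(rho = NA_real_, p_value = NA_real_, n = length(w),
                weight_name = weight_name, flag = "zero_variance"))
  }
  ct <- suppressWarnings(
    stats::cor.test(w, empathy_change_scores, method = "spearman",
                    exact = FALSE))
  list(rho = unname(ct$estimate), p_value = ct$p.value, n = length(w),
       weight_name = weight_name, flag = NULL)
}
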