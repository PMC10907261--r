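#' Rescorla-Wagner parameters
#'
#' @param alpha Learning rate in [0, 1].
#' @param p0 Initial prediction rating (0-100).
#' @param sigma_pred Gaussian observation noise SD (rating units, > 0).
#' @return An object of class \code{rw_params}.
#' @export
rw_params <- function(alpha, p0, sigma_pred = 5) {
  assert_unit_interval(alpha, "alpha")
  assert_rating(p0, "p0")
  if (sigma_pred <= 0) stop("'sigma_pred' must be positive", call. = FALSE)
  structure(list(alpha = alpha, p0 = p0, sigma_pred = sigma_pred),
            class = "rw_params")
}

#' Rescorla-Wagner forward pass
#'
#' Runs the delta-rule recursion over a series of demonstrator ratings:
#' \eqn{P_1 = p_0}, \eqn{\delta_t = R_t - P_t},
#' \eqn{P_{t+1} = P_t + \alpha \delta_t}. The prediction error
#' \eqn{\delta_t} is the observational learning signal: positive when the
#' demonstrator rated higher (more empathically) than predicted.
#'
#' @param params An \code{\link{rw_params}} object.
#' @param demonstrator_ratings Numeric vector of observed ratings (0-100).
#' @return List with \code{p} (prediction trajectory) and \code{pe}
#'   (prediction errors), both the length of the input.
#' @export
rw_forward <- function(params, demonstrator_ratings) {
  if (!inherits(params, "rw_params")) {
    stop("'params' must be an rw_params object", call. = FALSE)
  }
  r <- demonstrator_ratings
  if (length(r) == 0L) stop("empty rating series", call. = FALSE)
  n <- length(r)
  p <- numeric(n)
  p[1] <- params$p0
  a <- params$alpha
  if (n > 1L) {
    for (t in seq_len(n - 1L)) {
      p[t + 1L] <- p[t] + a * (r[t] - p[t])
    }
  }
  list(p = p, pe = r - p)
}

#' Priors for Rescorla-Wagner MAP fitting
#'
#' \code{alpha} carries a mildly regularizing Beta(1.1, 1.1) prior (applied
#' through a logit transform), \code{p0} a normal prior centered on the
#' participant's baseline mean for painful videos, and \code{log(sigma)} a
#' normal prior centered on log(5) rating units.
#'
#' @param p0_mean Center of the \code{p0} prior; if NULL it is taken from the
#'   first observed prediction at fit time.
#' @param p0_sd SD of the \code{p0} prior.
#' @param alpha_shape1,alpha_shape2 Beta shape parameters for \code{alpha}.
#' @param log_sigma_mean,log_sigma_sd Normal prior on \code{log(sigma_pred)}.
#' @return An object of class \code{rw_priors}.
#' @export
rw_priors <- function(p0_mean = NULL, p0_sd = 10,
                      alpha_shape1 = 1.1, alpha_shape2 = 1.1,
                      log_sigma_mean = log(5), log_sigma_sd = 1) {
  structure(list(p0_mean = p0_mean, p0_sd = p0_sd,
                 alpha_shape1 = alpha_shape1, alpha_shape2 = alpha_shape2,
                 log_sigma_mean = log_sigma_mean, log_sigma_sd = log_sigma_sd),
            class = "rw_priors")
}

#' MAP fit of the Rescorla-Wagner model to trial-wise predictions
#'
#' Fits learning rate, initial prediction and observation noise by maximum a
#' posteriori estimation under an independent Gaussian likelihood of the
#' observed predictions around the model trajectory, with multi-start
#' quasi-Newton optimization in an unconstrained parameter space. Returns the
#' minimized negative log posterior (LPP), the Laplace approximation to the
#' model evidence (LAME), the goodness of fit \eqn{r^2}, and the trial-wise
#' observational prediction errors evaluated at the MAP estimate.
#'
#' Missing predictions are allowed (they drop out of the likelihood while the
#' forward recursion still runs over all trials); at least 10 non-missing
#' predictions are required. If both the demonstrator series and the
#' observed predictions are constant, the learning rate is unidentifiable and
#' the fit is flagged (\code{"alpha_unidentifiable"}); boundary estimates of
#' alpha are flagged \code{"alpha_boundary"}.
#'
#' @param observed_predictions Participant's trial-wise predictions of the
#'   demonstrator's ratings (NA allowed).
#' @param demonstrator_ratings Demonstrator ratings, same length.
#' @param priors An \code{\link{rw_priors}} object.
#' @param n_starts Number of seeded optimization restarts.
#' @param seed Seed for the restart draws.
#' @param r2_method \code{"pearson"} (squared Pearson correlation between
#'   model and observed predictions, the default) or \code{"rss"}
#'   (1 - SSE/SST, floored at 0).
#' @return An object of class \code{rw_fit}: MAP parameters, \code{lpp},
#'   \code{lame}, \code{r2}, \code{model_predictions},
#'   \code{prediction_errors}, and \code{flags}.
#' @export
fit_rw <- function(observed_predictions, demonstrator_ratings,
                   priors = rw_priors(), n_starts = 10L, seed = 1L,
                   r2_method = c("pearson", "rss")) {
  r2_method <- match.arg(r2_method)
  y <- observed_predictions
  r <- demonstrator_ratings
  if (length(y) != length(r)) {
    stop("prediction and rating series must have equal length", call. = FALSE)
  }
  obs <- which(!is.na(y))
  if (length(obs) < 10L) {
    stop("need at least 10 non-missing predictions", call. = FALSE)
  }
  flags <- character(0)
  if (stats::sd(y[obs]) == 0 && stats::sd(r) == 0) {
    flags <- c(flags, "alpha_unidentifiable")
    warning("constant predictions and ratings: learning rate unidentifiable",
            call. = FALSE)
  }
  p0_mean <- priors$p0_mean %||% y[obs[1]]

  # theta = (logit alpha, p0, log sigma)
  nlp <- function(theta) {
    a <- stats::plogis(theta[1])
    p <- rw_forward_raw(a, theta[2], r)
    sigma <- exp(theta[3])
    nll <- -sum(stats::dnorm(y[obs], p[obs], sigma, log = TRUE))
    lp <- log_prior_logit_beta(theta[1], priors$alpha_shape1, priors$alpha_shape2) +
      stats::dnorm(theta[2], p0_mean, priors$p0_sd, log = TRUE) +
      stats::dnorm(theta[3], priors$log_sigma_mean, priors$log_sigma_sd, log = TRUE)
    val <- nll - lp
    if (!is.finite(val)) val <- 1e10
    val
  }

  alpha_grid <- c(0.1, 0.3, 0.6, 0.9)
  start_fun <- function(s) {
    if (s <= length(alpha_grid)) {
      c(stats::qlogis(alpha_grid[s]), p0_mean, log(5))
    } else {
      c(stats::qlogis(stats::runif(1, 0.02, 0.98)),
        stats::rnorm(1, p0_mean, priors$p0_sd),
        stats::rnorm(1, priors$log_sigma_mean, 0.5))
    }
  }
  best <- map_optimize(nlp, start_fun, n_starts = n_starts, seed = seed)
  theta <- best$par
  alpha_hat <- stats::plogis(theta[1])
  if (alpha_hat < 1e-3 || alpha_hat > 1 - 1e-3) {
    flags <- c(flags, "alpha_boundary")
  }
  H <- fd_hessian(nlp, theta)
  lame <- suppressWarnings(laplace_evidence(-best$objective, theta, H))
  if (isTRUE(attr(lame, "regularized"))) flags <- c(flags, "hessian_regularized")

  p_hat <- rw_forward_raw(alpha_hat, theta[2], r)
  structure(list(
    map_params = rw_params(alpha = alpha_hat,
                           p0 = clip_rating(theta[2]),
                           sigma_pred = exp(theta[3])),
    p0_raw = theta[2],
    model_predictions = p_hat,
    prediction_errors = r - p_hat,
    lpp = best$objective,
    lame = as.numeric(lame),
    r2 = fit_r2(y[obs], p_hat[obs], r2_method),
    n_trials = length(r),
    n_observed = length(obs),
    flags = flags,
    convergence = best$convergence,
    priors = priors
  ), class = "rw_fit")
}

# unchecked forward pass used inside optimization loops
rw_forward_raw <- function(alpha, p0, r) {
  n <- length(r)
  p <- numeric(n)
  p[1] <- p0
  if (n > 1L) {
    for (t in seq_len(n - 1L)) p[t + 1L] <- p[t] + alpha * (r[t] - p[t])
  }
  p
}

#' @export
print.rw_fit <- function(x, ...) {
  cat(sprintf(
    "Rescorla-Wagner MAP fit (%d trials): alpha = %.3f, p0 = %.1f, sigma = %.2f\n",
    x$n_trials, x$map_params$alpha, x$map_params$p0, x$map_params$sigma_pred))
  cat(sprintf("  LPP = %.2f, LAME = %.2f, r2 = %.3f\n", x$lpp, x$lame, x$r2))
  if (length(x$flags)) cat("  flags:", paste(x$flags, collapse = ", "), "\n")
  invisible(x)
}

#' Tidy table of observational prediction errors
#'
#' Aligns the prediction errors of a fitted Rescorla-Wagner model with the
#' learning trials of a schedule. The sign convention is
#' \eqn{\delta_t = R_t - P_t}: positive when the demonstrator rated more
#' empathically than the model predicted.
#'
#' @param fit An \code{\link{fit_rw}} result.
#' @param schedule Schedule whose learning trials the fit was computed on.
#' @return Data frame with \code{trial_index}, \code{block}, \code{pain},
#'   \code{recipient_id}, \code{demonstrator_rating}, \code{model_prediction}
#'   and \code{pe}.
#' @export
prediction_errors_table <- function(fit, schedule) {
  if (!inherits(fit, "rw_fit")) stop("'fit' must be an rw_fit", call. = FALSE)
  learning <- schedule[schedule$session == "learning", , drop = FALSE]
  if (nrow(learning) != fit$n_trials) {
    stop("schedule learning trials do not match the fitted series", call. = FALSE)
  }
  data.frame(
    trial_index = learning$trial_index,
    block = learning$block,
    pain = learning$pain,
    recipient_id = learning$recipient_id,
    demonstrator_rating = fit$model_predictions + fit$prediction_errors,
    model_prediction = fit$model_predictions,
    pe = fit$prediction_errors,
    stringsAsFactors = FALSE
  )
}
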