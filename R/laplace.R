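#' Central finite-difference Hessian
#'
#' Numerical Hessian of a scalar function, computed by central differences
#' with a relative step size. Used to obtain the curvature of the negative
#' log posterior at the MAP estimate for the Laplace approximation.
#'
#' @param f Scalar function of a numeric vector.
#' @param x Point at which to evaluate the Hessian.
#' @param rel_step Relative step size (default 1e-4).
#' @return A symmetric k x k matrix.
#' @export
fd_hessian <- function(f, x, rel_step = 1e-4) {
  k <- length(x)
  h <- rel_step * pmax(abs(x), 1)
  H <- matrix(0, k, k)
  f0 <- f(x)
  for (i in seq_len(k)) {
    ei <- numeric(k); ei[i] <- h[i]
    H[i, i] <- (f(x + ei) - 2 * f0 + f(x - ei)) / h[i]^2
    if (i > 1L) {
      for (j in seq_len(i - 1L)) {
        ej <- numeric(k); ej[j] <- h[j]
        H[i, j] <- H[j, i] <-
          (f(x + ei + ej) - f(x + ei - ej) - f(x - ei + ej) + f(x - ei - ej)) /
          (4 * h[i] * h[j])
      }
    }
  }
  H
}

#' Laplace approximation to the log model evidence
#'
#' Approximates the log marginal likelihood of a model by a second-order
#' expansion of the log posterior around its mode:
#' \deqn{LAME = \log p(y, \hat\theta) + (k/2) \log 2\pi - (1/2) \log |H|}
#' where \eqn{H} is the Hessian of the negative log posterior at the MAP
#' estimate and \eqn{k} the number of free parameters. The approximation
#' trades goodness of fit against model complexity and is used as the
#' per-participant evidence entering group-level Bayesian model selection.
#'
#' If the Hessian is not positive definite it is regularized by adding jitter
#' to the diagonal and the result carries attribute \code{regularized = TRUE}.
#'
#' @param log_posterior_at_map Unnormalized log posterior at the MAP point
#'   (i.e. minus the minimized LPP).
#' @param map_params MAP parameter vector (length k; may be length 0 for a
#'   model without free parameters, in which case the log likelihood is
#'   returned unchanged).
#' @param hessian_of_neg_log_posterior k x k Hessian of the negative log
#'   posterior at the MAP.
#' @return Scalar LAME (log-evidence units) with attribute
#'   \code{regularized}.
#' @export
laplace_evidence <- function(log_posterior_at_map, map_params,
                             hessian_of_neg_log_posterior) {
  k <- length(map_params)
  if (k == 0L) {
    return(structure(log_posterior_at_map, regularized = FALSE))
  }
  H <- hessian_of_neg_log_posterior
  if (!is.matrix(H) || any(dim(H) != k)) {
    stop("Hessian dimensions do not match the parameter vector", call. = FALSE)
  }
  ev <- eigen((H + t(H)) / 2, symmetric = TRUE, only.values = TRUE)$values
  regularized <- FALSE
  if (any(ev <= 0)) {
    jitter <- abs(min(ev)) + 1e-6 * max(abs(ev), 1)
    H <- H + diag(jitter, k)
    regularized <- TRUE
    warning("Hessian not positive definite; jitter added to the diagonal",
            call. = FALSE)
  }
  ld <- as.numeric(determinant(H, logarithm = TRUE)$modulus)
  structure(log_posterior_at_map + 0.5 * k * log(2 * pi) - 0.5 * ld,
            regularized = regularized)
}

# Multi-start minimization of a negative log posterior. start_fun() must
# return a fresh starting vector each call (deterministic given the RNG
# state). Returns the best nlminb fit.
map_optimize <- function(nlp, start_fun, n_starts = 10L, seed = 1L) {
  set.seed(seed)
  best <- NULL
  for (s in seq_len(n_starts)) {
    th0 <- start_fun(s)
    fit <- tryCatch(
      stats::nlminb(th0, nlp, control = list(iter.max = 500, eval.max = 1000)),
      error = function(e) NULL
    )
    if (!is.null(fit) && is.finite(fit$objective) &&
        (is.null(best) || fit$objective < best$objective)) {
      best <- fit
    }
  }
  if (is.null(best)) {
    stop("all optimization restarts failed", call. = FALSE)
  }
  best
}

# Goodness of fit between observed and model trajectories.
fit_r2 <- function(observed, fitted, method = c("pearson", "rss")) {
  method <- match.arg(method)
  if (method == "pearson") {
    if (stats::sd(observed) == 0 || stats::sd(fitted) == 0) return(0)
    stats::cor(observed, fitted)^2
  } else {
    sst <- sum((observed - mean(observed))^2)
    if (sst == 0) return(0)
    max(0, min(1, 1 - sum((observed - fitted)^2) / sst))
  }
}

# log prior for a logit-transformed Beta(a, b) parameter, including the
# Jacobian of the transform so the density is proper in the unconstrained
# space used by the optimizer.
log_prior_logit_beta <- function(theta, shape1, shape2) {
  p <- stats::plogis(theta)
  stats::dbeta(p, shape1, shape2, log = TRUE) + log(p) + log1p(-p)
}
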