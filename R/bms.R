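#' Random-effects Bayesian model selection
#'
#' Group-level model comparison over a matrix of per-participant log model
#' evidences (here, Laplace approximations). The random-effects scheme
#' treats the data-generating model as a random variable per participant and
#' estimates the population model frequencies with a variational Dirichlet
#' update (uniform Dirichlet(1) prior). The exceedance probability (XP) of
#' model m is the posterior probability that m is the most frequent model in
#' the population, estimated by Monte-Carlo sampling from the fitted
#' Dirichlet.
#'
#' @param evidence Numeric matrix (or data frame) of log evidences, one row
#'   per participant, one column per model. Column names label the models.
#' @param n_samples Number of Dirichlet Monte-Carlo samples for the XP.
#' @param seed Seed for the Monte-Carlo draws.
#' @param alpha0 Dirichlet prior concentration (default 1 per model).
#' @param max_iter,tol Convergence controls of the variational update.
#' @return An object of class \code{bms_result}: \code{dirichlet_alpha},
#'   \code{expected_frequencies}, \code{exceedance_probability},
#'   \code{model_attribution} (posterior model probabilities per
#'   participant), \code{n_mc_samples} and \code{seed}.
#' @references Stephan et al. (2009) Bayesian model selection for group
#'   studies. NeuroImage 46:1004-1017.
#' @export
bms_random_effects <- function(evidence, n_samples = 1e5, seed = 1L,
                               alpha0 = 1, max_iter = 500L, tol = 1e-10) {
  lme <- as.matrix(evidence)
  if (nrow(lme) < 2L) stop("need at least 2 participants", call. = FALSE)
  if (ncol(lme) < 2L) stop("need at least 2 models", call. = FALSE)
  if (any(!is.finite(lme))) stop("evidence entries must be finite", call. = FALSE)
  n <- nrow(lme); K <- ncol(lme)
  models <- colnames(lme) %||% paste0("M", seq_len(K))

  # variational Dirichlet update
  alpha <- rep(alpha0, K)
  u <- matrix(1 / K, n, K)
  for (it in seq_len(max_iter)) {
    lw <- sweep(lme, 2, digamma(alpha) - digamma(sum(alpha)), "+")
    lw <- lw - apply(lw, 1, max)
    u <- exp(lw)
    u <- u / rowSums(u)
    alpha_new <- alpha0 + colSums(u)
    if (max(abs(alpha_new - alpha)) < tol) {
      alpha <- alpha_new
      break
    }
    alpha <- alpha_new
  }

  # exceedance probability by Monte-Carlo over the Dirichlet posterior
  set.seed(seed)
  g <- matrix(stats::rgamma(n_samples * K, shape = rep(alpha, each = n_samples)),
              nrow = n_samples, ncol = K)
  winner <- max.col(g, ties.method = "first")
  xp <- tabulate(winner, nbins = K) / n_samples

  structure(list(
    dirichlet_alpha = stats::setNames(alpha, models),
    expected_frequencies = stats::setNames(alpha / sum(alpha), models),
    exceedance_probability = stats::setNames(xp, models),
    model_attribution = structure(u, dimnames = list(rownames(lme), models)),
    n_mc_samples = as.integer(n_samples),
    seed = as.integer(seed)
  ), class = "bms_result")
}

#' @export
print.bms_result <- function(x, ...) {
  cat("Random-effects Bayesian model selection\n")
  tab <- rbind(`expected frequency` = x$expected_frequencies,
               `exceedance probability` = x$exceedance_probability)
  print(round(tab, 4))
  invisible(x)
}

#' Fixed-effects model comparison
#'
#' Diagnostic companion to the random-effects scheme: sums the log evidences
#' over participants (equivalent to assuming every participant shares one
#' data-generating model) and reports pairwise log group Bayes factors.
#'
#' @param evidence As in \code{\link{bms_random_effects}}; a single row is
#'   allowed (reduces to the per-participant evidence ranking).
#' @return List with \code{total_log_evidence} (per model) and
#'   \code{log_bayes_factors} (matrix, entry \code{[i, j]} = evidence for
#'   model i over model j).
#' @export
fixed_effects_comparison <- function(evidence) {
  lme <- as.matrix(evidence)
  if (ncol(lme) < 2L) stop("need at least 2 models", call. = FALSE)
  if (any(!is.finite(lme))) stop("evidence entries must be finite", call. = FALSE)
  models <- colnames(lme) %||% paste0("M", seq_len(ncol(lme)))
  total <- stats::setNames(colSums(lme), models)
  lbf <- outer(total, total, "-")
  dimnames(lbf) <- list(models, models)
  list(total_log_evidence = total, log_bayes_factors = lbf)
}
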