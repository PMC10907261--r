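#' Demonstrator rating algorithm
#'
#' Parameterizes the pre-defined algorithm that generates the demonstrator's
#' empathy ratings during the learning session, anchored to the participant's
#' own baseline ratings. For painful trials the ratings are drawn from a
#' normal distribution whose mean equals the participant's baseline mean for
#' painful videos shifted by \code{offset_multiplier * offset_sd} rating
#' points upwards (high-empathy group), downwards (low-empathy group) or not
#' at all (neutral), with sampling noise \code{noise_sd}. Non-painful trials
#' are drawn around the baseline non-painful mean without any shift.
#'
#' @param group \code{"high"}, \code{"low"} or \code{"neutral"}.
#' @param baseline_mean_pain Participant's mean baseline rating for painful
#'   videos (0-100).
#' @param baseline_mean_nonpain Participant's mean baseline rating for
#'   non-painful videos (0-100).
#' @param offset_sd SD unit used for the group offset (default 5).
#' @param offset_multiplier Number of SD units the painful-trial mean is
#'   shifted by (default 3, i.e. a 15-point offset).
#' @param noise_sd Sampling SD of the generated ratings (default 5).
#' @param seed Integer seed for the rating draws.
#' @return An object of class \code{demonstrator_algorithm}.
#' @export
demonstrator_algorithm <- function(group = c("high", "low", "neutral"),
                                   baseline_mean_pain,
                                   baseline_mean_nonpain,
                                   offset_sd = 5,
                                   offset_multiplier = 3,
                                   noise_sd = 5,
                                   seed = 1L) {
  group <- match.arg(group)
  assert_rating(baseline_mean_pain, "baseline_mean_pain")
  assert_rating(baseline_mean_nonpain, "baseline_mean_nonpain")
  if (noise_sd < 0) stop("'noise_sd' must be non-negative", call. = FALSE)
  structure(list(
    group = group,
    baseline_mean_pain = baseline_mean_pain,
    baseline_mean_nonpain = baseline_mean_nonpain,
    offset_sd = offset_sd,
    offset_multiplier = offset_multiplier,
    noise_sd = noise_sd,
    seed = as.integer(seed)
  ), class = "demonstrator_algorithm")
}

group_sign <- function(group) {
  switch(group, high = 1, low = -1, neutral = 0)
}

#' Generate demonstrator ratings for the learning session
#'
#' Draws one demonstrator rating per learning trial of a schedule using the
#' pre-defined algorithm (see \code{\link{demonstrator_algorithm}}). Draws are
#' clipped to the 0-100 scale and, by default, rounded to integers to match a
#' discrete rating display; set \code{round = FALSE} to obtain the raw
#' (clipped, unrounded) draws, e.g. when checking the sampling SD.
#'
#' @param algo A \code{\link{demonstrator_algorithm}}.
#' @param schedule A schedule from \code{\link{generate_schedule}} (only its
#'   learning rows are used).
#' @param round Round ratings to integers after clipping (default TRUE).
#' @return Numeric vector of ratings, one per learning trial, in presentation
#'   order.
#' @export
generate_demonstrator_ratings <- function(algo, schedule, round = TRUE) {
  if (!inherits(algo, "demonstrator_algorithm")) {
    stop("'algo' must be a demonstrator_algorithm", call. = FALSE)
  }
  learning <- schedule[schedule$session == "learning", , drop = FALSE]
  if (nrow(learning) == 0L) {
    stop("schedule contains no learning trials", call. = FALSE)
  }
  offset <- group_sign(algo$group) * algo$offset_multiplier * algo$offset_sd
  mu <- ifelse(learning$pain == "painful",
               algo$baseline_mean_pain + offset,
               algo$baseline_mean_nonpain)
  set.seed(algo$seed)
  draws <- stats::rnorm(nrow(learning), mean = mu, sd = algo$noise_sd)
  draws <- clip_rating(draws)
  if (round) draws <- round(draws)
  draws
}
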