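#' Ground-truth synthetic observer
#'
#' Bundles the generative parameters of a synthetic participant: a
#' Rescorla-Wagner learner for the prediction series (learning rate
#' \code{alpha}, initial prediction \code{p0}) and a discounted
#' prediction-error update rule for the empathy ratings (weights
#' \code{w1_pos}, \code{w1_neg} for the first half of the learning session and
#' \code{w2_pos}, \code{w2_neg} for the second half, discount \code{gamma},
#' baseline empathy level \code{empathy_t0}). Emitted predictions and empathy
#' ratings receive additive Gaussian noise and are clipped to 0-100.
#'
#' @param alpha Learning rate in [0, 1].
#' @param p0 Initial prediction rating (0-100).
#' @param gamma Discount factor in [0, 1] applied to earlier prediction
#'   errors; 0 keeps only the latest error, 1 weighs all equally.
#' @param empathy_t0 Baseline empathy rating for painful videos (0-100).
#' @param w1_pos,w1_neg,w2_pos,w2_neg Weights (rating units per PE unit) on
#'   positive/negative discounted prediction-error sums in the first/second
#'   half of the learning session.
#' @param pred_noise_sd,empathy_noise_sd Report noise SDs (rating units).
#' @param nonpain_t0 Baseline rating level for non-painful videos.
#' @param group Demonstrator regime the observer is paired with:
#'   \code{"high"}, \code{"low"} or \code{"neutral"}.
#' @return An object of class \code{ground_truth_observer}.
#' @export
ground_truth_observer <- function(alpha, p0, gamma, empathy_t0,
                                  w1_pos = 0, w1_neg = 0,
                                  w2_pos = 0, w2_neg = 0,
                                  pred_noise_sd = 8, empathy_noise_sd = 8,
                                  nonpain_t0 = 15,
                                  group = c("high", "low", "neutral")) {
  group <- match.arg(group)
  assert_unit_interval(alpha, "alpha")
  assert_unit_interval(gamma, "gamma")
  assert_rating(p0, "p0")
  assert_rating(empathy_t0, "empathy_t0")
  assert_rating(nonpain_t0, "nonpain_t0")
  if (pred_noise_sd < 0 || empathy_noise_sd < 0) {
    stop("noise SDs must be non-negative", call. = FALSE)
  }
  structure(list(
    alpha = alpha, p0 = p0, gamma = gamma, empathy_t0 = empathy_t0,
    w1_pos = w1_pos, w1_neg = w1_neg, w2_pos = w2_pos, w2_neg = w2_neg,
    pred_noise_sd = pred_noise_sd, empathy_noise_sd = empathy_noise_sd,
    nonpain_t0 = nonpain_t0, group = group
  ), class = "ground_truth_observer")
}

#' Sampling ranges for ground-truth observer parameters
#'
#' Uniform sampling ranges used when drawing synthetic cohorts for recovery
#' studies. By default the group-typical ("active") weights are drawn from
#' \code{w_active} and the atypical-sign weights are fixed at zero, mirroring
#' the empirical finding that atypical-sign weights are indistinguishable from
#' zero.
#'
#' @param alpha Range for the learning rate.
#' @param gamma Range for the discount factor.
#' @param w_active Range for the group-typical weights.
#' @param level Range for \code{empathy_t0} and \code{p0}.
#' @param pred_noise_sd,empathy_noise_sd Report noise SDs.
#' @param nonpain_t0 Baseline non-painful rating level.
#' @param w_active_second Range for the group-typical second-half weight in
#'   the half-split generative regime; NULL (default) reuses
#'   \code{w_active}. Recovery studies set this to \code{c(0, 0)} so the
#'   half-split structure is maximally expressed in the generated data.
#' @return An object of class \code{observer_priors}.
#' @export
observer_priors <- function(alpha = c(0.1, 0.7),
                            gamma = c(0.3, 0.95),
                            w_active = c(0.2, 1.0),
                            level = c(35, 65),
                            pred_noise_sd = 8,
                            empathy_noise_sd = 8,
                            nonpain_t0 = 15,
                            w_active_second = NULL) {
  pr <- list(alpha = alpha, gamma = gamma, w_active = w_active, level = level,
             pred_noise_sd = pred_noise_sd,
             empathy_noise_sd = empathy_noise_sd,
             nonpain_t0 = nonpain_t0,
             w_active_second = w_active_second)
  ranges <- c("alpha", "gamma", "w_active", "level")
  if (!is.null(w_active_second)) ranges <- c(ranges, "w_active_second")
  for (nm in ranges) {
    rng <- pr[[nm]]
    if (length(rng) != 2L || any(!is.finite(rng)) || rng[1] > rng[2]) {
      stop(sprintf("prior range '%s' must be c(lower, upper) with lower <= upper", nm),
           call. = FALSE)
    }
  }
  structure(pr, class = "observer_priors")
}

runif1 <- function(rng) stats::runif(1, rng[1], rng[2])

# Draw one ground-truth observer under a generative model regime.
# M1: one weight shared by both signs and halves; M2: sign-split, halves
# equal; M3: four independent weights. Group determines which signs are
# active (high: positive, low: negative, neutral: both).
draw_observer <- function(priors, group, model, seed) {
  set.seed(seed)
  alpha <- runif1(priors$alpha)
  gamma <- runif1(priors$gamma)
  t0 <- runif1(priors$level)
  p0 <- runif1(priors$level)
  w <- c(w1_pos = 0, w1_neg = 0, w2_pos = 0, w2_neg = 0)
  model <- match.arg(model, c("M1_single", "M2_signsplit", "M3_signsplit_halfsplit"))
  if (model == "M1_single") {
    w[] <- runif1(priors$w_active)
  } else {
    pos_active <- group %in% c("high", "neutral")
    neg_active <- group %in% c("low", "neutral")
    if (model == "M2_signsplit") {
      if (pos_active) w[c("w1_pos", "w2_pos")] <- runif1(priors$w_active)
      if (neg_active) w[c("w1_neg", "w2_neg")] <- runif1(priors$w_active)
    } else {
      w2_range <- priors$w_active_second %||% priors$w_active
      if (pos_active) {
        w["w1_pos"] <- runif1(priors$w_active)
        w["w2_pos"] <- runif1(w2_range)
      }
      if (neg_active) {
        w["w1_neg"] <- runif1(priors$w_active)
        w["w2_neg"] <- runif1(w2_range)
      }
    }
  }
  ground_truth_observer(
    alpha = alpha, p0 = p0, gamma = gamma, empathy_t0 = t0,
    w1_pos = w[["w1_pos"]], w1_neg = w[["w1_neg"]],
    w2_pos = w[["w2_pos"]], w2_neg = w[["w2_neg"]],
    pred_noise_sd = priors$pred_noise_sd,
    empathy_noise_sd = priors$empathy_noise_sd,
    nonpain_t0 = priors$nonpain_t0,
    group = group
  )
}

#' Simulate one synthetic participant
#'
#' Forward-runs the generative models over a trial schedule. Baseline empathy
#' ratings are drawn around \code{empathy_t0} (painful) and \code{nonpain_t0}
#' (non-painful). Demonstrator ratings (if not supplied) are generated by the
#' pre-defined algorithm anchored to the participant's realized baseline
#' means. Predictions for painful trials follow the Rescorla-Wagner
#' recursion over the painful-trial demonstrator series plus report noise
#' (the pain-intensity cue precedes each prediction, so painful-trial
#' expectations form their own series); predictions for non-painful trials
#' are anchored at the realized baseline non-painful mean plus noise.
#' Empathy ratings for painful learning trials follow the discounted
#' prediction-error update rule on the true (noise-free) prediction errors
#' plus report noise; generalization-session painful ratings persist at the
#' final learned empathy level. All emitted
#' ratings are clipped to 0-100. Ground truth (internal prediction
#' trajectory, prediction errors, model empathy trajectory and realized
#' baseline means) is stored alongside for recovery analyses.
#'
#' @param observer A \code{\link{ground_truth_observer}}.
#' @param schedule Optional schedule; generated from \code{spec} if NULL.
#' @param demonstrator_ratings Optional vector of demonstrator ratings (one
#'   per learning trial); generated if NULL.
#' @param spec Schedule specification used when \code{schedule} is NULL.
#' @param seed Integer seed for all of this participant's random draws.
#' @param participant_id Identifier stored in the trial table.
#' @param half_boundary Learning-session trial index separating the first-half
#'   weights (\code{w1_*}) from the second-half weights (\code{w2_*}).
#' @param demonstrator_group Demonstrator regime for the rating algorithm;
#'   NULL (default) uses the observer's own group. Setting it to
#'   \code{"neutral"} pairs, e.g., positively-weighted observers with
#'   unshifted demonstrators, which recovery studies use to obtain
#'   prediction errors of both signs.
#' @param prediction_series \code{"all"} (default): one Rescorla-Wagner
#'   process over the full learning series in presentation order;
#'   \code{"painful_only"}: the process tracks painful trials alone and
#'   non-painful predictions are anchored at the baseline non-painful mean.
#'   Note that under the published schedule the default drags the single
#'   prediction state between the painful and (much lower) non-painful
#'   rating levels, which keeps painful-trial prediction errors
#'   predominantly positive in both groups; simulations that need negative
#'   learning signals should use an all-painful learning schedule or the
#'   painful-only series.
#' @return An object of class \code{participant_data}: a list with elements
#'   \code{trials} (tidy per-trial data frame), \code{truth} (generative
#'   ground truth) and \code{spec}.
#' @export
simulate_participant <- function(observer,
                                 schedule = NULL,
                                 demonstrator_ratings = NULL,
                                 spec = trial_schedule_spec(),
                                 seed = 1L,
                                 participant_id = "S01",
                                 half_boundary = 24L,
                                 demonstrator_group = NULL,
                                 prediction_series = c("all", "painful_only")) {
  prediction_series <- match.arg(prediction_series)
  if (!inherits(observer, "ground_truth_observer")) {
    stop("'observer' must be a ground_truth_observer", call. = FALSE)
  }
  if (is.null(schedule)) {
    spec$seed <- child_seed(seed, 1L)
    schedule <- generate_schedule(spec)
  }
  trials <- schedule
  n <- nrow(trials)
  trials$participant_id <- participant_id
  trials$group <- observer$group
  trials$demonstrator_rating <- NA_real_
  trials$prediction <- NA_real_
  trials$empathy_rating <- NA_real_

  is_base <- trials$session == "baseline"
  is_learn <- trials$session == "learning"
  is_gen <- trials$session == "generalization"
  is_pain <- trials$pain == "painful"

  set.seed(child_seed(seed, 2L))

  # baseline ratings around the ground-truth levels
  trials$empathy_rating[is_base] <- clip_rating(
    ifelse(is_pain[is_base], observer$empathy_t0, observer$nonpain_t0) +
      stats::rnorm(sum(is_base), 0, observer$empathy_noise_sd))
  base_mean_pain <- mean(trials$empathy_rating[is_base & is_pain])
  base_mean_nonpain <- mean(trials$empathy_rating[is_base & !is_pain])

  if (is.null(demonstrator_ratings)) {
    algo <- demonstrator_algorithm(
      group = demonstrator_group %||% observer$group,
      baseline_mean_pain = base_mean_pain,
      baseline_mean_nonpain = base_mean_nonpain,
      seed = child_seed(seed, 3L)
    )
    demonstrator_ratings <- generate_demonstrator_ratings(algo, schedule)
  }
  n_learn <- sum(is_learn)
  if (length(demonstrator_ratings) != n_learn) {
    stop("'demonstrator_ratings' must have one value per learning trial",
         call. = FALSE)
  }
  trials$demonstrator_rating[is_learn] <- demonstrator_ratings

  # internal RW prediction trajectory and true observational PEs; the
  # demonstrator rates painful and non-painful trials alike, so by default a
  # single prediction process runs over the whole learning series in
  # presentation order; prediction_series = "painful_only" tracks painful
  # trials alone and anchors non-painful predictions at the baseline
  # non-painful mean
  learn_pain_idx <- which(is_learn & is_pain)
  pain_in_learn <- is_pain[is_learn]
  set.seed(child_seed(seed, 4L))
  if (prediction_series == "all") {
    fwd <- rw_forward(rw_params(alpha = observer$alpha, p0 = observer$p0),
                      demonstrator_ratings)
    trials$prediction[is_learn] <- clip_rating(
      fwd$p + stats::rnorm(n_learn, 0, observer$pred_noise_sd))
    pe_pain <- fwd$pe[pain_in_learn]
  } else {
    fwd <- rw_forward(rw_params(alpha = observer$alpha, p0 = observer$p0),
                      demonstrator_ratings[pain_in_learn])
    pred <- numeric(n_learn)
    pred[pain_in_learn] <- fwd$p
    pred[!pain_in_learn] <- base_mean_nonpain
    trials$prediction[is_learn] <- clip_rating(
      pred + stats::rnorm(n_learn, 0, observer$pred_noise_sd))
    pe_pain <- fwd$pe
  }
  t_idx <- trials$trial_index[learn_pain_idx]
  mspec <- update_model_spec("M3_signsplit_halfsplit",
                             half_boundary = half_boundary)
  params <- update_params(
    weights = c(W1_pos = observer$w1_pos, W1_neg = observer$w1_neg,
                W2_pos = observer$w2_pos, W2_neg = observer$w2_neg),
    gamma = observer$gamma, empathy_t0 = observer$empathy_t0,
    sigma_emp = max(observer$empathy_noise_sd, 1e-9)
  )
  e_traj <- predict_empathy(mspec, params, pe_pain, trial_index = t_idx)
  set.seed(child_seed(seed, 5L))
  trials$empathy_rating[learn_pain_idx] <- clip_rating(
    e_traj + stats::rnorm(length(e_traj), 0, observer$empathy_noise_sd))
  learn_nonpain_idx <- which(is_learn & !is_pain)
  trials$empathy_rating[learn_nonpain_idx] <- clip_rating(
    observer$nonpain_t0 +
      stats::rnorm(length(learn_nonpain_idx), 0, observer$empathy_noise_sd))

  # learned empathy level persists into the generalization session
  e_final <- if (length(e_traj)) e_traj[length(e_traj)] else observer$empathy_t0
  set.seed(child_seed(seed, 6L))
  trials$empathy_rating[is_gen] <- clip_rating(
    ifelse(is_pain[is_gen], e_final, observer$nonpain_t0) +
      stats::rnorm(sum(is_gen), 0, observer$empathy_noise_sd))

  cols <- c("participant_id", "group", "session", "block", "trial_index",
            "pain", "recipient_id", "demonstrator_rating", "prediction",
            "empathy_rating")
  trials <- trials[, cols]
  structure(list(
    trials = trials,
    truth = list(
      observer = observer,
      prediction_trajectory = fwd$p,   # painful-trial series
      prediction_errors = fwd$pe,      # painful-trial series
      pe_painful = pe_pain,
      empathy_trajectory = e_traj,
      painful_trial_index = t_idx,
      baseline_mean_pain = base_mean_pain,
      baseline_mean_nonpain = base_mean_nonpain
    ),
    spec = spec,
    seed = as.integer(seed)
  ), class = "participant_data")
}

#' Simulate a synthetic cohort
#'
#' Draws ground-truth observers from \code{\link{observer_priors}} and
#' forward-simulates each through the full three-session task, with an
#' independent seeded stream per participant so the whole cohort is
#' reproducible from the master seed. Per-participant pre/post helping-time
#' and pain-intensity scores are generated coupled to the participant's
#' simulated empathy change (generalization minus baseline painful mean), so
#' that downstream correlation analyses have a known positive association.
#'
#' @param n_per_group Number of participants per group.
#' @param priors An \code{\link{observer_priors}} object.
#' @param spec A \code{\link{trial_schedule_spec}}.
#' @param seed Master seed.
#' @param model Generative update model: \code{"M1_single"},
#'   \code{"M2_signsplit"} or \code{"M3_signsplit_halfsplit"}.
#' @param groups Character vector of groups to simulate (default high + low).
#' @param demonstrator_group Optional demonstrator regime override (see
#'   \code{\link{simulate_participant}}).
#' @param prediction_series Prediction-series mode (see
#'   \code{\link{simulate_participant}}).
#' @return An object of class \code{cohort}: list with \code{trials} (stacked
#'   tidy trial table), \code{participants} (one row per participant with
#'   ground-truth parameters and pre/post questionnaire scores) and
#'   \code{data} (list of \code{participant_data}).
#' @export
simulate_cohort <- function(n_per_group = 26L,
                            priors = observer_priors(),
                            spec = trial_schedule_spec(),
                            seed = 1L,
                            model = "M3_signsplit_halfsplit",
                            groups = c("high", "low"),
                            demonstrator_group = NULL,
                            prediction_series = "all") {
  assert_positive_count(n_per_group, "n_per_group")
  if (!inherits(priors, "observer_priors")) {
    stop("'priors' must be an observer_priors object", call. = FALSE)
  }
  groups <- match.arg(groups, c("high", "low", "neutral"), several.ok = TRUE)

  grid <- expand.grid(j = seq_len(n_per_group), group = groups,
                      stringsAsFactors = FALSE)
  data <- vector("list", nrow(grid))
  rows <- vector("list", nrow(grid))
  for (i in seq_len(nrow(grid))) {
    g <- grid$group[i]
    pid <- sprintf("S%03d", i)
    obs <- draw_observer(priors, g, model, seed = child_seed(seed, 10L + i))
    pd <- simulate_participant(obs, spec = spec,
                               seed = child_seed(seed, 5000L + i),
                               participant_id = pid,
                               demonstrator_group = demonstrator_group,
                               prediction_series = prediction_series)
    data[[i]] <- pd
    rows[[i]] <- data.frame(
      participant_id = pid, group = g, model = model,
      alpha = obs$alpha, p0 = obs$p0, gamma = obs$gamma,
      empathy_t0 = obs$empathy_t0,
      w1_pos = obs$w1_pos, w1_neg = obs$w1_neg,
      w2_pos = obs$w2_pos, w2_neg = obs$w2_neg,
      pred_noise_sd = obs$pred_noise_sd,
      empathy_noise_sd = obs$empathy_noise_sd,
      baseline_mean_pain = pd$truth$baseline_mean_pain,
      baseline_mean_nonpain = pd$truth$baseline_mean_nonpain,
      stringsAsFactors = FALSE
    )
  }
  participants <- do.call(rbind, rows)
  trials <- do.call(rbind, lapply(data, function(p) p$trials))
  rownames(participants) <- rownames(trials) <- NULL

  # pre/post helping minutes and pain-intensity, coupled to empathy change
  chg <- change_scores_from_trials(trials)
  participants <- merge(participants, chg[, c("participant_id", "empathy_change")],
                        by = "participant_id", sort = FALSE)
  set.seed(child_seed(seed, 999983L))
  n_all <- nrow(participants)
  sd_chg <- stats::sd(participants$empathy_change)
  if (!is.finite(sd_chg) || sd_chg == 0) sd_chg <- 4
  helping_noise <- 0.5 * sd_chg * sqrt(1 / 0.345^2 - 1)
  participants$pre_helping <- round(stats::runif(n_all, 10, 40))
  participants$post_helping <- pmin(60, pmax(0,
    participants$pre_helping + 0.5 * participants$empathy_change +
      stats::rnorm(n_all, 0, helping_noise)))
  participants$pre_pain_intensity <- pmin(9, pmax(1,
    round(stats::rnorm(n_all, 6.5, 0.8), 1)))
  participants$post_pain_intensity <- pmin(9, pmax(1,
    participants$pre_pain_intensity + 0.04 * participants$empathy_change +
      stats::rnorm(n_all, 0, 0.4)))
  participants$empathy_change <- NULL

  structure(list(trials = trials, participants = participants, data = data,
                 spec = spec, seed = as.integer(seed), model = model,
                 priors = priors),
            class = "cohort")
}

#' @export
print.cohort <- function(x, ...) {
  cat(sprintf("Synthetic cohort: %d participants (%s), generative model %s\n",
              nrow(x$participants),
              paste(sprintf("%d %s", table(x$participants$group),
                            names(table(x$participants$group))),
                    collapse = ", "),
              x$model))
  invisible(x)
}
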