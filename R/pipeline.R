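#' Default run configuration
#'
#' Plain-list configuration binding all pipeline stages. It can be written
#' to / read from YAML (\code{\link{read_run_config}}) and mirrors the
#' study design: a 52-participant cohort (26 per group), the published
#' trial schedule, and the three-model candidate family.
#'
#' @param seed Master seed; every source of randomness in a run flows from
#'   it through named child streams.
#' @return A named list of class \code{run_config}.
#' @export
default_run_config <- function(seed = 1L) {
  structure(list(
    seed = as.integer(seed),
    schedule = unclass(trial_schedule_spec()),
    cohort = list(n_per_group = 26L, groups = c("high", "low"),
                  model = "M3_signsplit_halfsplit"),
    priors = unclass(observer_priors()),
    fitting = list(models = c("M1_single", "M2_signsplit",
                              "M3_signsplit_halfsplit"),
                   n_starts = 10L, r2_method = "pearson",
                   half_boundary = 24L, rw_series = "all"),
    selection = list(n_samples = 1e5),
    recover = list(n_subjects = 50L, n_cohorts = 3L, n_per_cohort = 26L,
                   group = "high", demonstrator_group = "neutral",
                   pred_noise_sd = 5, empathy_noise_sd = 5),
    output_dir = "runs"
  ), class = "run_config")
}

#' Read a run configuration from YAML
#'
#' Fields present in the file override the defaults; everything else keeps
#' its default value. The seed is mandatory (either in the file or via the
#' default).
#'
#' @param path Path to a YAML file, or NULL for pure defaults.
#' @param overrides Named list applied on top of the file.
#' @return A validated \code{run_config}.
#' @export
read_run_config <- function(path = NULL, overrides = list()) {
  cfg <- default_run_config()
  merge_into <- function(base, new) {
    for (nm in names(new)) {
      if (is.list(new[[nm]]) && is.list(base[[nm]])) {
        base[[nm]] <- merge_into(base[[nm]], new[[nm]])
      } else {
        base[[nm]] <- new[[nm]]
      }
    }
    base
  }
  if (!is.null(path)) cfg <- merge_into(cfg, yaml::read_yaml(path))
  cfg <- merge_into(cfg, overrides)
  validate_run_config(cfg)
  structure(cfg, class = "run_config")
}

validate_run_config <- function(cfg) {
  if (is.null(cfg$seed) || !is.finite(cfg$seed)) {
    stop("configuration error: 'seed' is mandatory", call. = FALSE)
  }
  if (is.null(cfg$cohort$n_per_group) || cfg$cohort$n_per_group < 1) {
    stop("configuration error: 'cohort$n_per_group' must be >= 1", call. = FALSE)
  }
  do.call(trial_schedule_spec, cfg$schedule)     # re-validates counts
  do.call(observer_priors, cfg$priors)           # re-validates ranges
  invisible(cfg)
}

config_schedule <- function(cfg) do.call(trial_schedule_spec, cfg$schedule)
config_priors <- function(cfg) do.call(observer_priors, cfg$priors)

# ---- file I/O ---------------------------------------------------------------

trial_csv_columns <- c("participant_id", "group", "session", "block",
                       "trial_index", "pain", "recipient_id",
                       "demonstrator_rating", "prediction", "empathy_rating")

#' Write / read the tidy trial CSV
#'
#' One row per trial; empty fields mark non-applicable cells (e.g. no
#' demonstrator rating outside the learning session). The same schema is
#' shared by the simulator and the fitting stages, so externally collected
#' data converted to this schema can be fed through unchanged.
#'
#' @param trials Tidy trial table.
#' @param path Output/input CSV path.
#' @return \code{read_trials_csv} returns the validated data frame.
#' @export
write_trials_csv <- function(trials, path) {
  utils::write.csv(trials[, trial_csv_columns], path, row.names = FALSE,
                   na = "")
  invisible(path)
}

#' @rdname write_trials_csv
#' @export
read_trials_csv <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing <- setdiff(trial_csv_columns, names(d))
  if (length(missing)) {
    stop(sprintf("malformed trial CSV '%s': missing column(s) %s",
                 path, paste(missing, collapse = ", ")), call. = FALSE)
  }
  for (col in c("demonstrator_rating", "prediction", "empathy_rating")) {
    d[[col]] <- as.numeric(d[[col]])
  }
  d
}

config_hash <- function(cfg) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  jsonlite::write_json(unclass(cfg), tmp, auto_unbox = TRUE, digits = NA)
  unname(tools::md5sum(tmp))
}

write_manifest <- function(cfg, files, out_dir) {
  manifest <- list(
    package_version = as.character(utils::packageVersion("empathylearn")),
    config_hash = config_hash(cfg),
    seed = cfg$seed,
    created = format(Sys.time(), tz = "UTC", usetz = TRUE),
    files = files
  )
  path <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(manifest)
}

# ---- pipeline stages --------------------------------------------------------

#' Simulate a cohort and write its artifacts
#'
#' @param config A \code{run_config}.
#' @param out_dir Output directory (created if needed); NULL returns the
#'   cohort without writing files.
#' @return The simulated \code{cohort}, invisibly when writing.
#' @export
cmd_simulate <- function(config = default_run_config(), out_dir = NULL) {
  validate_run_config(config)
  cohort <- simulate_cohort(
    n_per_group = config$cohort$n_per_group,
    priors = config_priors(config),
    spec = config_schedule(config),
    seed = config$seed,
    model = config$cohort$model,
    groups = config$cohort$groups
  )
  if (is.null(out_dir)) return(cohort)
  if (!dir.exists(out_dir) && !dir.create(out_dir, recursive = TRUE)) {
    stop(sprintf("cannot create output directory '%s'", out_dir), call. = FALSE)
  }
  trials_path <- file.path(out_dir, "trials.csv")
  participants_path <- file.path(out_dir, "participants.csv")
  write_trials_csv(cohort$trials, trials_path)
  utils::write.csv(cohort$participants, participants_path, row.names = FALSE)
  write_manifest(config, c(trials_path, participants_path), out_dir)
  invisible(cohort)
}

#' Fit the Rescorla-Wagner and empathy-update models to one participant
#'
#' Runs the full per-participant modeling pass used by \code{\link{cmd_fit}}:
#' the baseline painful-trial mean fixes \code{empathy_t0} and centers the
#' \code{p0} prior; the Rescorla-Wagner model is fitted to the prediction
#' series over all learning trials in presentation order (the demonstrator
#' rates painful and non-painful trials alike), or over painful trials only
#' with \code{rw_series = "painful_only"}; its MAP prediction errors on
#' painful trials feed each candidate empathy-update model.
#'
#' @param trials Trial table rows for one participant.
#' @param models Character vector of candidate model ids.
#' @param n_starts,r2_method,half_boundary Fitting options.
#' @param rw_series \code{"all"} or \code{"painful_only"} prediction series.
#' @param seed Seed for the optimization restarts.
#' @return List with \code{rw} (\code{rw_fit}), \code{updates} (named list
#'   of \code{update_fit}), \code{evidence} (named LAME vector including the
#'   RW fit), \code{empathy_t0} and \code{pe_table}.
#' @export
fit_participant <- function(trials,
                            models = c("M1_single", "M2_signsplit",
                                       "M3_signsplit_halfsplit"),
                            n_starts = 10L, r2_method = "pearson",
                            half_boundary = 24L,
                            rw_series = c("all", "painful_only"),
                            seed = 1L) {
  rw_series <- match.arg(rw_series)
  learn <- trials[trials$session == "learning", , drop = FALSE]
  learn <- learn[order(learn$trial_index), , drop = FALSE]
  base_pain <- trials$empathy_rating[trials$session == "baseline" &
                                       trials$pain == "painful"]
  empathy_t0 <- mean(base_pain, na.rm = TRUE)
  if (!is.finite(empathy_t0)) {
    stop("no baseline painful-trial ratings for this participant", call. = FALSE)
  }
  rw_rows <- if (rw_series == "all") learn else
    learn[learn$pain == "painful", , drop = FALSE]
  rw <- fit_rw(rw_rows$prediction, rw_rows$demonstrator_rating,
               priors = rw_priors(p0_mean = empathy_t0),
               n_starts = n_starts, seed = child_seed(seed, 1L),
               r2_method = r2_method)
  pe_tab <- prediction_errors_table(rw, rw_rows)
  pain_pe <- pe_tab[pe_tab$pain == "painful", , drop = FALSE]
  pain_rows <- learn[learn$pain == "painful", , drop = FALSE]
  updates <- list()
  for (i in seq_along(models)) {
    m <- models[i]
    spec_m <- update_model_spec(m, half_boundary = half_boundary)
    updates[[m]] <- fit_update_model(
      empathy_ratings = pain_rows$empathy_rating,
      pe_series = pain_pe$pe,
      spec = spec_m,
      priors = update_priors(empathy_t0 = empathy_t0),
      trial_index = pain_rows$trial_index,
      n_starts = n_starts, seed = child_seed(seed, 10L + i),
      r2_method = r2_method
    )
  }
  list(rw = rw, updates = updates,
       evidence = vapply(updates, function(f) f$lame, numeric(1)),
       empathy_t0 = empathy_t0, pe_table = pe_tab)
}

#' Fit all participants of a trial table
#'
#' Fits every participant independently; participants whose fit fails (e.g.
#' all predictions missing) are skipped with a message and recorded in
#' \code{failures}, and the run continues.
#'
#' @param trials Tidy trial table (data frame or CSV path).
#' @param config A \code{run_config}.
#' @param out_dir Optional output directory for per-participant fit JSONs,
#'   the evidence matrix CSV and fitted-parameter CSVs.
#' @return List with \code{fits} (per participant), \code{evidence} (matrix
#'   participants x models of LAME values), \code{rw_params},
#'   \code{update_params} (data frames of MAP estimates) and
#'   \code{failures}.
#' @export
cmd_fit <- function(trials, config = default_run_config(), out_dir = NULL) {
  if (is.character(trials)) trials <- read_trials_csv(trials)
  validate_run_config(config)
  models <- config$fitting$models
  ids <- unique(trials$participant_id)
  fits <- list()
  failures <- character(0)
  for (i in seq_along(ids)) {
    id <- ids[i]
    res <- tryCatch(
      fit_participant(trials[trials$participant_id == id, , drop = FALSE],
                      models = models,
                      n_starts = config$fitting$n_starts,
                      r2_method = config$fitting$r2_method,
                      half_boundary = config$fitting$half_boundary,
                      rw_series = config$fitting$rw_series %||% "all",
                      seed = child_seed(config$seed, 20000L + i)),
      error = function(e) {
        message(sprintf("fit failed for participant %s: %s", id,
                        conditionMessage(e)))
        NULL
      })
    if (is.null(res)) failures <- c(failures, id) else fits[[id]] <- res
  }
  if (!length(fits)) stop("all participant fits failed", call. = FALSE)
  evidence <- do.call(rbind, lapply(fits, function(f) f$evidence))
  rownames(evidence) <- names(fits)

  group_of <- trials$group[match(names(fits), trials$participant_id)]
  rw_params_df <- data.frame(
    participant_id = names(fits), group = group_of,
    alpha = vapply(fits, function(f) f$rw$map_params$alpha, numeric(1)),
    p0 = vapply(fits, function(f) f$rw$map_params$p0, numeric(1)),
    sigma_pred = vapply(fits, function(f) f$rw$map_params$sigma_pred, numeric(1)),
    r2 = vapply(fits, function(f) f$rw$r2, numeric(1)),
    row.names = NULL, stringsAsFactors = FALSE
  )
  upd_rows <- lapply(names(fits), function(id) {
    do.call(rbind, lapply(models, function(m) {
      f <- fits[[id]]$updates[[m]]
      w <- f$map_params$weights
      data.frame(participant_id = id,
                 group = group_of[match(id, names(fits))],
                 model = m, parameter = c(names(w), "gamma", "sigma_emp"),
                 value = c(unname(w), f$map_params$gamma,
                           f$map_params$sigma_emp),
                 lame = f$lame, r2 = f$r2,
                 stringsAsFactors = FALSE)
    }))
  })
  update_params_df <- do.call(rbind, upd_rows)

  if (!is.null(out_dir)) {
    if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
    utils::write.csv(data.frame(participant_id = rownames(evidence),
                                evidence, check.names = FALSE),
                     file.path(out_dir, "evidence.csv"), row.names = FALSE)
    utils::write.csv(rw_params_df, file.path(out_dir, "rw_params.csv"),
                     row.names = FALSE)
    utils::write.csv(update_params_df,
                     file.path(out_dir, "update_params.csv"), row.names = FALSE)
    fit_dir <- file.path(out_dir, "fits")
    if (!dir.exists(fit_dir)) dir.create(fit_dir)
    for (id in names(fits)) {
      f <- fits[[id]]
      jsonlite::write_json(list(
        participant_id = id,
        rw = list(alpha = f$rw$map_params$alpha, p0 = f$rw$map_params$p0,
                  sigma_pred = f$rw$map_params$sigma_pred,
                  lpp = f$rw$lpp, lame = f$rw$lame, r2 = f$rw$r2,
                  flags = f$rw$flags),
        updates = lapply(f$updates, function(u) list(
          model_id = u$spec$model_id,
          weights = as.list(u$map_params$weights),
          gamma = u$map_params$gamma,
          empathy_t0 = u$map_params$empathy_t0,
          sigma_emp = u$map_params$sigma_emp,
          lpp = u$lpp, lame = u$lame, r2 = u$r2, flags = u$flags))
      ), file.path(fit_dir, paste0(id, ".json")),
      auto_unbox = TRUE, digits = NA, pretty = TRUE)
    }
  }
  list(fits = fits, evidence = evidence, rw_params = rw_params_df,
       update_params = update_params_df, failures = failures)
}

#' Group-level model selection stage
#'
#' @param evidence Evidence matrix (participants x models) or path to an
#'   evidence CSV written by \code{\link{cmd_fit}}.
#' @param config A \code{run_config} (supplies Monte-Carlo sample count and
#'   seed).
#' @param out_dir Optional directory for \code{bms.json}.
#' @return List with \code{random_effects} (\code{bms_result}) and
#'   \code{fixed_effects}.
#' @export
cmd_select <- function(evidence, config = default_run_config(),
                       out_dir = NULL) {
  if (is.character(evidence)) {
    d <- utils::read.csv(evidence, check.names = FALSE)
    evidence <- as.matrix(d[, -1, drop = FALSE])
    rownames(evidence) <- d[[1]]
  }
  bms <- bms_random_effects(evidence,
                            n_samples = config$selection$n_samples,
                            seed = child_seed(config$seed, 777L))
  fx <- fixed_effects_comparison(evidence)
  if (!is.null(out_dir)) {
    if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
    jsonlite::write_json(list(
      dirichlet_alpha = as.list(bms$dirichlet_alpha),
      expected_frequencies = as.list(bms$expected_frequencies),
      exceedance_probability = as.list(bms$exceedance_probability),
      n_mc_samples = bms$n_mc_samples,
      fixed_effects_total = as.list(fx$total_log_evidence)
    ), file.path(out_dir, "bms.json"), auto_unbox = TRUE, digits = NA,
    pretty = TRUE)
  }
  list(random_effects = bms, fixed_effects = fx)
}

#' Model-independent behavioral statistics stage
#'
#' Computes the learning-trend contrasts, the pooled PE-to-empathy-change
#' regression and the empathy-change/helping-time correlation, and writes a
#' JSON report plus a short text summary.
#'
#' @param trials Tidy trial table (or CSV path).
#' @param participants Participant metadata table (or CSV path) with
#'   pre/post helping columns.
#' @param fit_result Result of \code{\link{cmd_fit}} (supplies prediction
#'   errors); if NULL, Rescorla-Wagner fits are computed on the fly.
#' @param config A \code{run_config}.
#' @param out_dir Optional output directory.
#' @return List with \code{trends_prediction}, \code{trends_empathy},
#'   \code{pe_regression} and \code{helping} results.
#' @export
cmd_stats <- function(trials, participants, fit_result = NULL,
                      config = default_run_config(), out_dir = NULL) {
  if (is.character(trials)) trials <- read_trials_csv(trials)
  if (is.character(participants)) {
    participants <- utils::read.csv(participants, stringsAsFactors = FALSE)
  }
  trends_pred <- tryCatch(fit_trends(trials, "prediction"),
                          error = function(e) e)
  trends_emp <- fit_trends(trials, "empathy")
  if (is.null(fit_result)) fit_result <- cmd_fit(trials, config)
  pe_tables <- lapply(fit_result$fits, function(f) f$pe_table)
  delta <- pe_delta_table(trials, pe_tables)
  pe_reg <- pe_change_regression(delta)
  chg <- change_scores_from_trials(trials)
  chg <- merge(chg, participants[, c("participant_id", "pre_helping",
                                     "post_helping")],
               by = "participant_id")
  chg$helping_change <- chg$post_helping - chg$pre_helping
  helping <- change_vs_helping(chg)

  report <- list(
    trends_prediction = if (inherits(trends_pred, "error")) {
      list(error = conditionMessage(trends_pred))
    } else {
      list(group_means = as.list(trends_pred$group_means),
           group_p = trends_pred$group_test$p.value)
    },
    trends_empathy = list(group_means = as.list(trends_emp$group_means),
                          group_p = trends_emp$group_test$p.value),
    pe_regression = list(slope = pe_reg$slope, se = pe_reg$se,
                         p = pe_reg$p_value),
    helping = list(overall_rho = helping$overall$rho,
                   overall_p = helping$overall$p_value,
                   by_group = lapply(helping$by_group,
                                     function(x) x[c("rho", "p_value")]))
  )
  if (!is.null(out_dir)) {
    if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
    jsonlite::write_json(report, file.path(out_dir, "stats_report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    txt <- c(
      "Behavioral summary",
      "==================",
      if (!inherits(trends_pred, "error")) {
        sprintf("Prediction slopes by group: %s (contrast p = %.3g)",
                paste(sprintf("%s %.3f", names(trends_pred$group_means),
                              trends_pred$group_means), collapse = ", "),
                trends_pred$group_test$p.value)
      } else sprintf("Prediction series: %s", conditionMessage(trends_pred)),
      sprintf("Empathy slopes by group: %s (contrast p = %.3g)",
              paste(sprintf("%s %.3f", names(trends_emp$group_means),
                            trends_emp$group_means), collapse = ", "),
              trends_emp$group_test$p.value),
      sprintf("PE -> empathy-change slope: %.3f (robust p = %.3g)",
              pe_reg$slope, pe_reg$p_value),
      sprintf("Empathy change vs helping change: rho = %.3f (p = %.3g)",
              helping$overall$rho, helping$overall$p_value)
    )
    writeLines(txt, file.path(out_dir, "stats_summary.txt"))
  }
  list(trends_prediction = trends_pred, trends_empathy = trends_emp,
       pe_regression = pe_reg, helping = helping, report = report)
}

# ---- recovery harness -------------------------------------------------------

#' Parameter recovery study
#'
#' Simulates synthetic observers with known parameters, runs the full
#' fitting pipeline (Rescorla-Wagner on predictions, then the generative
#' update model on empathy ratings), and correlates true with recovered
#' parameters. By default 50 high-group observers generated from the
#' sign-/half-split model at report noise SD 5, with the active influence
#' confined to the first-half weight (\code{w_active_second = c(0, 0)}), the
#' same regime the model-recovery study uses.
#'
#' @param n_subjects Number of synthetic observers.
#' @param priors \code{\link{observer_priors}} for the ground-truth draws.
#' @param spec Trial schedule specification.
#' @param seed Master seed.
#' @param model Generative (and fitted) update model.
#' @param group Demonstrator regime.
#' @param n_starts Optimization restarts per fit.
#' @return List with \code{table} (true and fitted parameters per subject)
#'   and \code{correlations} (named vector: alpha, active weight, gamma).
#' @export
recover_parameters <- function(n_subjects = 50L,
                               priors = observer_priors(
                                 pred_noise_sd = 5, empathy_noise_sd = 5,
                                 w_active_second = c(0, 0)),
                               spec = trial_schedule_spec(),
                               seed = 1L,
                               model = "M3_signsplit_halfsplit",
                               group = "high",
                               n_starts = 10L) {
  active_w <- switch(group, high = "w1_pos", low = "w1_neg", neutral = "w1_pos")
  fitted_w <- switch(group, high = "W1_pos", low = "W1_neg", neutral = "W1_pos")
  rows <- vector("list", n_subjects)
  for (i in seq_len(n_subjects)) {
    obs <- draw_observer(priors, group, model, seed = child_seed(seed, 100L + i))
    pd <- simulate_participant(obs, spec = spec,
                               seed = child_seed(seed, 4000L + i),
                               participant_id = sprintf("R%03d", i))
    fp <- fit_participant(pd$trials, models = model, n_starts = n_starts,
                          seed = child_seed(seed, 8000L + i))
    uf <- fp$updates[[model]]
    rows[[i]] <- data.frame(
      subject = i,
      true_alpha = obs$alpha, fit_alpha = fp$rw$map_params$alpha,
      true_w1 = obs[[active_w]],
      fit_w1 = uf$map_params$weights[[fitted_w]],
      true_gamma = obs$gamma, fit_gamma = uf$map_params$gamma,
      stringsAsFactors = FALSE
    )
  }
  tab <- do.call(rbind, rows)
  list(table = tab,
       correlations = c(
         alpha = stats::cor(tab$true_alpha, tab$fit_alpha),
         w1 = stats::cor(tab$true_w1, tab$fit_w1),
         gamma = stats::cor(tab$true_gamma, tab$fit_gamma)))
}

#' Model recovery study
#'
#' Simulates cohorts from each generative regime in the candidate family,
#' fits all candidate models to every synthetic participant, and runs
#' random-effects Bayesian model selection per cohort. Returns the
#' cohort-level confusion matrix (generative regime x selected model) and
#' the exceedance probability of the generating model in each cohort.
#'
#' The regimes are set up so that each model's distinctive structure is
#' actually expressed in the data it generates (a model-recovery study is
#' ill-posed otherwise): demonstrators are neutral (no group offset) and the
#' schedule uses painful learning trials only, so prediction errors of both
#' signs occur in comparable numbers (under a shifted demonstrator, or with
#' the low-rated non-painful trials interleaved in the prediction series,
#' painful-trial prediction errors are predominantly positive and the
#' single-weight and sign-split models become observationally equivalent);
#' observers carry positively-weighted ("high"-typical) update rules except
#' under M1, whose single weight applies to both signs; and the half-split
#' regime confines the active weight to the first half
#' (\code{w_active_second = c(0, 0)}), since half-split data generated with
#' equal first- and second-half weights are indistinguishable from
#' sign-split data.
#'
#' @param generative_models Regimes to simulate from.
#' @param n_cohorts Cohorts per regime.
#' @param n_per_cohort Participants per cohort.
#' @param priors Ground-truth sampling ranges.
#' @param spec Schedule specification.
#' @param seed Master seed.
#' @param group Weight-activity group of the simulated observers.
#' @param demonstrator_group Demonstrator regime (default neutral).
#' @param n_starts Optimization restarts per fit.
#' @param n_samples Dirichlet Monte-Carlo samples for the XP.
#' @return List with \code{confusion} (counts matrix) and \code{xp_table}
#'   (per-cohort winner and XP of the generating model).
#' @export
recover_models <- function(generative_models = c("M1_single", "M2_signsplit",
                                                 "M3_signsplit_halfsplit"),
                           n_cohorts = 3L, n_per_cohort = 26L,
                           priors = observer_priors(
                             pred_noise_sd = 5, empathy_noise_sd = 5,
                             w_active_second = c(0, 0)),
                           spec = trial_schedule_spec(pain_per_block = 12L),
                           seed = 1L, group = "high",
                           demonstrator_group = "neutral",
                           n_starts = 10L, n_samples = 1e5) {
  fitted_models <- c("M1_single", "M2_signsplit", "M3_signsplit_halfsplit")
  confusion <- matrix(0L, length(generative_models), length(fitted_models),
                      dimnames = list(generative_models, fitted_models))
  rows <- list()
  cfg <- default_run_config(seed)
  cfg$fitting$n_starts <- n_starts
  for (gi in seq_along(generative_models)) {
    gm <- generative_models[gi]
    for (ci in seq_len(n_cohorts)) {
      cohort_seed <- child_seed(seed, gi * 1000L + ci)
      cohort <- simulate_cohort(n_per_group = n_per_cohort, priors = priors,
                                spec = spec, seed = cohort_seed, model = gm,
                                groups = group,
                                demonstrator_group = demonstrator_group)
      cfg$seed <- cohort_seed
      fit <- cmd_fit(cohort$trials, cfg)
      bms <- bms_random_effects(fit$evidence, n_samples = n_samples,
                                seed = child_seed(cohort_seed, 99L))
      xp <- bms$exceedance_probability
      winner <- names(xp)[which.max(xp)]
      confusion[gm, winner] <- confusion[gm, winner] + 1L
      rows[[length(rows) + 1L]] <- data.frame(
        generative = gm, cohort = ci, winner = winner,
        xp_generative = unname(xp[gm]),
        stringsAsFactors = FALSE)
    }
  }
  list(confusion = confusion, xp_table = do.call(rbind, rows))
}

#' Recovery stage of the pipeline
#'
#' Runs the parameter- and model-recovery studies at the sizes given in the
#' configuration and writes their reports.
#'
#' @param config A \code{run_config}.
#' @param out_dir Optional output directory.
#' @return List with \code{parameters} and \code{models} recovery results.
#' @export
cmd_recover <- function(config = default_run_config(), out_dir = NULL) {
  validate_run_config(config)
  rc <- config$recover
  priors <- config_priors(config)
  priors$pred_noise_sd <- rc$pred_noise_sd
  priors$empathy_noise_sd <- rc$empathy_noise_sd
  priors$w_active_second <- c(0, 0)  # recovery regime: first-half influence
  par_rec <- recover_parameters(
    n_subjects = rc$n_subjects, priors = priors,
    spec = config_schedule(config), seed = child_seed(config$seed, 31L),
    n_starts = config$fitting$n_starts)
  # all-painful learning schedule: both PE signs occur, so sign-split
  # weights are identifiable (see ?recover_models)
  mr_schedule <- config$schedule
  mr_schedule$pain_per_block <- mr_schedule$trials_per_block
  mod_rec <- recover_models(
    n_cohorts = rc$n_cohorts, n_per_cohort = rc$n_per_cohort,
    priors = priors, spec = do.call(trial_schedule_spec, mr_schedule),
    seed = child_seed(config$seed, 37L), group = rc$group,
    demonstrator_group = rc$demonstrator_group,
    n_starts = config$fitting$n_starts,
    n_samples = config$selection$n_samples)
  if (!is.null(out_dir)) {
    if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
    utils::write.csv(par_rec$table,
                     file.path(out_dir, "parameter_recovery.csv"),
                     row.names = FALSE)
    utils::write.csv(as.data.frame(mod_rec$confusion),
                     file.path(out_dir, "model_recovery_confusion.csv"))
    utils::write.csv(mod_rec$xp_table,
                     file.path(out_dir, "model_recovery_xp.csv"),
                     row.names = FALSE)
    jsonlite::write_json(list(
      parameter_correlations = as.list(par_rec$correlations)),
      file.path(out_dir, "recovery_summary.json"),
      auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  list(parameters = par_rec, models = mod_rec)
}

#' Run the full pipeline
#'
#' Simulate, fit, select and summarize in one reproducible pass.
#'
#' @param config A \code{run_config}.
#' @param out_dir Output directory (stage subdirectories are created).
#' @param recover Also run the recovery stage (slow; default FALSE).
#' @return Named list of all stage results.
#' @export
run_all <- function(config = default_run_config(), out_dir = NULL,
                    recover = FALSE) {
  cohort <- cmd_simulate(config, out_dir)
  fit <- cmd_fit(cohort$trials, config,
                 if (!is.null(out_dir)) file.path(out_dir, "fit"))
  sel <- cmd_select(fit$evidence, config,
                    if (!is.null(out_dir)) file.path(out_dir, "select"))
  stats_res <- cmd_stats(cohort$trials, cohort$participants, fit, config,
                         if (!is.null(out_dir)) file.path(out_dir, "stats"))
  rec <- if (recover) {
    cmd_recover(config, if (!is.null(out_dir)) file.path(out_dir, "recover"))
  } else NULL
  list(cohort = cohort, fit = fit, selection = sel, stats = stats_res,
       recovery = rec)
}
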