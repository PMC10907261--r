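#' Per-participant learning trends by group
#'
#' Model-independent check of the learning effect: an ordinary least-squares
#' slope over trial number is computed per participant for the chosen series
#' (predictions of the demonstrator's ratings, or the participant's own
#' empathy ratings) on painful learning trials; groups are then contrasted
#' with a two-sample Welch t test on the slopes and each group's trend is
#' tested against zero with a one-sample t test. This is a deliberate
#' simplification of a mixed-model analysis: directions and group contrasts
#' are preserved while each participant contributes exactly one slope.
#'
#' @param trials Tidy trial table (see \code{\link{simulate_cohort}}).
#' @param series \code{"prediction"} or \code{"empathy"}.
#' @param pain_only Restrict to painful trials (default TRUE).
#' @return An object of class \code{trend_result}: \code{slopes} (data frame
#'   with \code{participant_id}, \code{group}, \code{slope}),
#'   \code{group_means}, \code{group_test} (Welch t test across groups, NULL
#'   if fewer than two groups) and \code{per_group_tests}.
#' @export
fit_trends <- function(trials, series = c("prediction", "empathy"),
                       pain_only = TRUE) {
  series <- match.arg(series)
  col <- if (series == "prediction") "prediction" else "empathy_rating"
  d <- trials[trials$session == "learning", , drop = FALSE]
  if (pain_only) d <- d[d$pain == "painful", , drop = FALSE]
  if (all(is.na(d[[col]]))) {
    stop(sprintf("series '%s' is absent from the trial table", series),
         call. = FALSE)
  }
  ids <- unique(d$participant_id)
  slopes <- lapply(ids, function(id) {
    di <- d[d$participant_id == id & !is.na(d[[col]]), , drop = FALSE]
    if (nrow(di) < 10L) {
      stop(sprintf("participant %s has fewer than 10 '%s' trials", id, series),
           call. = FALSE)
    }
    data.frame(participant_id = id, group = di$group[1],
               slope = unname(stats::coef(
                 stats::lm(di[[col]] ~ di$trial_index))[2]),
               stringsAsFactors = FALSE)
  })
  slopes <- do.call(rbind, slopes)
  groups <- unique(slopes$group)
  if (any(table(slopes$group) < 2L)) {
    stop("each group needs at least 2 participants", call. = FALSE)
  }
  safe_t <- function(expr) tryCatch(expr, error = function(e) NULL)
  group_means <- tapply(slopes$slope, slopes$group, mean)
  group_test <- if (length(groups) >= 2L) {
    safe_t(stats::t.test(slope ~ group,
                         data = slopes[slopes$group %in% groups[1:2], ]))
  } else NULL
  per_group <- lapply(stats::setNames(groups, groups), function(g) {
    safe_t(stats::t.test(slopes$slope[slopes$group == g]))
  })
  structure(list(series = series, slopes = slopes,
                 group_means = group_means, group_test = group_test,
                 per_group_tests = per_group),
            class = "trend_result")
}

#' @export
print.trend_result <- function(x, ...) {
  cat(sprintf("Learning trends (%s series, painful trials)\n", x$series))
  for (g in names(x$group_means)) {
    tt <- x$per_group_tests[[g]]
    if (is.null(tt)) {
      cat(sprintf("  %s: mean slope %.3f/trial (degenerate: constant slopes)\n",
                  g, x$group_means[[g]]))
    } else {
      cat(sprintf("  %s: mean slope %.3f/trial (t = %.2f, p = %.3g)\n",
                  g, x$group_means[[g]], tt$statistic, tt$p.value))
    }
  }
  if (!is.null(x$group_test)) {
    cat(sprintf("  group contrast: t = %.2f, p = %.3g\n",
                x$group_test$statistic, x$group_test$p.value))
  }
  invisible(x)
}

#' Per-trial empathy changes paired with prediction errors
#'
#' Builds the table used by \code{\link{pe_change_regression}}: for each
#' participant, the change in empathy rating between consecutive painful
#' learning trials, paired with the observational prediction error of the
#' later trial.
#'
#' @param trials Tidy trial table.
#' @param pe_tables Named list (by participant id) of prediction-error
#'   tables from \code{\link{prediction_errors_table}}.
#' @return Data frame with \code{participant_id}, \code{group},
#'   \code{trial_index}, \code{pe} and \code{d_empathy}.
#' @export
pe_delta_table <- function(trials, pe_tables) {
  ids <- unique(trials$participant_id)
  out <- lapply(ids, function(id) {
    d <- trials[trials$participant_id == id & trials$session == "learning" &
                  trials$pain == "painful", , drop = FALSE]
    d <- d[order(d$trial_index), , drop = FALSE]
    pe_tab <- pe_tables[[id]]
    pe <- pe_tab$pe[match(d$trial_index, pe_tab$trial_index)]
    n <- nrow(d)
    if (n < 2L) return(NULL)
    data.frame(participant_id = id, group = d$group[1],
               trial_index = d$trial_index[-1],
               pe = pe[-1],
               d_empathy = diff(d$empathy_rating),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Pooled regression of empathy changes on prediction errors
#'
#' Pooled ordinary least-squares regression of trial-wise empathy changes on
#' trial-wise observational prediction errors, with participant-clustered
#' robust standard errors. An optional grouping factor (e.g. a study label
#' contrasting human- and computer-demonstrator cohorts) enters as an
#' interaction, testing whether the PE-to-change coupling differs between
#' levels.
#'
#' @param data Data frame from \code{\link{pe_delta_table}} (columns
#'   \code{participant_id}, \code{pe}, \code{d_empathy}, plus any factor
#'   named by \code{interaction}).
#' @param interaction Optional column name whose interaction with \code{pe}
#'   is estimated.
#' @return List with \code{slope}, \code{se}, \code{p_value} (cluster-robust,
#'   for the pooled PE slope), \code{interaction} (coefficient row for the
#'   interaction term, if requested), \code{coefficients} (full robust
#'   coefficient table) and \code{model}.
#' @export
pe_change_regression <- function(data, interaction = NULL) {
  if (length(unique(data$participant_id)) < 2L) {
    stop("need at least 2 participants", call. = FALSE)
  }
  if (is.null(interaction)) {
    m <- stats::lm(d_empathy ~ pe, data = data)
  } else {
    if (!interaction %in% names(data)) {
      stop(sprintf("column '%s' not found", interaction), call. = FALSE)
    }
    data[[interaction]] <- factor(data[[interaction]])
    m <- stats::lm(stats::reformulate(c("pe", interaction,
                                        paste0("pe:", interaction)),
                                      response = "d_empathy"),
                   data = data)
  }
  vc <- sandwich::vcovCL(m, cluster = data$participant_id)
  ct <- lmtest::coeftest(m, vcov. = vc)
  inter_row <- NULL
  if (!is.null(interaction)) {
    idx <- grep("^pe:", rownames(ct))
    if (length(idx)) inter_row <- ct[idx, , drop = FALSE]
  }
  list(slope = ct["pe", "Estimate"],
       se = ct["pe", "Std. Error"],
       p_value = ct["pe", "Pr(>|t|)"],
       interaction = inter_row,
       coefficients = ct,
       model = m)
}

#' Session change scores from the trial table
#'
#' Empathy change is the generalization-session mean minus the
#' baseline-session mean of the painful-trial empathy ratings, per
#' participant.
#'
#' @param trials Tidy trial table.
#' @return Data frame with \code{participant_id}, \code{group} and
#'   \code{empathy_change}.
#' @export
change_scores_from_trials <- function(trials) {
  pain <- trials[trials$pain == "painful", , drop = FALSE]
  ids <- unique(pain$participant_id)
  out <- lapply(ids, function(id) {
    d <- pain[pain$participant_id == id, , drop = FALSE]
    data.frame(
      participant_id = id,
      group = d$group[1],
      empathy_change = mean(d$empathy_rating[d$session == "generalization"]) -
        mean(d$empathy_rating[d$session == "baseline"]),
      stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Empathy change versus willingness to help
#'
#' Spearman rank correlation between the baseline-to-generalization change
#' in empathy ratings and the pre-to-post change in the time participants
#' are willing to spend helping the pain recipient, overall and per group.
#'
#' @param change_scores Data frame with \code{participant_id}, \code{group},
#'   \code{empathy_change} and \code{helping_change}.
#' @return List with \code{overall} (\code{rho}, \code{p_value}, \code{n})
#'   and \code{by_group}. A zero-variance score yields \code{rho = NA} with
#'   flag \code{"zero_variance"}.
#' @export
change_vs_helping <- function(change_scores) {
  req <- c("empathy_change", "helping_change")
  if (!all(req %in% names(change_scores))) {
    stop("'change_scores' needs empathy_change and helping_change columns",
         call. = FALSE)
  }
  spearman <- function(d, strict = TRUE) {
    if (nrow(d) < 5L) {
      if (strict) stop("need at least 5 participants", call. = FALSE)
      return(list(rho = NA_real_, p_value = NA_real_, n = nrow(d),
                  flag = "too_few"))
    }
    if (stats::sd(d$empathy_change) == 0 || stats::sd(d$helping_change) == 0) {
      return(list(rho = NA_real_, p_value = NA_real_, n = nrow(d),
                  flag = "zero_variance"))
    }
    ct <- suppressWarnings(
      stats::cor.test(d$empathy_change, d$helping_change,
                      method = "spearman", exact = FALSE))
    list(rho = unname(ct$estimate), p_value = ct$p.value, n = nrow(d),
         flag = NULL)
  }
  by_group <- lapply(split(change_scores, change_scores$group), spearman,
                     strict = FALSE)
  list(overall = spearman(change_scores), by_group = by_group)
}
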