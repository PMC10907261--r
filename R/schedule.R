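#' Trial schedule specification
#'
#' Defines the three-session structure of the observational-learning-of-empathy
#' task: a baseline rating session, a blocked learning session in which the
#' participant observes a demonstrator's empathy ratings, and a generalization
#' session with a new pain recipient.
#'
#' The defaults reproduce the published design: a baseline session of 18
#' painful and 12 non-painful video trials, a learning session of 4 blocks of
#' 12 trials each (9 painful + 3 non-painful per block, i.e. 36 painful and 12
#' non-painful trials in total), and a generalization session mirroring the
#' baseline with a new recipient.
#'
#' @param n_baseline_pain Number of painful baseline trials.
#' @param n_baseline_nonpain Number of non-painful baseline trials.
#' @param n_learning_blocks Number of learning blocks.
#' @param trials_per_block Trials per learning block.
#' @param pain_per_block Painful trials per learning block.
#' @param n_generalization_pain Painful generalization trials.
#' @param n_generalization_nonpain Non-painful generalization trials.
#' @param n_recipients_learning Number of distinct pain recipients across the
#'   learning blocks; blocks are split evenly between recipients.
#' @param seed Integer seed controlling the within-session trial ordering.
#' @return An object of class \code{trial_schedule_spec}.
#' @seealso \code{\link{generate_schedule}}
#' @export
trial_schedule_spec <- function(n_baseline_pain = 18L,
                                n_baseline_nonpain = 12L,
                                n_learning_blocks = 4L,
                                trials_per_block = 12L,
                                pain_per_block = 9L,
                                n_generalization_pain = 18L,
                                n_generalization_nonpain = 12L,
                                n_recipients_learning = 2L,
                                seed = 1L) {
  spec <- list(
    n_baseline_pain = assert_positive_count(n_baseline_pain, "n_baseline_pain"),
    n_baseline_nonpain = assert_positive_count(n_baseline_nonpain, "n_baseline_nonpain"),
    n_learning_blocks = assert_positive_count(n_learning_blocks, "n_learning_blocks"),
    trials_per_block = assert_positive_count(trials_per_block, "trials_per_block"),
    pain_per_block = assert_positive_count(pain_per_block, "pain_per_block"),
    n_generalization_pain = assert_positive_count(n_generalization_pain, "n_generalization_pain"),
    n_generalization_nonpain = assert_positive_count(n_generalization_nonpain, "n_generalization_nonpain"),
    n_recipients_learning = assert_positive_count(n_recipients_learning, "n_recipients_learning"),
    seed = as.integer(seed)
  )
  if (spec$pain_per_block > spec$trials_per_block) {
    stop("'pain_per_block' cannot exceed 'trials_per_block'", call. = FALSE)
  }
  if (spec$n_learning_blocks %% spec$n_recipients_learning != 0L) {
    stop("'n_recipients_learning' must divide 'n_learning_blocks' evenly",
         call. = FALSE)
  }
  structure(spec, class = "trial_schedule_spec")
}

#' Generate a trial schedule
#'
#' Lays out the baseline, learning and generalization sessions in presentation
#' order. Within each session (and within each learning block) the order of
#' painful and non-painful trials is a seeded uniform permutation, so the same
#' specification and seed always yields the identical schedule. Recipients
#' alternate across learning blocks (one recipient per
#' \code{n_learning_blocks / n_recipients_learning} consecutive blocks) and the
#' generalization session introduces a new recipient, as in the task design.
#'
#' @param spec A \code{\link{trial_schedule_spec}}.
#' @return A data frame with one row per trial and columns \code{session}
#'   (baseline/learning/generalization), \code{block} (learning only, else
#'   \code{NA}), \code{trial_index} (1-based within session), \code{pain}
#'   (\code{"painful"}/\code{"nonpainful"}) and \code{recipient_id}.
#' @examples
#' sched <- generate_schedule(trial_schedule_spec(seed = 7))
#' table(sched$session, sched$pain)
#' @export
generate_schedule <- function(spec = trial_schedule_spec()) {
  if (!inherits(spec, "trial_schedule_spec")) {
    stop("'spec' must be a trial_schedule_spec", call. = FALSE)
  }
  set.seed(spec$seed)

  shuffle_pain <- function(n_pain, n_nonpain) {
    sample(c(rep("painful", n_pain), rep("nonpainful", n_nonpain)))
  }

  baseline <- data.frame(
    session = "baseline",
    block = NA_integer_,
    trial_index = seq_len(spec$n_baseline_pain + spec$n_baseline_nonpain),
    pain = shuffle_pain(spec$n_baseline_pain, spec$n_baseline_nonpain),
    recipient_id = "B1",
    stringsAsFactors = FALSE
  )

  blocks_per_recipient <- spec$n_learning_blocks / spec$n_recipients_learning
  learning_list <- lapply(seq_len(spec$n_learning_blocks), function(b) {
    data.frame(
      session = "learning",
      block = b,
      trial_index = NA_integer_,  # filled below
      pain = shuffle_pain(spec$pain_per_block,
                          spec$trials_per_block - spec$pain_per_block),
      recipient_id = sprintf("L%d", ceiling(b / blocks_per_recipient)),
      stringsAsFactors = FALSE
    )
  })
  learning <- do.call(rbind, learning_list)
  learning$trial_index <- seq_len(nrow(learning))

  generalization <- data.frame(
    session = "generalization",
    block = NA_integer_,
    trial_index = seq_len(spec$n_generalization_pain + spec$n_generalization_nonpain),
    pain = shuffle_pain(spec$n_generalization_pain, spec$n_generalization_nonpain),
    recipient_id = "G1",
    stringsAsFactors = FALSE
  )

  out <- rbind(baseline, learning, generalization)
  rownames(out) <- NULL
  out
}
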