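# Descriptive behavioral statistics of the serial choice task.

#' Choices to criterion for one phase
#'
#' Number of completed (non-omitted, non-reminder) choices up to and
#' including the criterion-satisfying trial. Sessions that never reach
#' criterion are censored: the total completed-choice count is returned with
#' `censored = TRUE`.
#'
#' @param sess a [session()]
#' @param phase `"acquisition"` or `"test"`
#' @param config a [task_config()]
#' @return list with `choices` (integer) and `censored` (logical)
#' @export
choices_to_criterion <- function(sess, phase, config = task_config()) {
  cd <- completed_trials(sess, phase)
  if (nrow(cd) == 0L)
    return(list(choices = NA_integer_, censored = TRUE))
  crit <- first_criterion_trial(cd$choice == config$rewarded_odor, config)
  if (is.na(crit)) list(choices = nrow(cd), censored = TRUE)
  else list(choices = crit, censored = FALSE)
}

#' Completed-choice counts per odor plus omissions
#'
#' Reminder trials are excluded throughout; the per-odor counts plus the
#' omission count always sum to the number of non-reminder trials.
#'
#' @inheritParams choices_to_criterion
#' @return list with `per_odor` (named integer vector over odors),
#'   `nonrewarded` (counts for the non-rewarded odors only), `choices_to_O2`
#'   (count for the innately preferred odor), `omissions`
#' @export
choice_breakdown <- function(sess, phase, config = task_config()) {
  tr <- sess$trials[sess$trials$phase == phase & !sess$trials$reminder, ]
  per_odor <- tabulate(tr$choice[!is.na(tr$choice)], nbins = config$n_odors)
  names(per_odor) <- paste0("O", seq_len(config$n_odors))
  nonrew <- per_odor[-config$rewarded_odor]
  list(per_odor = per_odor,
       nonrewarded = nonrew,
       choices_to_O2 = unname(per_odor["O2"]),
       omissions = sum(is.na(tr$choice)))
}

#' Cumulative reward accumulation and its through-origin slope
#'
#' The curve counts cumulative rewarded choices against the completed-trial
#' index; the slope is the least-squares line through the origin,
#' `sum(t * y) / sum(t^2)`, summarizing the per-choice accumulation rate
#' (1 for an all-correct session, 0 when nothing is rewarded).
#'
#' @inheritParams choices_to_criterion
#' @return list with `curve` (integer vector) and `slope` (`NA` when fewer
#'   than 2 completed trials)
#' @export
reward_accumulation <- function(sess, phase, config = task_config()) {
  cd <- completed_trials(sess, phase)
  curve <- cumsum(cd$rewarded)
  n <- length(curve)
  slope <- if (n < 2L) NA_real_ else {
    t <- seq_len(n)
    sum(t * curve) / sum(t^2)
  }
  list(curve = curve, slope = slope)
}

#' Proportion of single-entry choices
#'
#' A single-entry choice is a completed trial in which the animal dug at the
#' first pot it approached (entries list of length 1). Omitted and reminder
#' trials never enter the denominator; completed trials with no recorded
#' entries are excluded with a warning.
#'
#' @inheritParams choices_to_criterion
#' @return list with `proportion`, `n_single`, `n_trials` (denominator) and
#'   `per_odor` (single-entry counts by chosen odor)
#' @export
single_entry_proportion <- function(sess, phase, config = task_config()) {
  cd <- completed_trials(sess, phase)
  lens <- vapply(cd$entries, function(s) length(parse_entries(s)), 1L)
  missing_e <- lens == 0L
  if (any(missing_e)) {
    warning(sum(missing_e), " completed trial(s) without recorded entries excluded")
    cd <- cd[!missing_e, , drop = FALSE]
    lens <- lens[!missing_e]
  }
  single <- lens == 1L
  per_odor <- tabulate(cd$choice[single], nbins = config$n_odors)
  names(per_odor) <- paste0("O", seq_len(config$n_odors))
  list(proportion = if (nrow(cd)) mean(single) else NA_real_,
       n_single = sum(single), n_trials = nrow(cd), per_odor = per_odor)
}

#' Tidy behavioral summary of a cohort
#'
#' One row per mouse x phase with the headline task measures: choices to
#' criterion (with censoring flag), nonrewarded choices, choices to the
#' innately preferred odor O2, omissions, single-entry proportion and the
#' reward-accumulation slope.
#'
#' @param sessions a list of sessions (e.g. a [simulate_cohort()] result)
#' @param config a [task_config()]
#' @return data frame
#' @export
behavior_summary <- function(sessions, config = task_config()) {
  rows <- list()
  for (sess in sessions) {
    for (ph in unique(sess$trials$phase)) {
      ctc <- choices_to_criterion(sess, ph, config)
      bd <- choice_breakdown(sess, ph, config)
      se <- single_entry_proportion(sess, ph, config)
      ra <- reward_accumulation(sess, ph, config)
      rows[[length(rows) + 1L]] <- data.frame(
        mouse_id = sess$mouse_id, group = sess$group, phase = ph,
        choices_to_criterion = ctc$choices, censored = ctc$censored,
        nonrewarded_choices = sum(bd$nonrewarded),
        choices_to_O2 = bd$choices_to_O2,
        omissions = bd$omissions,
        single_entry_proportion = se$proportion,
        reward_slope = ra$slope,
        disqualified = sess$disqualified,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}
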