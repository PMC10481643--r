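# Task rules and domain containers for the four-odor serial choice task.

#' Phases of the serial choice task
#' @keywords internal
task_phases <- function() c("acquisition", "test")

#' Experimental group labels used in the chemogenetic study design
#'
#' @return character vector of the recognised group labels
#' @export
study_groups <- function() {
  c("mCherry", "D2-hM4Di", "D2-hM3Dq", "D1-hM4Di", "pan-hM4Di")
}

#' Task configuration for the odor-guided serial choice task
#'
#' Encodes the rules of the four-odor foraging task: one rewarded odor,
#' reward magnitude on the 0--100 value scale, the 8-of-10 consecutive-trial
#' performance criterion, the 3-minute omission timeout, a free-reward
#' reminder after every two consecutive omissions, and disqualification after
#' four omission pairs.
#'
#' @param n_odors number of scented pots presented per trial
#' @param rewarded_odor index (1-based) of the rewarded odor; odor 1 is the
#'   rewarded odor and odor 2 the innately preferred odor by convention
#' @param reward_magnitude value delivered on a rewarded choice (`r = 100`;
#'   unrewarded choices deliver 0)
#' @param criterion_correct,criterion_window performance criterion: at least
#'   `criterion_correct` correct among the last `criterion_window` completed
#'   choices
#' @param omission_timeout seconds without a choice before a trial is scored
#'   as an omission
#' @param reminder_after_omissions consecutive omissions that trigger a
#'   free-reward reminder trial
#' @param disqualify_omission_pairs number of consecutive-omission pairs at
#'   which the animal is disqualified
#' @param carry_over_values logical; whether odor values learned in the
#'   acquisition phase persist into the test phase. By default each phase
#'   starts from the shared initial values: the test phase is a fresh
#'   expression of the learned rule after a 24 h delay, and the model fits
#'   test-phase relearning (without the reset, the test phase starts with
#'   saturated values and its learning rate carries no information)
#' @return an object of class `task_config`
#' @examples
#' cfg <- task_config()
#' first_criterion_trial(rep(TRUE, 8), cfg)
#' @export
task_config <- function(n_odors = 4L,
                        rewarded_odor = 1L,
                        reward_magnitude = 100,
                        criterion_correct = 8L,
                        criterion_window = 10L,
                        omission_timeout = 180,
                        reminder_after_omissions = 2L,
                        disqualify_omission_pairs = 4L,
                        carry_over_values = FALSE) {
  n_odors <- as.integer(n_odors)
  rewarded_odor <- as.integer(rewarded_odor)
  criterion_correct <- as.integer(criterion_correct)
  criterion_window <- as.integer(criterion_window)
  if (criterion_correct <= 0L || criterion_correct > criterion_window)
    stop("need 0 < criterion_correct <= criterion_window")
  if (rewarded_odor < 1L || rewarded_odor > n_odors)
    stop("rewarded_odor must lie in 1..n_odors")
  if (reward_magnitude <= 0) stop("reward_magnitude must be positive")
  structure(
    list(n_odors = n_odors, rewarded_odor = rewarded_odor,
         reward_magnitude = reward_magnitude,
         criterion_correct = criterion_correct,
         criterion_window = criterion_window,
         omission_timeout = omission_timeout,
         reminder_after_omissions = as.integer(reminder_after_omissions),
         disqualify_omission_pairs = as.integer(disqualify_omission_pairs),
         carry_over_values = isTRUE(carry_over_values)),
    class = "task_config")
}

#' First trial at which the performance criterion is satisfied
#'
#' Scans an ordered sequence of completed (non-omitted, non-reminder)
#' choices and returns the smallest trial index `t >= criterion_correct` at
#' which at least `criterion_correct` of the last `min(t, criterion_window)`
#' completed choices were correct. Omitted trials are not part of the input:
#' the criterion counts choices only.
#'
#' @param correct logical (or 0/1) vector of completed choices in order
#' @param config a [task_config()]
#' @return integer index of the criterion-satisfying choice, or
#'   `NA_integer_` if the criterion is never met (including an empty input)
#' @examples
#' first_criterion_trial(rep(TRUE, 8), task_config())   # 8
#' first_criterion_trial(rep(c(TRUE, FALSE), 50), task_config())  # NA
#' @export
first_criterion_trial <- function(correct, config = task_config()) {
  if (is.numeric(correct)) {
    if (!all(correct %in% c(0, 1))) stop("choices must be correct/incorrect (logical or 0/1)")
    correct <- correct > 0
  }
  if (!is.logical(correct)) stop("choices must be correct/incorrect (logical or 0/1)")
  if (anyNA(correct)) stop("choices must be complete; omissions are excluded upstream")
  n <- length(correct)
  cc <- config$criterion_correct
  w <- config$criterion_window
  if (n < cc) return(NA_integer_)
  cs <- cumsum(correct)
  lag <- c(rep(0L, w), cs[seq_len(max(n - w, 0L))])
  in_window <- cs - lag[seq_len(n)]
  hit <- which(in_window >= cc & seq_len(n) >= cc)
  if (length(hit) == 0L) NA_integer_ else hit[1L]
}

#' Omission bookkeeping: reminders due and disqualification
#'
#' Walks a session's trials in order counting omissions. Each run of
#' `reminder_after_omissions` consecutive omissions completes an "omission
#' pair" and triggers a free-reward reminder (which interrupts the run);
#' completed choices also reset the run. An animal is disqualified once the
#' number of omission pairs reaches `disqualify_omission_pairs`.
#'
#' @param trials a trial data frame (see [session()]) or a logical vector
#'   with `TRUE` marking an omitted trial (reminder trials excluded)
#' @param config a [task_config()]
#' @return list with `n_omissions`, `n_pairs`, `n_reminders_due`,
#'   `disqualified`
#' @export
omission_accounting <- function(trials, config = task_config()) {
  if (is.data.frame(trials)) {
    keep <- !trials$reminder
    omitted <- is.na(trials$choice[keep])
  } else {
    omitted <- as.logical(trials)
  }
  run <- 0L; pairs <- 0L
  for (om in omitted) {
    if (om) {
      run <- run + 1L
      if (run == config$reminder_after_omissions) {
        pairs <- pairs + 1L
        run <- 0L  # the reminder interrupts the omission run
      }
    } else run <- 0L
  }
  list(n_omissions = sum(omitted),
       n_pairs = pairs,
       n_reminders_due = pairs,
       disqualified = pairs >= config$disqualify_omission_pairs)
}

#' Construct a session: one mouse's ordered trials across phases
#'
#' @param mouse_id label
#' @param group experimental group label
#' @param trials data frame with columns `phase` ("acquisition"/"test"),
#'   `trial_index` (1-based within phase), `entries` (semicolon-joined odor
#'   indices, `""` allowed for omissions/reminders), `choice` (odor index or
#'   `NA` for omission), `rewarded` (logical), `reminder` (logical),
#'   `latency_s` (seconds, `NA` allowed)
#' @param drug_by_phase named character vector mapping phase to drug
#' @param disqualified logical
#' @return an object of class `choice_session`
#' @export
session <- function(mouse_id, group, trials,
                    drug_by_phase = c(acquisition = "saline", test = "CNO"),
                    disqualified = FALSE) {
  need <- c("phase", "trial_index", "entries", "choice", "rewarded",
            "reminder", "latency_s")
  miss <- setdiff(need, names(trials))
  if (length(miss)) stop("trials is missing columns: ", paste(miss, collapse = ", "))
  trials$phase <- as.character(trials$phase)
  trials$trial_index <- as.integer(trials$trial_index)
  trials$choice <- as.integer(trials$choice)
  trials$rewarded <- as.logical(trials$rewarded)
  trials$reminder <- as.logical(trials$reminder)
  structure(
    list(mouse_id = as.character(mouse_id), group = as.character(group),
         drug_by_phase = drug_by_phase,
         trials = trials[, need], disqualified = isTRUE(disqualified)),
    class = "choice_session")
}

#' @export
print.choice_session <- function(x, ...) {
  cat(sprintf("<choice_session> mouse %s (group %s)%s\n", x$mouse_id, x$group,
              if (x$disqualified) " [disqualified]" else ""))
  for (ph in unique(x$trials$phase)) {
    tr <- x$trials[x$trials$phase == ph, ]
    done <- !tr$reminder & !is.na(tr$choice)
    cat(sprintf("  %s: %d trials (%d completed, %d omissions, %d reminders)\n",
                ph, nrow(tr), sum(done), sum(!tr$reminder & is.na(tr$choice)),
                sum(tr$reminder)))
  }
  invisible(x)
}

# Completed, non-reminder trials of one phase (the rows entering choice
# statistics and the likelihood).
completed_trials <- function(sess, phase = NULL) {
  tr <- sess$trials
  if (!is.null(phase)) tr <- tr[tr$phase == phase, ]
  tr[!tr$reminder & !is.na(tr$choice), , drop = FALSE]
}

#' Validate a session against the task rules
#'
#' Checks ordering and the per-trial invariants: a rewarded non-reminder
#' choice must be the rewarded odor, an omission cannot be rewarded, entries
#' (when recorded) must end in the chosen odor, and -- unless the session is
#' disqualified or validated with `require_criterion = FALSE` -- each phase's
#' completed choices must satisfy the criterion exactly at the final
#' completed trial.
#'
#' @param sess a [session()]
#' @param config a [task_config()]
#' @param require_criterion enforce criterion termination of each phase
#'   (disable for fixed-length simulated sessions)
#' @return `TRUE` invisibly, or an error describing the first violation
#' @export
validate_session <- function(sess, config = task_config(),
                             require_criterion = TRUE) {
  stopifnot(inherits(sess, "choice_session"))
  tr <- sess$trials
  bad_phase <- setdiff(unique(tr$phase), task_phases())
  if (length(bad_phase)) stop("unknown phase label: ", bad_phase[1L])
  ord <- order(match(tr$phase, task_phases()), tr$trial_index)
  if (!identical(ord, seq_len(nrow(tr))))
    stop("trials are not sorted by (phase, trial_index)")
  for (ph in unique(tr$phase)) {
    ti <- tr$trial_index[tr$phase == ph]
    if (!identical(ti, seq_along(ti)))
      stop("non-contiguous trial indices in phase ", ph)
  }
  plain <- !tr$reminder
  om <- plain & is.na(tr$choice)
  if (any(tr$rewarded[om]))
    stop("omitted trial marked as rewarded (row ", which(om & tr$rewarded)[1L], ")")
  done <- plain & !is.na(tr$choice)
  bad <- done & tr$rewarded & tr$choice != config$rewarded_odor
  if (any(bad))
    stop("rewarded trial with a non-rewarded odor choice (row ", which(bad)[1L], ")")
  bad2 <- done & !tr$rewarded & tr$choice == config$rewarded_odor
  if (any(bad2))
    stop("unrewarded trial choosing the rewarded odor (row ", which(bad2)[1L], ")")
  if (any(done & !is.na(tr$choice) & (tr$choice < 1L | tr$choice > config$n_odors)))
    stop("choice outside 1..n_odors")
  for (i in which(done & nzchar(tr$entries))) {
    e <- parse_entries(tr$entries[i])
    if (length(e) == 0L || e[length(e)] != tr$choice[i])
      stop("entries do not end in the chosen odor (row ", i, ")")
  }
  if (require_criterion && !sess$disqualified) {
    for (ph in unique(tr$phase)) {
      cd <- completed_trials(sess, ph)
      crit <- first_criterion_trial(cd$choice == config$rewarded_odor, config)
      if (is.na(crit) || crit != nrow(cd))
        stop("phase ", ph, " does not terminate exactly at the criterion trial")
    }
  }
  invisible(TRUE)
}

parse_entries <- function(s) {
  if (is.na(s) || !nzchar(s)) return(integer(0))
  as.integer(strsplit(s, ";", fixed = TRUE)[[1L]])
}

entries_string <- function(e) paste(e, collapse = ";")
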