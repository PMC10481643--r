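# Independent oracles and session builders used across the suite.

# Exhaustive-window criterion oracle: scans every trial and counts correct
# choices in the trailing window directly.
oracle_first_criterion <- function(correct, cc = 8L, w = 10L) {
  for (t in seq_along(correct)) {
    wlen <- min(t, w)
    if (t >= cc && sum(correct[(t - wlen + 1L):t]) >= cc) return(t)
  }
  NA_integer_
}

# Build a completed-choices-only session from logical correctness vectors.
# Correct choices pick odor 1; incorrect ones cycle over odors 2..4.
session_from_correct <- function(acq, test = NULL, mouse_id = "m1",
                                 group = "mCherry") {
  build <- function(correct, phase) {
    if (is.null(correct) || length(correct) == 0L) return(NULL)
    wrong <- rep_len(2:4, length(correct))
    choice <- ifelse(correct, 1L, wrong)
    data.frame(phase = phase, trial_index = seq_along(correct),
               entries = as.character(choice), choice = choice,
               rewarded = correct, reminder = FALSE, latency_s = 10,
               stringsAsFactors = FALSE)
  }
  session(mouse_id, group, rbind(build(acq, "acquisition"),
                                 build(test, "test")))
}

# Trial row helpers for hand-built sessions.
trial_row <- function(phase, idx, choice, rewarded, reminder = FALSE,
                      entries = if (is.na(choice)) "" else as.character(choice),
                      latency = 10) {
  data.frame(phase = phase, trial_index = idx, entries = entries,
             choice = choice, rewarded = rewarded, reminder = reminder,
             latency_s = latency, stringsAsFactors = FALSE)
}

# Independent literal softmax (no max subtraction) for well-scaled inputs.
naive_softmax <- function(q, beta) exp(beta * q) / sum(exp(beta * q))

# Group spec shorthand for simulate_cohort.
gspec <- function(n_mice, alpha_acq, alpha_test, beta_acq, beta_test,
                  sigma_alpha = 0.2, sigma_beta = 0.2) {
  list(n_mice = n_mice, alpha_acq = alpha_acq, alpha_test = alpha_test,
       beta_acq = beta_acq, beta_test = beta_test,
       sigma_alpha = sigma_alpha, sigma_beta = sigma_beta)
}
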