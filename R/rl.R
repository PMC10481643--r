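# Softmax Q-learning model of trial-by-trial odor choice.

#' Per-animal reinforcement-learning parameters
#'
#' Phase-specific learning rates (alpha) and inverse temperatures (beta) for
#' the acquisition and test phases, with the derived phase changes
#' `delta_alpha = alpha_test - alpha_acq` and
#' `delta_beta = beta_test - beta_acq`.
#'
#' @param alpha_acq,alpha_test learning rates, strictly inside (0, 1)
#' @param beta_acq,beta_test inverse temperatures, `>= 0`; with rewards on
#'   the 0--100 scale, plausible values are of order 0.01--0.2
#' @return an object of class `rl_params`
#' @export
rl_params <- function(alpha_acq, alpha_test = alpha_acq,
                      beta_acq, beta_test = beta_acq) {
  a <- c(alpha_acq, alpha_test)
  b <- c(beta_acq, beta_test)
  if (any(a <= 0 | a >= 1)) stop("learning rates must satisfy 0 < alpha < 1")
  if (any(b < 0)) stop("inverse temperatures must be >= 0")
  structure(
    list(alpha_acq = alpha_acq, alpha_test = alpha_test,
         beta_acq = beta_acq, beta_test = beta_test,
         delta_alpha = alpha_test - alpha_acq,
         delta_beta = beta_test - beta_acq),
    class = "rl_params")
}

#' Shared initial odor values
#'
#' The innate odor preferences of untrained mice, expressed as initial Q
#' values `[v1..v4]` shared across all animals. Odor 2 carries the innate
#' preference in the task's convention. Softmax choice probabilities are
#' invariant to adding a constant to all values, so at the fitting level the
#' vector is anchored to mean zero; the constructor itself accepts any
#' finite vector.
#'
#' @param v numeric vector of length `n_odors` on the reward value scale
#' @param anchor if `TRUE`, centre `v` to mean zero
#' @return an object of class `initial_values`
#' @export
initial_values <- function(v, anchor = FALSE) {
  if (!is.numeric(v) || anyNA(v) || any(!is.finite(v)))
    stop("initial values must be finite numerics")
  if (anchor) v <- v - mean(v)
  structure(as.numeric(v), class = "initial_values")
}

#' Model variants compared by WAIC
#'
#' Four variants lie on the lattice of phase specificity: both alpha and
#' beta shared between phases ("shared"), only alpha phase-specific
#' ("alpha_only"), only beta phase-specific ("beta_only"), or both
#' ("full").
#'
#' @param name one of `"shared"`, `"alpha_only"`, `"beta_only"`, `"full"`
#' @return an object of class `model_spec` with logical fields
#'   `alpha_phase_specific` and `beta_phase_specific`
#' @export
model_spec <- function(name = c("full", "shared", "alpha_only", "beta_only")) {
  name <- match.arg(name)
  structure(
    list(name = name,
         alpha_phase_specific = name %in% c("alpha_only", "full"),
         beta_phase_specific = name %in% c("beta_only", "full")),
    class = "model_spec")
}

#' Number of free per-animal parameters implied by a model variant
#' @param spec a [model_spec()]
#' @return integer count (2, 3 or 4)
#' @export
n_free_params <- function(spec) {
  2L + spec$alpha_phase_specific + spec$beta_phase_specific
}

#' Map a model variant's free parameters onto full phase-specific parameters
#'
#' Shared variants copy the single alpha (or beta) into both phases;
#' phase-specific variants map their two values independently.
#'
#' @param spec a [model_spec()]
#' @param free named list: `alpha` or (`alpha_acq`, `alpha_test`) according
#'   to the variant, and likewise for beta
#' @return an [rl_params()] object
#' @export
apply_model_spec <- function(spec, free) {
  grab <- function(shared_name, acq_name, test_name, specific) {
    if (specific) {
      if (is.null(free[[acq_name]]) || is.null(free[[test_name]]))
        stop("spec '", spec$name, "' needs ", acq_name, " and ", test_name)
      c(free[[acq_name]], free[[test_name]])
    } else {
      if (is.null(free[[shared_name]]))
        stop("spec '", spec$name, "' needs a shared ", shared_name)
      rep(free[[shared_name]], 2L)
    }
  }
  a <- grab("alpha", "alpha_acq", "alpha_test", spec$alpha_phase_specific)
  b <- grab("beta", "beta_acq", "beta_test", spec$beta_phase_specific)
  n_named <- sum(!vapply(free, is.null, TRUE))
  if (n_named != n_free_params(spec))
    stop("expected ", n_free_params(spec), " free parameters, got ", n_named)
  rl_params(a[1L], a[2L], b[1L], b[2L])
}

#' Prediction-error value update for the chosen odor
#'
#' `delta = r - Q` with `r = reward_magnitude` on a rewarded choice and 0
#' otherwise; `Q_next = Q + alpha * delta`. Only the chosen odor's value
#' changes.
#'
#' @param q current value of the chosen odor
#' @param rewarded logical
#' @param alpha learning rate in (0, 1)
#' @param config a [task_config()] supplying the reward magnitude
#' @return list with `q_next` and `delta`
#' @examples
#' update_value(0, TRUE, 0.5)   # delta 100, q_next 50
#' @export
update_value <- function(q, rewarded, alpha, config = task_config()) {
  if (alpha <= 0 || alpha >= 1) stop("learning rate must satisfy 0 < alpha < 1")
  r <- if (isTRUE(rewarded)) config$reward_magnitude else 0
  delta <- r - q
  list(q_next = q + alpha * delta, delta = delta)
}

#' Softmax choice probabilities over odor values
#'
#' `p_i` is proportional to `exp(beta * q_i)`, computed with max subtraction
#' so large `beta * q` cannot overflow.
#'
#' @param q numeric vector of odor values
#' @param beta inverse temperature, `>= 0`
#' @return probability vector summing to 1
#' @examples
#' choice_probabilities(c(100, 0, 0, 0), 0.05)  # ~0.9802 for the first odor
#' @export
choice_probabilities <- function(q, beta) {
  if (beta < 0) stop("beta must be >= 0")
  if (anyNA(q) || any(!is.finite(q))) stop("values must be finite")
  x <- beta * q
  x <- x - max(x)
  e <- exp(x)
  e / sum(e)
}

#' Log-likelihood of a session under the softmax Q-learning model
#'
#' Replays the session's trials in order. For each completed, non-reminder
#' trial the log-probability of the observed choice under the current
#' phase's beta is accumulated, and the chosen odor's value is then updated
#' with the current phase's alpha. Values carry over from acquisition into
#' test unless `config$carry_over_values` is `FALSE`, in which case they
#' reset to the initial values at the phase boundary. Omission and reminder
#' trials contribute no likelihood term.
#'
#' @param sess a [session()]
#' @param params an [rl_params()]
#' @param init an [initial_values()] vector (length `config$n_odors`)
#' @param config a [task_config()]
#' @param spec optional [model_spec()]; when supplied, the parameters must
#'   respect its phase-sharing pattern
#' @return list with `total` (log-probability) and `pointwise` (per-trial
#'   log-probabilities over completed, non-reminder trials, in order)
#' @export
session_loglik <- function(sess, params, init, config = task_config(),
                           spec = NULL) {
  stopifnot(inherits(sess, "choice_session"), inherits(params, "rl_params"))
  v <- as.numeric(init)
  if (length(v) != config$n_odors) stop("initial values must have length n_odors")
  if (!is.null(spec)) {
    if (!spec$alpha_phase_specific && params$delta_alpha != 0)
      stop("spec '", spec$name, "' shares alpha across phases")
    if (!spec$beta_phase_specific && params$delta_beta != 0)
      stop("spec '", spec$name, "' shares beta across phases")
  }
  alpha <- c(acquisition = params$alpha_acq, test = params$alpha_test)
  beta <- c(acquisition = params$beta_acq, test = params$beta_test)
  q <- v
  pw <- numeric(0)
  prev_phase <- NULL
  tr <- sess$trials
  for (i in seq_len(nrow(tr))) {
    ph <- tr$phase[i]
    if (!config$carry_over_values && !is.null(prev_phase) && ph != prev_phase)
      q <- v
    prev_phase <- ph
    if (tr$reminder[i] || is.na(tr$choice[i])) next
    c_i <- tr$choice[i]
    p <- choice_probabilities(q, beta[[ph]])
    lp <- log(p[c_i])
    if (!is.finite(lp))
      stop("non-finite log-likelihood at trial row ", i)
    pw <- c(pw, lp)
    upd <- update_value(q[c_i], tr$rewarded[i], alpha[[ph]], config)
    q[c_i] <- upd$q_next
  }
  list(total = sum(pw), pointwise = pw)
}
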