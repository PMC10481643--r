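# Generative twin of the study: softmax Q-learning agents performing the
# serial choice task, cohorts drawn from group-level distributions, and
# rigid-body pose tracks for the rotation pipeline.

#' Specification of a single simulated agent
#'
#' @param params an [rl_params()] object (the agent's generating parameters)
#' @param init_values an [initial_values()] vector; the default encodes the
#'   innate preference for odor 2 on the 0--100 value scale
#' @param omission_prob per-trial probability of an omission, independent of
#'   odor values (the task gives no generative account of omissions)
#' @param entry_slope slope of the value-guided quadrant entry process; see
#'   [simulate_entries()]
#' @param group group label attached to the simulated session
#' @param mouse_id label
#' @param seed RNG seed; identical specs with identical seeds reproduce the
#'   session exactly
#' @return an object of class `agent_spec`
#' @export
agent_spec <- function(params,
                       init_values = initial_values(c(0, 25, 0, 0)),
                       omission_prob = 0.03,
                       entry_slope = 0.05,
                       group = "mCherry",
                       mouse_id = "sim1",
                       seed = NULL) {
  stopifnot(inherits(params, "rl_params"))
  if (omission_prob < 0 || omission_prob >= 1)
    stop("omission_prob must satisfy 0 <= p < 1")
  structure(
    list(params = params, init_values = init_values,
         omission_prob = omission_prob, entry_slope = entry_slope,
         group = as.character(group), mouse_id = as.character(mouse_id),
         seed = seed),
    class = "agent_spec")
}

#' Simulate the serial quadrant-entry sequence of one trial
#'
#' Models the animal's walk among the four pots before digging. Pots are
#' approached in an order drawn without replacement with Plackett-Luce
#' weights `exp(slope * q)`, so higher-valued pots tend to be visited first.
#' When `choice` is supplied (as it is by [simulate_session()], whose choice
#' is sampled from the softmax policy so the likelihood stays exact), the
#' entry list is the approach order truncated at the chosen pot. Otherwise
#' the dig decision is made at each approached pot by a logistic acceptance
#' `plogis(slope * (q_i - mean(q)))`; if a full circuit passes without a
#' dig, the animal is forced to choose the best pot (re-approaching it if
#' necessary), so the list never has immediate repeats and always ends at
#' the dug pot.
#'
#' @param q_values numeric vector of current odor values
#' @param slope acceptance/approach slope (per value unit); 0 gives a
#'   uniform approach order and coin-flip digs
#' @param choice optional odor index to condition the entry sequence on
#' @param seed optional RNG seed
#' @return integer vector of approached odor indices ending in the dug odor
#' @export
simulate_entries <- function(q_values, slope = 0.05, choice = NULL,
                             seed = NULL) {
  n <- length(q_values)
  with_seed(seed, {
    # floor keeps all pots reachable when steep slopes underflow the weights
    w <- exp(slope * (q_values - max(q_values))) + 1e-12
    order_visit <- sample.int(n, n, prob = w)
    if (!is.null(choice)) {
      stopifnot(choice >= 1L, choice <= n)
      return(order_visit[seq_len(which(order_visit == choice))])
    }
    acc <- stats::plogis(slope * (q_values - mean(q_values)))
    for (k in seq_len(n)) {
      if (stats::runif(1) < acc[order_visit[k]])
        return(order_visit[seq_len(k)])
    }
    best <- which.max(q_values)
    if (order_visit[n] == best) order_visit else c(order_visit, best)
  })
}

# One phase of agent behavior; returns trial rows, final values and status.
simulate_phase <- function(phase, q, agent, config, max_trials,
                           stop_at_criterion) {
  alpha <- if (phase == "acquisition") agent$params$alpha_acq else agent$params$alpha_test
  beta <- if (phase == "acquisition") agent$params$beta_acq else agent$params$beta_test
  rows <- list()
  correct <- logical(0)
  run <- 0L; pairs <- 0L
  idx <- 0L
  disqualified <- FALSE
  criterion_met <- FALSE
  n_plain <- 0L
  while (n_plain < max_trials) {
    idx <- idx + 1L
    if (stats::runif(1) < agent$omission_prob) {
      n_plain <- n_plain + 1L
      rows[[idx]] <- data.frame(
        phase = phase, trial_index = idx, entries = "",
        choice = NA_integer_, rewarded = FALSE, reminder = FALSE,
        latency_s = config$omission_timeout, stringsAsFactors = FALSE)
      run <- run + 1L
      if (run == config$reminder_after_omissions) {
        pairs <- pairs + 1L
        run <- 0L
        if (pairs >= config$disqualify_omission_pairs) {
          disqualified <- TRUE
          break
        }
        idx <- idx + 1L  # free-reward reminder trial interrupts the run
        rows[[idx]] <- data.frame(
          phase = phase, trial_index = idx, entries = "",
          choice = NA_integer_, rewarded = TRUE, reminder = TRUE,
          latency_s = NA_real_, stringsAsFactors = FALSE)
      }
      next
    }
    run <- 0L
    n_plain <- n_plain + 1L
    p <- choice_probabilities(q, beta)
    ch <- sample.int(config$n_odors, 1L, prob = p)
    entries <- simulate_entries(q, agent$entry_slope, choice = ch)
    rewarded <- ch == config$rewarded_odor
    lat <- min(stats::rlnorm(1, meanlog = log(15), sdlog = 0.6),
               config$omission_timeout - 1)
    rows[[idx]] <- data.frame(
      phase = phase, trial_index = idx, entries = entries_string(entries),
      choice = ch, rewarded = rewarded, reminder = FALSE,
      latency_s = lat, stringsAsFactors = FALSE)
    q[ch] <- q[ch] + alpha * ((if (rewarded) config$reward_magnitude else 0) - q[ch])
    correct <- c(correct, rewarded)
    if (stop_at_criterion) {
      t <- length(correct)
      wlen <- min(t, config$criterion_window)
      if (t >= config$criterion_correct &&
          sum(correct[(t - wlen + 1L):t]) >= config$criterion_correct) {
        criterion_met <- TRUE
        break
      }
    }
  }
  list(trials = do.call(rbind, rows), q = q, disqualified = disqualified,
       criterion_met = criterion_met)
}

#' Simulate one agent's full session (acquisition then test)
#'
#' Per trial the agent omits with `omission_prob` (reminder and
#' disqualification rules applied), otherwise samples a choice from the
#' softmax over its current odor values with the phase's inverse
#' temperature, receives the configured reward, and updates the chosen
#' odor's value with the phase's learning rate. Values carry over between
#' phases according to `config$carry_over_values`. Each phase ends at the
#' performance criterion (when `stop_at_criterion`), at disqualification, or
#' after `max_trials` non-reminder trials.
#'
#' @param agent an [agent_spec()]
#' @param config a [task_config()]
#' @param max_trials maximum non-reminder trials per phase
#' @param stop_at_criterion end each phase at the performance criterion
#'   (default); `FALSE` yields fixed-length phases, useful for parameter
#'   recovery, and such sessions validate only with
#'   `require_criterion = FALSE`
#' @param phases which phases to run
#' @return a [session()] carrying the generating `agent_spec` as attribute
#'   `"agent"`
#' @export
simulate_session <- function(agent, config = task_config(), max_trials = 100L,
                             stop_at_criterion = TRUE,
                             phases = c("acquisition", "test")) {
  stopifnot(inherits(agent, "agent_spec"))
  if (max_trials < config$criterion_correct)
    stop("max_trials must be at least criterion_correct")
  with_seed(agent$seed, {
    q <- as.numeric(agent$init_values)
    if (length(q) != config$n_odors) stop("init_values must have length n_odors")
    all_rows <- list()
    disq <- FALSE
    for (ph in phases) {
      if (!config$carry_over_values) q <- as.numeric(agent$init_values)
      res <- simulate_phase(ph, q, agent, config, max_trials, stop_at_criterion)
      q <- res$q
      all_rows[[ph]] <- res$trials
      if (res$disqualified) { disq <- TRUE; break }
    }
    out <- session(agent$mouse_id, agent$group, do.call(rbind, all_rows),
                   disqualified = disq)
    attr(out, "agent") <- agent
    out
  })
}

#' Simulate a cohort with group-level parameter distributions
#'
#' Draws each animal's phase-specific parameters from its group's
#' hyper-distribution (normal on the logit scale for learning rates, normal
#' on the log scale for inverse temperatures) and simulates a full session
#' per animal. Initial odor values are shared across the whole cohort, as in
#' the hierarchical model. The generating per-animal parameters are recorded
#' in the `"ground_truth"` attribute for recovery studies.
#'
#' @param groups named list; each element describes one group with fields
#'   `n_mice`, natural-scale group medians `alpha_acq`, `alpha_test`,
#'   `beta_acq`, `beta_test`, and hyper-scales `sigma_alpha` (logit scale)
#'   and `sigma_beta` (log scale). Hyper-scale 0 makes all animals in a
#'   group identical.
#' @param config a [task_config()]
#' @param init_values shared [initial_values()]
#' @param seed RNG seed for the whole cohort
#' @param omission_prob,entry_slope,max_trials,stop_at_criterion passed to
#'   each agent/session
#' @return list of sessions with class `choice_cohort`; attributes
#'   `ground_truth` (data frame of generating per-animal parameters) and
#'   `init_values`
#' @export
simulate_cohort <- function(groups, config = task_config(),
                            init_values = initial_values(c(0, 25, 0, 0)),
                            seed = 1L, omission_prob = 0.03,
                            entry_slope = 0.05, max_trials = 100L,
                            stop_at_criterion = TRUE) {
  stopifnot(is.list(groups), length(names(groups)) == length(groups))
  with_seed(seed, {
    sessions <- list()
    truth <- list()
    for (g in names(groups)) {
      gs <- groups[[g]]
      if (is.null(gs$n_mice) || gs$n_mice < 1L) stop("each group needs n_mice >= 1")
      sa <- gs$sigma_alpha %||% 0.25
      sb <- gs$sigma_beta %||% 0.25
      if (sa < 0 || sb < 0) stop("hyper-scales must be non-negative")
      for (i in seq_len(gs$n_mice)) {
        draw_alpha <- function(med) stats::plogis(stats::qlogis(med) + sa * stats::rnorm(1))
        draw_beta <- function(med) exp(log(med) + sb * stats::rnorm(1))
        pars <- rl_params(alpha_acq = draw_alpha(gs$alpha_acq),
                          alpha_test = draw_alpha(gs$alpha_test),
                          beta_acq = draw_beta(gs$beta_acq),
                          beta_test = draw_beta(gs$beta_test))
        id <- sprintf("%s_m%02d", gsub("[^A-Za-z0-9]", "", g), i)
        ag <- agent_spec(pars, init_values, omission_prob = omission_prob,
                         entry_slope = entry_slope, group = g, mouse_id = id)
        sessions[[id]] <- simulate_session(
          ag, config, max_trials = max_trials,
          stop_at_criterion = stop_at_criterion)
        truth[[id]] <- data.frame(
          mouse_id = id, group = g,
          alpha_acq = pars$alpha_acq, alpha_test = pars$alpha_test,
          beta_acq = pars$beta_acq, beta_test = pars$beta_test,
          stringsAsFactors = FALSE)
      }
    }
    out <- unname(sessions)
    class(out) <- "choice_cohort"
    attr(out, "ground_truth") <- do.call(rbind, unname(truth))
    attr(out, "init_values") <- init_values
    out
  })
}

#' Specification of a synthetic pose track
#'
#' Describes a rigid three-node body (head, torso, tail base) rotating at a
#' constant angular drift, with Gaussian positional noise and missing
#' coordinates inserted at random -- a stand-in for pose-estimation output.
#'
#' @param n_frames number of frames (> 20)
#' @param fps frames per second (video standard: 15)
#' @param angular_drift signed rotation in degrees per frame
#' @param step_noise standard deviation of Gaussian positional noise, pixels
#' @param missing_prob probability that a node's coordinates are missing in
#'   a frame
#' @param head_dist,tail_dist distances (pixels) from torso to head and to
#'   tail base
#' @param seed RNG seed
#' @return an object of class `pose_spec`
#' @export
pose_spec <- function(n_frames = 600L, fps = 15, angular_drift = 0,
                      step_noise = 0, missing_prob = 0,
                      head_dist = 20, tail_dist = 30, seed = NULL) {
  if (fps <= 0) stop("fps must be positive")
  if (n_frames <= 20L) stop("need n_frames > 20")
  if (missing_prob < 0 || missing_prob >= 1) stop("missing_prob must be in [0, 1)")
  structure(
    list(n_frames = as.integer(n_frames), fps = fps,
         angular_drift = angular_drift, step_noise = step_noise,
         missing_prob = missing_prob, head_dist = head_dist,
         tail_dist = tail_dist, seed = seed),
    class = "pose_spec")
}

#' Simulate a pose track of a rigid rotating body
#'
#' The torso sits at a fixed arena position; head and tail base lie at fixed
#' distances along the (rotating) body axis. Heading advances by
#' `angular_drift` degrees per frame; independent Gaussian noise is added to
#' every coordinate and node coordinates go missing with `missing_prob`.
#'
#' @param spec a [pose_spec()]
#' @return a `pose_track` data frame with columns `frame`, `head_x`,
#'   `head_y`, `torso_x`, `torso_y`, `tail_x`, `tail_y` and attribute `fps`
#' @export
simulate_pose_track <- function(spec) {
  stopifnot(inherits(spec, "pose_spec"))
  with_seed(spec$seed, {
    n <- spec$n_frames
    heading <- (spec$angular_drift * (seq_len(n) - 1L)) * pi / 180
    cx <- 250; cy <- 250
    noise <- function() stats::rnorm(n, sd = spec$step_noise)
    tr <- data.frame(
      frame = seq_len(n),
      head_x = cx + spec$head_dist * cos(heading) + noise(),
      head_y = cy + spec$head_dist * sin(heading) + noise(),
      torso_x = cx + noise(),
      torso_y = cy + noise(),
      tail_x = cx - spec$tail_dist * cos(heading) + noise(),
      tail_y = cy - spec$tail_dist * sin(heading) + noise())
    if (spec$missing_prob > 0) {
      for (node in c("head", "torso", "tail")) {
        gone <- stats::runif(n) < spec$missing_prob
        tr[gone, paste0(node, c("_x", "_y"))] <- NA_real_
      }
    }
    pose_track(tr, fps = spec$fps)
  })
}

#' Construct a pose track from a coordinate data frame
#'
#' @param df data frame with columns `frame`, `head_x`, `head_y`, `torso_x`,
#'   `torso_y`, `tail_x`, `tail_y`; empty cells (`NA`) mark missing
#'   coordinates
#' @param fps frames per second of the recording (taken from the input, not
#'   assumed)
#' @return the data frame with class `pose_track` and attribute `fps`
#' @export
pose_track <- function(df, fps = 15) {
  need <- c("frame", "head_x", "head_y", "torso_x", "torso_y",
            "tail_x", "tail_y")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("pose track missing columns: ", paste(miss, collapse = ", "))
  out <- df[, need]
  attr(out, "fps") <- fps
  class(out) <- c("pose_track", "data.frame")
  out
}
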