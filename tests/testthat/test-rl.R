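test_that("value update implements the prediction-error rule", {
  cfg <- task_config()
  up <- update_value(0, TRUE, 0.31, cfg)
  expect_equal(up$delta, 100)
  expect_equal(update_value(0, TRUE, 0.5, cfg)$q_next, 50)
  # the reward magnitude is a fixed point
  fp <- update_value(100, TRUE, 0.7, cfg)
  expect_equal(fp$q_next, 100)
  expect_equal(fp$delta, 0)
  # unrewarded choices decay toward zero
  expect_equal(update_value(40, FALSE, 0.25, cfg)$q_next, 30)
  expect_error(update_value(0, TRUE, 1, cfg), "alpha")
})

test_that("softmax probabilities are exact on closed-form cases", {
  expect_equal(choice_probabilities(rep(7, 4), 0.2), rep(0.25, 4))
  expect_equal(choice_probabilities(c(3, -2, 90, 14), 0), rep(0.25, 4))
  p <- choice_probabilities(c(100, 0, 0, 0), 0.05)
  expect_equal(p[1], exp(5) / (exp(5) + 3), tolerance = 1e-12)
  expect_equal(sum(p), 1, tolerance = 1e-12)
  # overflow safety: huge beta*q must not produce NaN
  expect_equal(choice_probabilities(c(1000, 0, 0, 0), 10)[1], 1)
})

test_that("softmax is shift-invariant and sharpens with beta", {
  set.seed(11)
  for (i in 1:50) {
    q <- stats::rnorm(4, sd = 30)
    beta <- stats::runif(1, 0, 0.2)
    shift <- stats::rnorm(1, sd = 50)
    expect_equal(choice_probabilities(q, beta),
                 choice_probabilities(q + shift, beta), tolerance = 1e-12)
    pmax_by_beta <- vapply(c(0, 0.01, 0.05, 0.1, 0.5),
                           function(b) max(choice_probabilities(q, b)), 0)
    expect_true(all(diff(pmax_by_beta) >= -1e-12))
  }
})

test_that("model variants map free parameters with the right arity", {
  shared <- apply_model_spec(model_spec("shared"),
                             list(alpha = 0.3, beta = 0.05))
  expect_equal(shared$alpha_test, 0.3)
  expect_equal(shared$delta_alpha, 0)
  expect_equal(shared$delta_beta, 0)

  full <- apply_model_spec(model_spec("full"),
                           list(alpha_acq = 0.2, alpha_test = 0.6,
                                beta_acq = 0.02, beta_test = 0.07))
  expect_equal(full$delta_beta, 0.05)
  expect_equal(full$delta_alpha, 0.4)

  expect_error(apply_model_spec(model_spec("full"),
                                list(alpha = 0.3, beta = 0.05)), "needs")
  expect_error(apply_model_spec(model_spec("shared"),
                                list(alpha = 0.3, beta = 0.05,
                                     beta_acq = 0.01)), "free parameters")
  counts <- vapply(c("shared", "alpha_only", "beta_only", "full"),
                   function(m) n_free_params(model_spec(m)), 0L)
  expect_identical(unname(counts), c(2L, 3L, 3L, 4L))
})

test_that("session log-likelihood replays trials exactly", {
  cfg <- task_config()
  # single trial at beta = 0 is uniform over the four odors
  one <- session("m", "mCherry",
                 trial_row("acquisition", 1L, 2L, FALSE))
  ll <- session_loglik(one, rl_params(0.5, 0.5, 0, 0),
                       initial_values(c(0, 20, 0, 0)), cfg)
  expect_equal(ll$total, log(0.25), tolerance = 1e-12)

  # omissions and reminders contribute nothing
  om <- session("m", "mCherry", rbind(
    trial_row("acquisition", 1L, NA_integer_, FALSE),
    trial_row("acquisition", 2L, NA_integer_, FALSE),
    trial_row("acquisition", 3L, NA_integer_, TRUE, reminder = TRUE)))
  llo <- session_loglik(om, rl_params(0.5, 0.5, 0.05, 0.05),
                        initial_values(c(0, 20, 0, 0)), cfg)
  expect_equal(llo$total, 0)
  expect_length(llo$pointwise, 0)

  # three-trial hand playthrough: O2 unrewarded, O1 rewarded, O1 rewarded
  sess <- session("m", "mCherry", rbind(
    trial_row("acquisition", 1L, 2L, FALSE),
    trial_row("acquisition", 2L, 1L, TRUE),
    trial_row("acquisition", 3L, 1L, TRUE)))
  alpha <- 0.5; beta <- 0.02
  v <- c(0, 20, 0, 0)
  hand <- log(naive_softmax(v, beta)[2])            # choose O2 at [0,20,0,0]
  v2 <- c(0, 10, 0, 0)                              # Q2: 20 -> 10
  hand <- hand + log(naive_softmax(v2, beta)[1])    # choose O1
  v3 <- c(50, 10, 0, 0)                             # Q1: 0 -> 50
  hand <- hand + log(naive_softmax(v3, beta)[1])    # choose O1 again
  got <- session_loglik(sess, rl_params(alpha, alpha, beta, beta),
                        initial_values(v), cfg)
  expect_equal(got$total, hand, tolerance = 1e-12)
  expect_length(got$pointwise, 3L)
})

test_that("total log-likelihood equals the pointwise sum", {
  cfg <- task_config()
  agent <- agent_spec(rl_params(0.4, 0.6, 0.03, 0.04), seed = 9)
  sess <- simulate_session(agent, cfg, max_trials = 40,
                           stop_at_criterion = FALSE)
  ll <- session_loglik(sess, agent$params, agent$init_values, cfg)
  expect_equal(ll$total, sum(ll$pointwise), tolerance = 1e-10)
})

test_that("R and compiled likelihood routes agree", {
  cfg <- task_config()
  set.seed(31)
  sessions <- lapply(1:4, function(i) {
    ag <- agent_spec(rl_params(stats::runif(1, 0.2, 0.8),
                               stats::runif(1, 0.2, 0.8),
                               stats::runif(1, 0.01, 0.06),
                               stats::runif(1, 0.01, 0.06)),
                     mouse_id = paste0("m", i), seed = 100 + i)
    simulate_session(ag, cfg, max_trials = 30, stop_at_criterion = FALSE)
  })
  pk <- foragefit:::pack_sessions(sessions, cfg)
  al <- t(vapply(sessions, function(s) {
    a <- attr(s, "agent")$params; c(a$alpha_acq, a$alpha_test)
  }, numeric(2)))
  be <- t(vapply(sessions, function(s) {
    a <- attr(s, "agent")$params; c(a$beta_acq, a$beta_test)
  }, numeric(2)))
  v <- as.numeric(attr(sessions[[1]], "agent")$init_values)
  cpp <- foragefit:::cohort_loglik(pk$choice, pk$reward, pk$phase,
                                   pk$offsets, al, be, v, cfg$n_odors,
                                   cfg$reward_magnitude,
                                   cfg$carry_over_values)
  for (i in seq_along(sessions)) {
    ag <- attr(sessions[[i]], "agent")
    rll <- session_loglik(sessions[[i]], ag$params, ag$init_values, cfg)
    expect_equal(cpp$totals[i], rll$total, tolerance = 1e-8)
  }
})

test_that("the generating parameters beat strongly perturbed ones on average", {
  cfg <- task_config()
  true <- rl_params(0.5, 0.5, 0.03, 0.03)
  pert <- rl_params(0.75, 0.75, 0.045, 0.045)  # +50%
  pert2 <- rl_params(0.25, 0.25, 0.015, 0.015) # -50%
  v <- initial_values(c(0, 25, 0, 0))
  diffs <- vapply(1:50, function(i) {
    sess <- simulate_session(agent_spec(true, v, omission_prob = 0, seed = i),
                             cfg, max_trials = 40, stop_at_criterion = FALSE)
    base <- session_loglik(sess, true, v, cfg)$total
    base - max(session_loglik(sess, pert, v, cfg)$total,
               session_loglik(sess, pert2, v, cfg)$total)
  }, 0)
  expect_gt(mean(diffs), 0)
})
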