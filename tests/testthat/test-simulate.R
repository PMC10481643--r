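test_that("identical agent specs and seeds reproduce sessions exactly", {
  cfg <- task_config()
  ag <- agent_spec(rl_params(0.45, 0.55, 0.03, 0.04), omission_prob = 0.05,
                   seed = 123)
  s1 <- simulate_session(ag, cfg)
  s2 <- simulate_session(ag, cfg)
  expect_identical(s1$trials, s2$trials)
  expect_identical(s1$disqualified, s2$disqualified)
})

test_that("a near-deterministic exploiter reaches criterion in 8 choices", {
  cfg <- task_config()
  # odor 1 holds the maximum initial value and beta is very large, so the
  # softmax is effectively an argmax from the first trial
  pars <- rl_params(0.5, 0.5, 10, 10)
  v <- initial_values(c(40, 10, 0, 0))
  ctc <- vapply(1:300, function(i) {
    s <- simulate_session(agent_spec(pars, v, omission_prob = 0, seed = i),
                          cfg, phases = "acquisition")
    choices_to_criterion(s, "acquisition", cfg)$choices
  }, 0L)
  expect_true(all(ctc == 8L))
})

test_that("beta = 0 yields uniform choice frequencies", {
  cfg <- task_config()
  pars <- rl_params(0.5, 0.5, 0, 0)
  s <- simulate_session(agent_spec(pars, omission_prob = 0, seed = 7),
                        cfg, max_trials = 10000, stop_at_criterion = FALSE,
                        phases = "acquisition")
  freq <- tabulate(completed_trials(s)$choice, 4) / 10000
  expect_true(all(abs(freq - 0.25) < 4 * sqrt(0.25 * 0.75 / 10000)))
})

test_that("entry sequences end at the dig without immediate repeats", {
  set.seed(5)
  for (i in 1:200) {
    q <- stats::rnorm(4, sd = 30)
    e <- simulate_entries(q, slope = stats::runif(1, 0, 0.2))
    expect_gt(length(e), 0)
    if (length(e) > 1) expect_true(all(diff(e) != 0))
    ch <- sample(1:4, 1)
    ec <- simulate_entries(q, slope = 0.05, choice = ch)
    expect_identical(ec[length(ec)], ch)
    expect_identical(anyDuplicated(ec), 0L)
  }
  expect_identical(simulate_entries(c(0, 30, 0, 0), 0.05, seed = 3),
                   simulate_entries(c(0, 30, 0, 0), 0.05, seed = 3))
})

test_that("steep acceptance with a dominant value makes digs single-entry", {
  q <- c(80, 0, 0, 0)
  single <- mean(vapply(1:500, function(i)
    length(simulate_entries(q, slope = 50, seed = i)) == 1L, TRUE))
  expect_gt(single, 0.9)
})

test_that("flat acceptance matches the exact enumeration of the entry walk", {
  # slope 0: uniform approach order, coin-flip digs, forced best pot after a
  # full rejected circuit (re-approached only if not already last)
  q <- c(10, 40, 0, 5)
  best <- which.max(q)
  perms <- as.matrix(expand.grid(rep(list(1:4), 4)))
  perms <- perms[apply(perms, 1, function(r) length(unique(r)) == 4L), ]
  exp_len <- 0
  for (r in seq_len(nrow(perms))) {
    for (k in 1:4) exp_len <- exp_len + (1 / nrow(perms)) * 0.5^k * k
    forced_len <- if (perms[r, 4] == best) 4 else 5
    exp_len <- exp_len + (1 / nrow(perms)) * 0.5^4 * forced_len
  }
  sim <- mean(vapply(1:4000, function(i)
    length(simulate_entries(q, slope = 0, seed = i)), 0L))
  expect_equal(sim, exp_len, tolerance = 0.05)
})

test_that("zero hyper-variance makes a group's animals identical", {
  cfg <- task_config()
  co <- simulate_cohort(
    list(mCherry = gspec(4, 0.5, 0.5, 0.03, 0.03, 0, 0)), cfg, seed = 2)
  gt <- attr(co, "ground_truth")
  expect_equal(length(unique(gt$alpha_acq)), 1L)
  expect_equal(length(unique(gt$beta_test)), 1L)
  one <- simulate_cohort(list(mCherry = gspec(1, 0.5, 0.5, 0.03, 0.03)),
                         cfg, seed = 3)
  expect_length(one, 1L)
})

test_that("raising beta lowers mean choices to criterion", {
  cfg <- task_config()
  mean_ctc <- vapply(c(0.01, 0.03, 0.08), function(b) {
    ctc <- vapply(1:300, function(i) {
      ag <- agent_spec(rl_params(0.5, 0.5, b, b), omission_prob = 0,
                       seed = 10000 + i)
      s <- simulate_session(ag, cfg, max_trials = 200,
                            phases = "acquisition")
      choices_to_criterion(s, "acquisition", cfg)$choices
    }, 0L)
    mean(ctc)
  }, 0)
  expect_true(all(diff(mean_ctc) < 0))
})

test_that("omission rules generate reminders and disqualification", {
  cfg <- task_config()
  ag <- agent_spec(rl_params(0.5, 0.5, 0.05, 0.05), omission_prob = 0.9,
                   seed = 42)
  s <- simulate_session(ag, cfg, max_trials = 60)
  expect_true(s$disqualified)
  acc <- omission_accounting(s$trials, cfg)
  expect_true(acc$disqualified)
  expect_identical(sum(s$trials$reminder),
                   acc$n_pairs - 1L)  # disqualifying pair gets no reminder
  expect_error(simulate_session(ag, cfg, max_trials = 5), "max_trials")
})

test_that("simulated pose tracks honour drift, noise and missingness", {
  still <- simulate_pose_track(pose_spec(n_frames = 100, angular_drift = 0,
                                         seed = 1))
  r <- analyze_rotation(still)
  expect_true(all(abs(r$angle_series) < 1e-9))

  sp <- pose_spec(n_frames = 200, angular_drift = 4, step_noise = 0,
                  missing_prob = 0.05, seed = 8)
  tr <- simulate_pose_track(sp)
  expect_true(anyNA(tr$head_x) || anyNA(tr$torso_x) || anyNA(tr$tail_x))
  pp <- preprocess_track(tr)
  expect_false(anyNA(pp$head_x) || anyNA(pp$torso_x) || anyNA(pp$tail_x))
  expect_identical(nrow(pp), nrow(tr) - 5L)

  expect_identical(simulate_pose_track(sp), simulate_pose_track(sp))
})
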