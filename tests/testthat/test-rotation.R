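make_track <- function(headings_deg, head_dist = 20, tail_dist = 30,
                       cx = 100, cy = 100, fps = 15) {
  h <- headings_deg * pi / 180
  pose_track(data.frame(
    frame = seq_along(h),
    head_x = cx + head_dist * cos(h), head_y = cy + head_dist * sin(h),
    torso_x = cx, torso_y = cy,
    tail_x = cx - tail_dist * cos(h), tail_y = cy - tail_dist * sin(h)),
    fps = fps)
}

test_that("preprocessing imputes, preserves polynomials and trims frames", {
  # constant positions survive the polynomial filter unchanged
  const <- make_track(rep(30, 40))
  pp <- preprocess_track(const)
  expect_identical(nrow(pp), 35L)
  expect_equal(pp$head_x, rep(const$head_x[1], 35), tolerance = 1e-9)

  # a single missing coordinate is filled with the nearest neighbour
  gap <- const
  gap$torso_x[10] <- NA_real_
  pp2 <- preprocess_track(gap)
  expect_false(anyNA(pp2$torso_x))
  expect_equal(pp2$torso_x, pp$torso_x, tolerance = 1e-9)
  expect_equal(impute_nearest(c(NA, 1, NA, 3, NA)), c(1, 1, 1, 3, 3))
  # equidistant gaps resolve to the earlier frame
  expect_equal(impute_nearest(c(1, NA, 3)), c(1, 1, 3))

  # straight-line motion is invariant under a degree-3 filter
  lin <- pose_track(data.frame(
    frame = 1:40,
    head_x = 1:40 * 2, head_y = 1:40 * -1,
    torso_x = 1:40 * 2 - 5, torso_y = 1:40 * -1,
    tail_x = 1:40 * 2 - 11, tail_y = 1:40 * -1), fps = 15)
  pl <- preprocess_track(lin)
  expect_equal(pl$head_x, lin$head_x[6:40], tolerance = 1e-9)

  expect_error(preprocess_track(make_track(rep(0, 15))), "too short")
  allna <- const
  allna$tail_x <- NA_real_
  expect_error(preprocess_track(allna), "entirely missing")
})

test_that("rotation series recovers rigid rotation and wraps the axis crossing", {
  # rigid body at +4 deg/frame
  tr <- make_track(4 * (0:199))
  ang <- compute_rotation_series(preprocess_track(tr))
  expect_true(all(abs(ang - 4) < 0.01))

  # static posture
  expect_true(all(abs(compute_rotation_series(preprocess_track(
    make_track(rep(77, 60))))) < 1e-9))

  # headings stepping 179 -> -179 report +2, never -358
  cross <- make_track(seq(150, 250, by = 2))  # crosses 180
  angc <- compute_rotation_series(preprocess_track(cross))
  expect_true(all(abs(angc - 2) < 0.01))
  expect_equal(foragefit:::wrap_angle(-358), 2)
  expect_equal(foragefit:::wrap_angle(180), 180)
  expect_equal(foragefit:::wrap_angle(-180), 180)
})

test_that("moving-state classifier reproduces the threshold rule exactly", {
  cases <- data.frame(
    disp  = c(0.5, 0.2, 0.0, 0.41, 0.4, 1.0, 0.39, 0.0),
    angle = c(1.0, 1.0, 2.5, 0.51, 1.0, 0.5, 2.01, -2.5),
    want  = c(TRUE, FALSE, TRUE, TRUE, FALSE, FALSE, TRUE, TRUE))
  got <- classify_moving(cases$angle, cases$disp)
  expect_identical(got, cases$want)
  expect_error(classify_moving(1:3, 1:2), "equal length")
})

test_that("bias score normalizes net rotation over moving frames", {
  all_pos <- score_rotation_bias(c(1, 3, 2.5), rep(TRUE, 3), fps = 15)
  expect_equal(all_pos$bias, 1)
  sym <- score_rotation_bias(c(3, -3, 1.2, -1.2), rep(TRUE, 4), fps = 15)
  expect_equal(sym$bias, 0)
  none <- score_rotation_bias(c(1, 2), c(FALSE, FALSE), fps = 15)
  expect_true(is.na(none$bias))
  # net rate: sum of moving angles over the series duration
  r <- score_rotation_bias(rep(4, 150), rep(TRUE, 150), fps = 15)
  expect_equal(r$net_rotation_rate, 4 * 150 / (150 / 15 / 60))
})

test_that("mirroring a track negates bias and net rotation exactly", {
  tr <- simulate_pose_track(pose_spec(n_frames = 400, angular_drift = 5,
                                      step_noise = 1, seed = 3))
  tm <- as.data.frame(tr)
  for (cl in c("head_y", "torso_y", "tail_y")) tm[[cl]] <- -tm[[cl]]
  r1 <- analyze_rotation(tr)
  r2 <- analyze_rotation(pose_track(tm, fps = 15))
  expect_equal(r1$bias, -r2$bias, tolerance = 1e-12)
  expect_equal(r1$net_rotation_rate, -r2$net_rotation_rate, tolerance = 1e-12)
  expect_identical(r1$moving_mask, r2$moving_mask)
})

test_that("bias is bounded and invariant to uniform spatial scaling", {
  set.seed(14)
  for (i in 1:10) {
    tr <- simulate_pose_track(pose_spec(
      n_frames = 300, angular_drift = stats::runif(1, -6, 6),
      step_noise = stats::runif(1, 0, 2), seed = i))
    r <- analyze_rotation(tr)
    expect_true(is.na(r$bias) || (r$bias >= -1 && r$bias <= 1))
    sc <- as.data.frame(tr)
    for (cl in setdiff(names(sc), "frame")) sc[[cl]] <- sc[[cl]] * 3
    r3 <- analyze_rotation(pose_track(sc, fps = 15))
    # angles are scale-free; displacements only grow, so moving frames with
    # ample displacement keep their classification
    expect_equal(r3$angle_series, r$angle_series, tolerance = 1e-9)
  }
})

test_that("known angular drift is recovered through the full pipeline", {
  set.seed(99)
  for (i in 1:10) {
    drift <- sample(c(-1, 1), 1) * stats::runif(1, 2, 8)
    tr <- simulate_pose_track(pose_spec(n_frames = 500, angular_drift = drift,
                                        step_noise = 0.5,
                                        missing_prob = 0.02, seed = 300 + i))
    r <- analyze_rotation(tr)
    est <- mean(r$angle_series[r$moving_mask])
    expect_identical(sign(est), sign(drift))
    expect_lt(abs(est - drift) / abs(drift), 0.1)
  }
})
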