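test_that("joint_angle matches the law of cosines", {
  expect_equal(joint_angle(c(-1, 0), c(0, 0), c(1, 0)), 180)
  expect_equal(joint_angle(c(0, 1), c(0, 0), c(1, 0)), 90)
  set.seed(20)
  for (i in 1:25) {
    p <- matrix(rnorm(6), 3, 2)
    a <- sqrt(sum((p[1, ] - p[2, ])^2))
    b <- sqrt(sum((p[3, ] - p[2, ])^2))
    cc <- sqrt(sum((p[1, ] - p[3, ])^2))
    want <- acos((a^2 + b^2 - cc^2) / (2 * a * b)) * 180 / pi
    expect_equal(joint_angle(p[1, ], p[2, ], p[3, ]), want,
                 tolerance = 1e-9)
  }
  expect_error(joint_angle(c(0, 0), c(0, 0), c(1, 0)), "coincides")
})

test_that("reconstruct_knee solves the two-circle intersection", {
  expect_equal(reconstruct_knee(c(0, 0), c(0, -2), sqrt(2), sqrt(2)),
               c(x = 1, y = -1), tolerance = 1e-12)
  expect_equal(reconstruct_knee(c(0, 0), c(0, -2), sqrt(2), sqrt(2),
                                branch = "posterior"),
               c(x = -1, y = -1), tolerance = 1e-12)
  # fully extended limb: unique solution on the chord
  ext <- reconstruct_knee(c(0, 0), c(0, -3), 1.5, 1.5)
  expect_equal(unname(ext), c(0, -1.5), tolerance = 1e-7)
  expect_error(reconstruct_knee(c(0, 0), c(10, 0), 1.5, 1.5),
               "frame")
  # both distance constraints hold on random feasible configurations
  set.seed(21)
  for (i in 1:25) {
    H <- rnorm(2)
    femur <- runif(1, 1, 2); tibia <- runif(1, 1, 2)
    d <- runif(1, abs(femur - tibia) + 0.05, femur + tibia - 0.05)
    th <- runif(1, 0, 2 * pi)
    A <- H + d * c(cos(th), sin(th))
    K <- reconstruct_knee(H, A, femur, tibia)
    expect_equal(sqrt(sum((K - H)^2)), femur, tolerance = 1e-9)
    expect_equal(sqrt(sum((K - A)^2)), tibia, tolerance = 1e-9)
  }
})

test_that("stance onsets are found at toe-x maxima", {
  # sinusoidal toe trajectory: maxima at the analytic peaks
  fps <- 250
  tt <- (0:999) / fps
  toe <- sin(2 * pi * 2 * tt)          # peaks at t = 0.125 + k/2
  det <- detect_stance_onsets(toe, fps)
  want <- round((0.125 + (0:7) / 2) * fps)
  expect_equal(det$stance_onsets, want, tolerance = 1)

  expect_identical(detect_stance_onsets(rep(1, 100), fps,
                                        min_prominence = 0.1)$stance_onsets,
                   integer(0))
  expect_identical(detect_stance_onsets(seq_len(100), fps)$stance_onsets,
                   integer(0))
  expect_error(detect_stance_onsets(c(1, 2), fps), "3 frames")

  # synthetic gait trial: onsets match ground truth within one frame
  g <- gait_params(n_steps = 6, marker_noise_sd = 0, seed = 11)
  sim <- generate_kinematic_trial(g)
  det2 <- detect_stance_onsets(sim$markers$toe_x, g$fps)
  expect_identical(length(det2$stance_onsets),
                   length(sim$ground_truth$stance_onset_frames))
  expect_true(all(abs(det2$stance_onsets -
                        sim$ground_truth$stance_onset_frames) <= 1))
  expect_true(all(abs(det2$swing_onsets -
                        sim$ground_truth$swing_onset_frames[
                          seq_along(det2$swing_onsets)]) <= 1))
})

test_that("normalize_step resamples each phase to a fixed grid", {
  step <- list(stance_onset = 10L, swing_onset = 40L, end = 60L)
  const <- normalize_step(rep(2.5, 100), step)
  expect_length(const, 100)
  expect_true(all(const == 2.5))

  ramp <- normalize_step(seq(0, 99), step)
  expect_equal(ramp[1], 10, tolerance = 1e-12)
  expect_equal(ramp[50], 40, tolerance = 1e-12)
  expect_equal(ramp[100], 60, tolerance = 1e-12)
  # each phase is linear on its own grid
  expect_equal(diff(ramp[1:50]), rep(30 / 49, 49), tolerance = 1e-9)

  # commutes with affine transforms of the signal
  x <- cumsum(rnorm(100))
  expect_equal(normalize_step(3 * x + 7, step),
               3 * normalize_step(x, step) + 7, tolerance = 1e-10)

  expect_error(normalize_step(x, list(stance_onset = 10, swing_onset = 10,
                                      end = 20)), "degenerate")
  expect_error(normalize_step(x, list(stance_onset = 10, swing_onset = 50,
                                      end = 150)), "range")
})

test_that("normalized knee profile reproduces the programmed waveform", {
  g <- gait_params(n_steps = 6, marker_noise_sd = 0, seed = 12)
  sim <- generate_kinematic_trial(g)
  gt <- sim$ground_truth
  K <- reconstruct_knee(as.matrix(gt$markers[, c("hip_x", "hip_y")]),
                        as.matrix(gt$markers[, c("ankle_x", "ankle_y")]),
                        g$femur, g$tibia)
  knee_angle <- joint_angle(as.matrix(gt$markers[, c("hip_x", "hip_y")]),
                            K,
                            as.matrix(gt$markers[, c("ankle_x", "ankle_y")]))
  profs <- lapply(seq_len(nrow(gt$steps)), function(i)
    normalize_step(knee_angle, gt$steps[i, ]))
  # the programmed waveform, sampled on the same normalized grid
  sf <- g$stance_fraction
  u_grid <- c(seq(0, sf, length.out = 50), seq(sf, 1, length.out = 50))
  u_grid[100] <- 1 - 1e-12
  want <- locokit:::gait_angles_at(u_grid %% 1, sf, g$joint_waveforms)$knee
  for (prof in profs)
    expect_lt(max(abs(prof - want)), 0.1)
})

test_that("gait_summary computes durations, duty factor, and contact stats", {
  steps <- data.frame(stance_onset = 0L, swing_onset = 75L, end = 100L)
  gs <- gait_summary(steps, fps = 250)
  expect_equal(gs$per_step$stance_s, 0.3)
  expect_equal(gs$per_step$swing_s, 0.1)
  expect_equal(gs$per_step$period_s, 0.4)
  expect_equal(gs$per_step$duty_factor, 0.75)
  expect_equal(gs$per_step$stance_s + gs$per_step$swing_s,
               gs$per_step$period_s)

  contacts <- data.frame(lf = rep(1, 50), rf = 1, lh = 1, rh = 1)
  paw_x <- data.frame(lf = rep(0.4, 50), rf = -0.4, lh = 1.2, rh = -1.2)
  gs2 <- gait_summary(steps, fps = 250, contacts = contacts, paw_x = paw_x)
  expect_equal(unname(gs2$contact_proportions["4"]), 1)
  expect_equal(sum(gs2$contact_proportions), 1)
  expect_equal(gs2$front_spacing, 0.8)
  expect_equal(gs2$rear_spacing, 2.4)

  # generator with programmed stance fraction 0.6
  g <- gait_params(n_steps = 8, marker_noise_sd = 0, seed = 13)
  sim <- generate_kinematic_trial(g)
  det <- detect_stance_onsets(sim$markers$toe_x, g$fps)
  st <- step_cycles(det$stance_onsets, det$swing_onsets)
  gs3 <- gait_summary(st, fps = g$fps)
  expect_lt(abs(gs3$mean_duty_factor - 0.6), 0.05)
})

test_that("slope_comparison tests slope equality via the interaction term", {
  set.seed(22)
  x <- runif(50, 0.2, 1)
  y <- 0.5 * x + rnorm(50, sd = 0.01)
  same <- slope_comparison(x, y, x, y)
  expect_equal(same$slope1, same$slope2, tolerance = 1e-9)
  expect_gt(same$p, 0.99)

  y2 <- 0.8 * x + rnorm(50, sd = 0.01)
  y1 <- 0.2 * x + rnorm(50, sd = 0.01)
  diffres <- slope_comparison(x, y1, x, y2)
  expect_lt(diffres$p, 0.001)
  expect_equal(diffres$slope1, 0.2, tolerance = 0.05)
  expect_equal(diffres$slope2, 0.8, tolerance = 0.05)

  # agreement with a label-permutation oracle: both reject a clear
  # slope difference, and both retain equal slopes
  set.seed(23)
  xa <- runif(40); ya <- 0.3 * xa + rnorm(40, sd = 0.05)
  xb <- runif(40); yb <- 0.9 * xb + rnorm(40, sd = 0.05)
  p_lm <- slope_comparison(xa, ya, xb, yb)$p
  p_perm <- slope_perm_oracle(xa, ya, xb, yb, n_perm = 1000, seed = 2)
  expect_lt(p_lm, 0.01)
  expect_lt(p_perm, 0.01)
  yb0 <- 0.3 * xb + rnorm(40, sd = 0.05)
  p_lm0 <- slope_comparison(xa, ya, xb, yb0)$p
  p_perm0 <- slope_perm_oracle(xa, ya, xb, yb0, n_perm = 1000, seed = 3)
  se0 <- sqrt(p_perm0 * (1 - p_perm0) / 1000)
  expect_lt(abs(p_lm0 - p_perm0), 4 * se0 + 0.05)

  expect_error(slope_comparison(1:2, 1:2, 1:5, 1:5), "3 points")
  expect_error(slope_comparison(rep(1, 5), 1:5, 1:5, 1:5), "vary")
})
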