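test_that("fictive generator respects programmed timing and determinism", {
  fp <- fictive_params(cycle_freq = 1.2, noise_sd = 0, n_cycles = 10,
                       seed = 2)
  sim <- generate_fictive_recording(fp)
  gt <- sim$ground_truth
  expect_equal(diff(gt$ext_onsets), rep(1 / 1.2, 9))
  expect_true(all(diff(gt$ext_onsets) > 0))
  expect_equal(gt$flex_onsets - gt$ext_onsets,
               rep(0.6 / 1.2, 10))

  sim2 <- generate_fictive_recording(fp)
  expect_identical(sim$roots$flexor$samples, sim2$roots$flexor$samples)
  expect_identical(sim$roots$extensor$samples, sim2$roots$extensor$samples)

  # independent substreams: adding spikes leaves the roots untouched
  sim3 <- generate_fictive_recording(fp, spikes = spike_train_params(seed = 2))
  expect_identical(sim3$roots$extensor$samples, sim$roots$extensor$samples)

  expect_error(fictive_params(cycle_freq = -1), "cycle_freq")
  expect_error(fictive_params(extensor_fraction = 1), "extensor_fraction")
  expect_error(fictive_params(noise_sd = NaN), "noise_sd")
})

test_that("spike phases follow the programmed von Mises distribution", {
  # degenerate concentration: all phases at mu
  sharp <- generate_fictive_recording(
    fictive_params(n_cycles = 30, seed = 5),
    spikes = spike_train_params(mu_phase = 0.25, kappa = 1e6,
                                spikes_per_cycle = 5, seed = 5))
  expect_true(all(abs(sharp$ground_truth$spike_phases - 0.25) < 1e-3))
  expect_true(all(sharp$ground_truth$spike_phases >= 0 &
                    sharp$ground_truth$spike_phases < 1))

  # circular mean converges to mu_phase within 3 standard errors
  big <- generate_fictive_recording(
    fictive_params(n_cycles = 100, seed = 6),
    spikes = spike_train_params(mu_phase = 0.3, kappa = 3,
                                spikes_per_cycle = 10, seed = 6))
  st <- circular_stats(big$ground_truth$spike_phases)
  n <- st$n
  se <- 1 / sqrt(n * st$r * 3)     # kappa ~ 3 circular SE approximation
  expect_lt(abs(st$phi - 0.3), 3 * se)

  # spike times are consistent with their phases via the cycle map
  ph_back <- phase_of_time(big$ground_truth$spike_times,
                           big$ground_truth$cycles)
  expect_equal(ph_back, big$ground_truth$spike_phases, tolerance = 1e-9)
})

test_that("PSC events are phase-gated Poisson draws", {
  fp <- fictive_params(noise_sd = 0, n_cycles = 100, seed = 9)
  sim <- generate_fictive_recording(
    fp, pscs = psc_train_params(rate_flexor = 10, rate_extensor = 0,
                                amplitude_mean = 20, amplitude_sd = 2,
                                seed = 9))
  gt <- sim$ground_truth
  expect_true(all(gt$psc_phases >= 0.5 & gt$psc_phases < 1))
  total_flexor_time <- sum(gt$cycle_ends - gt$flex_onsets)
  lambda <- 10 * total_flexor_time
  expect_lt(abs(length(gt$psc_times) - lambda), 3 * sqrt(lambda))
  expect_true(all(diff(gt$psc_times) > 0))
  expect_true(inherits(sim$intracellular, "trace"))
})

test_that("brief extra flexor bursts are recorded without moving cycle boundaries", {
  fp <- fictive_params(noise_sd = 0, n_cycles = 40,
                       brief_flexor_burst_prob = 0.5, seed = 10)
  sim <- generate_fictive_recording(fp)
  gt <- sim$ground_truth
  expect_gt(nrow(gt$brief_flexor_bursts), 0)
  expect_equal(diff(gt$ext_onsets), rep(1 / 1.2, 39))
  # brief bursts lie inside the extensor phase and last 25% of a flexor burst
  for (i in seq_len(nrow(gt$brief_flexor_bursts))) {
    b <- gt$brief_flexor_bursts[i, ]
    k <- findInterval(b$onset, gt$ext_onsets)
    expect_gt(b$onset, gt$ext_onsets[k])
    expect_lt(b$offset, gt$flex_onsets[k])
    expect_equal(b$offset - b$onset, 0.25 * 0.4 / 1.2, tolerance = 1e-9)
  }
})

test_that("gait generator produces a consistent two-link trial", {
  g <- gait_params(n_steps = 8, marker_noise_sd = 0, seed = 3)
  sim <- generate_kinematic_trial(g)
  gt <- sim$ground_truth
  expect_identical(length(gt$stance_onset_frames), 8L)
  # forward/inverse kinematics roundtrip recovers the knee exactly
  K <- reconstruct_knee(as.matrix(gt$markers[, c("hip_x", "hip_y")]),
                        as.matrix(gt$markers[, c("ankle_x", "ankle_y")]),
                        g$femur, g$tibia)
  expect_lt(max(abs(K - gt$knee_xy)), 1e-9)
  # segment lengths hold on every frame
  d_ht <- sqrt((gt$markers$hip_x - gt$markers$knee_x)^2 +
                 (gt$markers$hip_y - gt$markers$knee_y)^2)
  expect_equal(d_ht, rep(g$femur, length(d_ht)), tolerance = 1e-9)

  # constant joint angles freeze every marker
  g0 <- gait_params(joint_waveforms = list(
    hip_amp = 0, knee_stance_amp = 0, knee_swing_amp = 0,
    ankle_stance_amp = 0, ankle_swing_amp = 0))
  s0 <- generate_kinematic_trial(g0)
  ranges <- vapply(s0$markers[setdiff(names(s0$markers), "frame")],
                   function(col) diff(range(col)), numeric(1))
  expect_true(all(ranges == 0))

  # determinism of the noisy marker table
  gn <- gait_params(marker_noise_sd = 0.02, seed = 7)
  expect_identical(generate_kinematic_trial(gn)$markers,
                   generate_kinematic_trial(gn)$markers)
})

test_that("recovery series follows the Hill curve with seeded noise", {
  days <- c(0, 10, 20, 40, 60)
  clean <- generate_recovery_series(0.8, 2, 20, days, noise_sd = 0)
  expect_equal(clean$S[clean$T == 20], 0.4)   # T = k_half gives S_max / 2
  expect_equal(clean$S[clean$T == 0], 0)
  a <- generate_recovery_series(0.8, 2, 20, days, noise_sd = 0.1, seed = 5)
  b <- generate_recovery_series(0.8, 2, 20, days, noise_sd = 0.1, seed = 5)
  expect_identical(a, b)
  expect_true(all(a$S >= 0))
  expect_error(generate_recovery_series(0.8, 2, 20, numeric(0)),
               "non-empty")
})
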