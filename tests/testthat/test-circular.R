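test_that("circular_stats matches hand computation on simple samples", {
  locked <- circular_stats(rep(0.3, 50))
  expect_equal(locked$r, 1)
  expect_equal(locked$phi, 0.3)

  even <- circular_stats((0:49) / 50)
  expect_lt(even$r, 1e-9)

  pair <- circular_stats(c(0, 0.25))
  expect_equal(pair$phi, 0.125)
  expect_equal(pair$r, sqrt(2) / 2)

  expect_error(circular_stats(numeric(0)), "empty")
  expect_error(circular_stats(c(0.2, 1.0)), "\\[0, 1\\)")
})

test_that("circular_stats agrees with the brute-force oracle to 1e-12", {
  set.seed(7)
  for (i in 1:20) {
    phases <- runif(sample(5:300, 1))
    got <- circular_stats(phases)
    want <- circ_oracle(phases)
    expect_equal(got$r, want$r, tolerance = 1e-12)
    expect_equal(got$phi, want$phi, tolerance = 1e-12)
  }
})

test_that("rotation shifts the mean phase and leaves r unchanged", {
  set.seed(8)
  phases <- rbeta(80, 2, 5)
  base <- circular_stats(phases)
  for (shift in c(0.1, 0.37, 0.73)) {
    rot <- circular_stats((phases + shift) %% 1)
    expect_equal(rot$r, base$r, tolerance = 1e-12)
    expect_equal(rot$phi, (base$phi + shift) %% 1, tolerance = 1e-10)
  }
})

test_that("rayleigh_p follows exp(-n r^2)", {
  expect_equal(rayleigh_p(50, 0), 1)
  expect_equal(rayleigh_p(50, 0.2448), 0.05, tolerance = 0.01)
  expect_equal(rayleigh_p(50, 0.24), exp(-50 * 0.24^2))
  expect_equal(rayleigh_p(50, 0.24), 0.056, tolerance = 0.01)
})

test_that("critical_r inverts the Rayleigh threshold and scales as 1/sqrt(n)", {
  expect_equal(round(critical_r(50, 0.05), 2), 0.24)
  expect_equal(critical_r(50, 0.05), sqrt(-log(0.05) / 50))
  expect_equal(critical_r(50, 0.05), 0.2448, tolerance = 1e-3)
  expect_equal(critical_r(10, 0.05), sqrt(-log(0.05) / 10))
  expect_equal(critical_r(10, 0.05), 0.5474, tolerance = 1e-3)
  n <- c(10, 25, 50, 200)
  expect_equal(critical_r(4 * n, 0.05), critical_r(n, 0.05) / 2)
  expect_error(critical_r(50, 1.2), "alpha")
  # self-consistency: p at the threshold equals alpha
  expect_equal(rayleigh_p(37, critical_r(37, 0.05)), 0.05)
})

test_that("phase_class uses half-open extensor/flexor intervals", {
  expect_identical(phase_class(0.25), "extensor")
  expect_identical(phase_class(0.75), "flexor")
  expect_identical(phase_class(0.5), "flexor")
  expect_identical(phase_class(0), "extensor")
  expect_error(phase_class(1))
})

test_that("classify_rhythmicity subsamples, thresholds, and classifies", {
  res <- classify_rhythmicity(rep(0.25, 200), seed = 1)
  expect_true(res$rhythmic)
  expect_identical(res$phase_class, "extensor")
  expect_identical(res$n_subsampled, 50L)
  expect_identical(res$n_total, 200L)

  # fewer spikes than the subsample: threshold recomputed for actual n
  few <- classify_rhythmicity(rep(0.8, 20), seed = 1)
  expect_true(few$rhythmic)
  expect_identical(few$n_subsampled, 20L)
  expect_equal(few$threshold, critical_r(20, 0.05))
  expect_identical(few$phase_class, "flexor")

  # deterministic given the seed
  set.seed(99)
  ph <- runif(300)
  a <- classify_rhythmicity(ph, seed = 5)
  b <- classify_rhythmicity(ph, seed = 5)
  expect_identical(a$stat$r, b$stat$r)

  expect_error(classify_rhythmicity(numeric(0), seed = 1), "empty")
  expect_error(classify_rhythmicity(runif(10)), "seed")
})

test_that("type-I error of the rhythmicity rule is near alpha under uniform phases", {
  set.seed(123)
  n_rep <- 100
  calls <- vapply(seq_len(n_rep), function(i) {
    phases <- runif(500)
    classify_rhythmicity(phases, seed = i)$rhythmic
  }, logical(1))
  rate <- mean(calls)
  band <- 3 * sqrt(0.05 * 0.95 / n_rep)
  expect_lt(abs(rate - 0.05), band + 1e-12)
})

test_that("mean-phase recovery from von Mises samples is unbiased", {
  sim <- generate_fictive_recording(
    fictive_params(n_cycles = 50, seed = 21),
    spikes = spike_train_params(mu_phase = 0.25, kappa = 2,
                                spikes_per_cycle = 4, seed = 21))
  res <- classify_rhythmicity(sim$ground_truth$spike_phases, n_sub = 200,
                              seed = 3)
  expect_true(res$rhythmic)
  expect_lt(abs(res$stat$phi - 0.25), 0.05)

  # bias of the circular mean over many replicates at kappa = 2, n = 50
  set.seed(31)
  err <- vapply(1:400, function(i) {
    ph <- locokit:::rvonmises_phase(50, 0.4, 2)
    d <- circular_stats(ph)$phi - 0.4
    (d + 0.5) %% 1 - 0.5      # wrapped signed error
  }, numeric(1))
  expect_lt(abs(mean(err)), 0.01)
})

test_that("interlimb_phase measures left-right coordination", {
  ref <- as.numeric(0:19)
  expect_equal(interlimb_phase(ref, ref[-1] + 1e-12)$phi, 0,
               tolerance = 1e-6)
  mid <- interlimb_phase(ref, ref[-20] + 0.5)
  expect_equal(mid$phi, 0.5)
  expect_equal(mid$r, 1)
  expect_error(interlimb_phase(ref, 100), "no target onset")
  expect_error(interlimb_phase(1, 1.5), "reference")

  # programmed left-right lag of 0.46 cycles is recovered
  gt <- generate_fictive_recording(
    fictive_params(noise_sd = 0, n_cycles = 20, seed = 4))$ground_truth
  left <- gt$ext_onsets + 0.46 * (1 / 1.2)
  res <- interlimb_phase(gt$ext_onsets, left)
  expect_lt(abs(res$phi - 0.46), 0.02)
  expect_gt(res$r, 0.99)
})
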