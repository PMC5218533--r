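# locokit

Quantitative analysis of rhythmic locomotor output and its recovery, for
experimenters working with isolated spinal cord preparations and rodent
treadmill locomotion. The package covers four linked problems:

1. **Fictive locomotion** — turning raw ventral-root recordings into
   rectified/integrated envelopes, detected bursts, and double-normalized
   locomotor cycles in which phase 0 marks extensor onset, the extensor
   phase spans [0, 0.5) and the flexor phase spans [0.5, 1) regardless of
   their real durations.
2. **Phase locking of spiking** — circular statistics on spike phases.
   With phases mapped to angles θ = 2πφ, the mean phase is
   Φ = atan2(mean sin θ, mean cos θ)/2π and the angular concentration is
   r = √((mean cos θ)² + (mean sin θ)²), with r = 1 for a cell firing at
   precisely the same phase every cycle and r = 0 for uniformly dispersed
   spikes. Significance uses the large-sample Rayleigh rule
   p = exp(−n·r²); a cell with more than 50 recorded spikes is judged on
   50 randomly subsampled spikes, for which the critical concentration at
   p < 0.05 is r* = √(−ln 0.05 / 50) ≈ 0.24.
3. **Synaptic input timing** — detection of postsynaptic currents by
   sliding scaled-template matching (the Clements–Bekkers criterion:
   fitted template scale divided by the standard error of the fit), and
   50-bin phase histograms of event times, against the 2%-per-bin level
   expected under a uniform distribution.
4. **Gait kinematics and recovery** — interior joint angles from 2-D
   marker tables, geometric knee reconstruction as the intersection of
   the femur circle around the hip with the tibia circle around the
   ankle, stance detection from toe-position maxima, 100-point step-cycle
   normalization, and the hindlimb/forelimb step ratio over days of
   training fitted with the Hill curve
   S = S_max·T^h / (k½^h + T^h).

Every analysis stage has a matching synthetic-data generator
(`generate_fictive_recording()`, `generate_kinematic_trial()`,
`generate_recovery_series()`) that returns full ground truth, so the
whole pipeline can be validated end to end on data with known answers.

## Worked example

```r
library(locokit)

fp  <- fictive_params(cycle_freq = 1.2, n_cycles = 20, noise_sd = 0.05, seed = 42)
sim <- generate_fictive_recording(
  fp,
  spikes = spike_train_params(mu_phase = 0.25, kappa = 3,
                              spikes_per_cycle = 6, seed = 42),
  pscs   = psc_train_params(rate_flexor = 40, rate_extensor = 4,
                            polarity = "outward", seed = 42))

cfg    <- pipeline_config(flexor_channel = "flexor",
                          extensor_channel = "extensor", seed = 7)
report <- run_pipeline(cfg, sim$roots,
                       spike_trains  = list(cell_A = sim$spike_times),
                       intracellular = sim$intracellular)
report
#> <pipeline_report> 19 cycles (0 discarded); 1/1 cells rhythmic; 776 PSC events
report$rhythmicity$cell_A
#> <rhythmicity> cell_A: rhythmic (r=0.814 vs r*=0.245, n=50/109, phi=0.246, extensor)
```

The report says: 20 simulated cycles yielded 19 complete locomotor
cycles; of the cell's 109 in-cycle spikes, 50 were subsampled and their
concentration r = 0.814 exceeds the critical r* = 0.245, so the cell is
rhythmically active, with mean phase Φ = 0.246 — mid-extensor, right
where the generator put it (μ = 0.25). The detected IPSCs concentrate in
the flexor half of the cycle (73.7% of events in phase bins above 0.5,
against 50% under uniformity), matching the programmed flexor-phase
gating.

Recovery fitting works the same way:

```r
pts <- generate_recovery_series(s_max = 0.9, h = 2, k_half = 20,
                                days = seq(2, 60, by = 3),
                                noise_sd = 0.05, seed = 42)
fit_hill(pts)
#> <hill_fit> S_max=0.8638 h=2.263 k_half=18.52 days (R2=0.972)
```

i.e. from 20 noisy observations the fit recovers a maximum step ratio of
0.86 (true 0.9), a Hill slope of 2.3 (true 2) and a half-recovery time
of 18.5 days (true 20).

Command-line wrappers over the same functions live in `inst/cli/`
(`simulate.R` for dataset generation, `gait.R` for marker-table
analysis).

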