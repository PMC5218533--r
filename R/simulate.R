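#' Parameters for a simulated fictive-locomotion episode
#'
#' Defines the rhythm of a simulated drug-evoked fictive locomotor episode:
#' alternating extensor- and flexor-related ventral-root bursts at a fixed
#' cycle frequency. Defaults follow the conditions these analyses are used
#' under: a 1.2 Hz locomotor rhythm with the extensor phase occupying 60%
#' of the cycle.
#'
#' @param cycle_freq Locomotor cycle frequency in Hz (> 0). Default 1.2.
#' @param extensor_fraction Fraction of the cycle occupied by the extensor
#'   burst, in (0, 1). Default 0.6.
#' @param n_cycles Number of cycles to simulate.
#' @param noise_sd Standard deviation of additive Gaussian noise on the
#'   root traces, in envelope units (>= 0).
#' @param brief_flexor_burst_prob Probability per cycle of inserting a
#'   brief extra flexor burst in the middle of the extensor phase (duration
#'   25% of a normal flexor burst). Such bursts do not redefine cycle
#'   boundaries in the ground truth.
#' @param seed Master integer seed.
#' @return A list of class `"fictive_params"`.
#' @export
fictive_params <- function(cycle_freq = 1.2, extensor_fraction = 0.6,
                           n_cycles = 20L, noise_sd = 0.05,
                           brief_flexor_burst_prob = 0, seed = 1L) {
  check_scalar(cycle_freq, "cycle_freq", lower = 0, open_lower = TRUE)
  check_scalar(extensor_fraction, "extensor_fraction", 0, 1,
               open_lower = TRUE, open_upper = TRUE)
  check_scalar(n_cycles, "n_cycles", lower = 1)
  check_scalar(noise_sd, "noise_sd", lower = 0)
  check_scalar(brief_flexor_burst_prob, "brief_flexor_burst_prob", 0, 1)
  structure(list(cycle_freq = cycle_freq,
                 extensor_fraction = extensor_fraction,
                 n_cycles = as.integer(n_cycles), noise_sd = noise_sd,
                 brief_flexor_burst_prob = brief_flexor_burst_prob,
                 seed = seed),
            class = "fictive_params")
}

#' Parameters for a phase-locked simulated spike train
#'
#' @param mu_phase Preferred phase as a cycle fraction in \[0, 1).
#' @param kappa von Mises concentration (>= 0); 0 gives uniform phases.
#' @param spikes_per_cycle Expected spike count per cycle (Poisson).
#' @param seed Integer seed (substream; independent of other signals).
#' @return A list of class `"spike_train_params"`.
#' @export
spike_train_params <- function(mu_phase = 0.25, kappa = 2,
                               spikes_per_cycle = 5, seed = 1L) {
  check_scalar(mu_phase, "mu_phase", 0, 1, open_upper = TRUE)
  check_scalar(kappa, "kappa", lower = 0)
  check_scalar(spikes_per_cycle, "spikes_per_cycle", lower = 0)
  structure(list(mu_phase = mu_phase, kappa = kappa,
                 spikes_per_cycle = spikes_per_cycle, seed = seed),
            class = "spike_train_params")
}

#' Parameters for a phase-gated simulated synaptic-event train
#'
#' Events are drawn as an inhomogeneous Poisson process whose rate is
#' `rate_flexor` during the flexor phase and `rate_extensor` during the
#' extensor phase, emulating rhythmic synaptic input gated by the step
#' cycle (e.g. flexor-phase inhibition of extensor-active cells).
#'
#' @param rate_flexor,rate_extensor Event rates (events/s, >= 0).
#' @param amplitude_mean,amplitude_sd Event amplitude distribution (pA,
#'   `amplitude_mean > 0`); amplitudes are drawn Gaussian and truncated
#'   below at one tenth of the mean.
#' @param polarity `"outward"` (positive deflections, IPSCs at -40 mV) or
#'   `"inward"` (negative, EPSCs).
#' @param seed Integer seed (substream).
#' @return A list of class `"psc_train_params"`.
#' @export
psc_train_params <- function(rate_flexor = 50, rate_extensor = 5,
                             amplitude_mean = 20, amplitude_sd = 5,
                             polarity = c("outward", "inward"), seed = 1L) {
  check_scalar(rate_flexor, "rate_flexor", lower = 0)
  check_scalar(rate_extensor, "rate_extensor", lower = 0)
  check_scalar(amplitude_mean, "amplitude_mean", lower = 0,
               open_lower = TRUE)
  check_scalar(amplitude_sd, "amplitude_sd", lower = 0)
  polarity <- match.arg(polarity)
  structure(list(rate_flexor = rate_flexor, rate_extensor = rate_extensor,
                 amplitude_mean = amplitude_mean,
                 amplitude_sd = amplitude_sd, polarity = polarity,
                 seed = seed),
            class = "psc_train_params")
}

# raised-cosine plateau burst envelope on [0, 1], ramp = edge fraction
burst_envelope <- function(u, ramp = 0.1) {
  y <- numeric(length(u))
  inb <- u >= 0 & u <= 1
  ui <- u[inb]
  yi <- rep(1, length(ui))
  lo <- ui < ramp
  hi <- ui > 1 - ramp
  yi[lo] <- 0.5 * (1 - cos(pi * ui[lo] / ramp))
  yi[hi] <- 0.5 * (1 - cos(pi * (1 - ui[hi]) / ramp))
  y[inb] <- yi
  y
}

# map a double-normalized phase to a time inside cycle [e, f, en)
time_of_phase <- function(phase, e, f, en) {
  ifelse(phase < 0.5,
         e + (phase / 0.5) * (f - e),
         f + ((phase - 0.5) / 0.5) * (en - f))
}

#' Simulate a fictive-locomotion recording with ground truth
#'
#' Generates a pair of envelope-modulated ventral-root traces (flexor- and
#' extensor-related, in strict antiphase), an optional phase-locked spike
#' train, and an optional intracellular voltage-clamp trace carrying
#' phase-gated synaptic events. Each root trace is a white-noise carrier
#' multiplied by a raised-cosine-plateau burst envelope (so rectification
#' and integration recover the envelope), plus additive Gaussian noise of
#' standard deviation `params$noise_sd`. Spike phases are drawn from a von
#' Mises distribution around `spikes$mu_phase`; synaptic events are an
#' inhomogeneous Poisson process gated by the flexor/extensor phase. All
#' random draws use independent substreams derived from each component's
#' seed, so adding one signal never perturbs another; identical parameters
#' and seeds give bit-identical output.
#'
#' @param params A [fictive_params()] object.
#' @param spikes Optional [spike_train_params()].
#' @param pscs Optional [psc_train_params()].
#' @param fs Sampling rate in Hz (default 10000, matching 10 kHz
#'   acquisition).
#' @param psc_template Template used to render synaptic events into the
#'   intracellular trace (default [make_template()] defaults).
#' @param psc_noise_sd Baseline current noise on the intracellular trace
#'   (pA).
#' @return A list with elements:
#'   \describe{
#'     \item{roots}{list of two [trace()] objects, `flexor` and `extensor`.}
#'     \item{spike_times}{numeric vector of spike times (s), or `NULL`.}
#'     \item{intracellular}{[trace()] of holding current (pA), or `NULL`.}
#'     \item{ground_truth}{list with `ext_onsets`, `flex_onsets`,
#'       `cycle_end`s, `cycles` (a cycle table), `brief_flexor_bursts`,
#'       `spike_times`, `spike_phases`, `psc_times`, `psc_phases`,
#'       `psc_amplitudes`, and the generating parameters.}
#'   }
#' @export
generate_fictive_recording <- function(params, spikes = NULL, pscs = NULL,
                                       fs = 10000,
                                       psc_template = make_template(),
                                       psc_noise_sd = 1) {
  stopifnot(inherits(params, "fictive_params"))
  check_scalar(fs, "fs", lower = 0, open_lower = TRUE)
  P <- 1 / params$cycle_freq
  n_cyc <- params$n_cycles
  ext_onsets <- (seq_len(n_cyc) - 1L) * P
  flex_onsets <- ext_onsets + params$extensor_fraction * P
  ends <- ext_onsets + P
  cycles <- data.frame(ext_onset = ext_onsets, flex_onset = flex_onsets,
                       end = ends)
  class(cycles) <- c("cycle_table", "data.frame")
  total_t <- n_cyc * P
  dt <- 1 / fs
  tt <- seq(0, total_t, by = dt)
  n <- length(tt)

  # burst envelopes: extensor on [e, f), flexor on [f, end)
  cyc_idx <- pmin(pmax(findInterval(tt, ext_onsets), 1L), n_cyc)
  e <- ext_onsets[cyc_idx]; f <- flex_onsets[cyc_idx]; en <- ends[cyc_idx]
  env_ext <- burst_envelope((tt - e) / (f - e))
  env_ext[tt >= f] <- 0
  env_flex <- burst_envelope((tt - f) / (en - f))
  env_flex[tt < f] <- 0

  # brief extra flexor bursts mid-extensor (do not move cycle boundaries)
  brief <- data.frame(onset = numeric(0), offset = numeric(0))
  if (params$brief_flexor_burst_prob > 0) {
    has_brief <- local_seed(substream_seed(params$seed, 1L),
                            stats::runif(n_cyc) < params$brief_flexor_burst_prob)
    dur <- 0.25 * (1 - params$extensor_fraction) * P
    for (k in which(has_brief)) {
      mid <- (ext_onsets[k] + flex_onsets[k]) / 2
      b_on <- mid - dur / 2
      env_flex <- env_flex + burst_envelope((tt - b_on) / dur)
      brief <- rbind(brief, data.frame(onset = b_on, offset = b_on + dur))
    }
    env_flex <- pmin(env_flex, 1)
  }

  mk_root <- function(env, stream, channel) {
    s <- local_seed(substream_seed(params$seed, stream), {
      carrier <- stats::rnorm(n)
      noise <- if (params$noise_sd > 0)
        stats::rnorm(n, sd = params$noise_sd) else 0
      env * carrier + noise
    })
    trace(s, dt = dt, start_time = 0, channel = channel)
  }
  roots <- list(flexor = mk_root(env_flex, 2L, "flexor_root"),
                extensor = mk_root(env_ext, 3L, "extensor_root"))

  spike_times <- spike_phases <- NULL
  if (!is.null(spikes)) {
    stopifnot(inherits(spikes, "spike_train_params"))
    sp <- local_seed(substream_seed(spikes$seed, 4L), {
      counts <- stats::rpois(n_cyc, spikes$spikes_per_cycle)
      ph <- rvonmises_phase(sum(counts), spikes$mu_phase, spikes$kappa)
      list(counts = counts, phases = ph)
    })
    cyc_of_spike <- rep(seq_len(n_cyc), sp$counts)
    spike_phases <- sp$phases
    spike_times <- time_of_phase(spike_phases, ext_onsets[cyc_of_spike],
                                 flex_onsets[cyc_of_spike],
                                 ends[cyc_of_spike])
    o <- order(spike_times)
    spike_times <- spike_times[o]; spike_phases <- spike_phases[o]
  }

  intracellular <- NULL
  psc_times <- psc_phases <- psc_amp <- NULL
  if (!is.null(pscs)) {
    stopifnot(inherits(pscs, "psc_train_params"))
    drawn <- local_seed(substream_seed(pscs$seed, 5L), {
      times <- numeric(0)
      for (k in seq_len(n_cyc)) {
        d_ext <- flex_onsets[k] - ext_onsets[k]
        d_flex <- ends[k] - flex_onsets[k]
        n_e <- stats::rpois(1L, pscs$rate_extensor * d_ext)
        n_f <- stats::rpois(1L, pscs$rate_flexor * d_flex)
        times <- c(times,
                   stats::runif(n_e, ext_onsets[k], flex_onsets[k]),
                   stats::runif(n_f, flex_onsets[k], ends[k]))
      }
      times <- sort(times)
      amp <- stats::rnorm(length(times), pscs$amplitude_mean,
                          pscs$amplitude_sd)
      amp <- pmax(amp, pscs$amplitude_mean / 10)
      noise <- if (psc_noise_sd > 0)
        stats::rnorm(n, sd = psc_noise_sd) else numeric(n)
      list(times = times, amp = amp, noise = noise)
    })
    psc_times <- drawn$times
    psc_amp <- drawn$amp
    psc_phases <- phase_of_time(psc_times, cycles)
    sgn <- if (pscs$polarity == "outward") 1 else -1
    samples <- drawn$noise
    w <- psc_template$waveform
    for (i in seq_along(psc_times)) {
      i0 <- round(psc_times[i] / dt) + 1L
      i1 <- min(i0 + length(w) - 1L, n)
      if (i0 <= n)
        samples[i0:i1] <- samples[i0:i1] +
          sgn * psc_amp[i] * w[seq_len(i1 - i0 + 1L)]
    }
    intracellular <- trace(samples, dt = dt, start_time = 0,
                           channel = "dI3_VC")
  }

  list(
    roots = roots,
    spike_times = spike_times,
    intracellular = intracellular,
    ground_truth = list(
      ext_onsets = ext_onsets, flex_onsets = flex_onsets,
      cycle_ends = ends, cycles = cycles,
      brief_flexor_bursts = brief,
      spike_times = spike_times, spike_phases = spike_phases,
      psc_times = psc_times, psc_phases = psc_phases,
      psc_amplitudes = psc_amp,
      params = params, spikes = spikes, pscs = pscs, fs = fs
    )
  )
}

#' Parameters for a simulated treadmill gait trial
#'
#' Describes a side-view hindlimb marker trial: a two-link thigh/shank
#' chain plus foot, driven by per-joint angle waveforms with a programmed
#' stance fraction, sampled at a video frame rate. Defaults give a
#' mouse-scale limb stepping at 2.5 steps/s filmed at 250 frames/s.
#'
#' @param femur,tibia,foot Segment lengths in cm (> 0).
#' @param step_freq Step frequency (steps/s).
#' @param stance_fraction Fraction of the cycle in stance, in (0, 1).
#' @param fps Video frame rate (frames/s, > 0). Default 250.
#' @param n_steps Number of complete step cycles.
#' @param marker_noise_sd Gaussian tracking noise on marker positions (cm).
#' @param joint_waveforms Named list of waveform amplitudes (degrees):
#'   `hip_amp` (femur sweep about vertical), `knee_mean`,
#'   `knee_stance_amp`, `knee_swing_amp`, `ankle_mean`,
#'   `ankle_stance_amp`, `ankle_swing_amp`. Setting all amplitudes to 0
#'   freezes the limb.
#' @param seed Master integer seed.
#' @return A list of class `"gait_params"`.
#' @export
gait_params <- function(femur = 1.6, tibia = 1.8, foot = 0.9,
                        step_freq = 2.5, stance_fraction = 0.6, fps = 250,
                        n_steps = 8L, marker_noise_sd = 0,
                        joint_waveforms = list(), seed = 1L) {
  for (nm in c("femur", "tibia", "foot"))
    check_scalar(get(nm), nm, lower = 0, open_lower = TRUE)
  check_scalar(step_freq, "step_freq", lower = 0, open_lower = TRUE)
  check_scalar(stance_fraction, "stance_fraction", 0, 1,
               open_lower = TRUE, open_upper = TRUE)
  check_scalar(fps, "fps", lower = 0, open_lower = TRUE)
  check_scalar(n_steps, "n_steps", lower = 1)
  check_scalar(marker_noise_sd, "marker_noise_sd", lower = 0)
  wf <- utils::modifyList(
    list(hip_amp = 18, knee_mean = 110, knee_stance_amp = 20,
         knee_swing_amp = 30, ankle_mean = 90, ankle_stance_amp = 15,
         ankle_swing_amp = 15),
    joint_waveforms)
  structure(list(femur = femur, tibia = tibia, foot = foot,
                 step_freq = step_freq, stance_fraction = stance_fraction,
                 fps = fps, n_steps = as.integer(n_steps),
                 marker_noise_sd = marker_noise_sd, joint_waveforms = wf,
                 seed = seed),
            class = "gait_params")
}

# Per-joint angle profiles as functions of normalized cycle time u in [0,1),
# with stance on [0, sf) and swing on [sf, 1). All profiles have zero slope
# at the stance/swing transitions, so the toe trajectory's extrema fall
# exactly on the programmed transitions: the hip sweep peaks at stance
# onset (toe farthest forward) and bottoms out at swing onset, while the
# knee/ankle excursions (extension through stance, flexion through swing)
# are half-raised-cosine bumps.
gait_angles_at <- function(u, sf, wf) {
  stance <- u < sf
  us <- u / sf                 # normalized stance time
  uw <- (u - sf) / (1 - sf)    # normalized swing time
  bump_s <- 0.5 * (1 - cos(2 * pi * us))
  bump_w <- 0.5 * (1 - cos(2 * pi * uw))
  hip <- ifelse(stance, wf$hip_amp * cos(pi * us),
                -wf$hip_amp * cos(pi * uw))
  knee <- ifelse(stance, wf$knee_mean + wf$knee_stance_amp * bump_s,
                 wf$knee_mean - wf$knee_swing_amp * bump_w)
  ankle <- ifelse(stance, wf$ankle_mean + wf$ankle_stance_amp * bump_s,
                  wf$ankle_mean - wf$ankle_swing_amp * bump_w)
  list(hip_sweep = hip, knee = knee, ankle = ankle)
}

rot2 <- function(theta_deg) {
  th <- theta_deg * pi / 180
  matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
}

#' Simulate a treadmill gait trial with ground truth
#'
#' Builds side-view marker trajectories (x = direction of travel, y =
#' vertical up, cm) by forward kinematics from per-joint angle waveforms:
#' the hip is fixed in the animal frame; the femur sweeps about the
#' vertical by the hip waveform; the shank hangs from the knee at the
#' programmed interior knee angle; the foot hangs from the ankle at the
#' interior ankle angle. Each step cycle starts at stance onset, where the
#' toe's horizontal position reaches its per-cycle maximum. Gaussian
#' tracking noise is added to every marker independently.
#'
#' @param params A [gait_params()] object.
#' @return A list with:
#'   \describe{
#'     \item{markers}{data frame with `frame` (0-based) and
#'       `<marker>_x`/`<marker>_y` columns for iliac_crest, hip, knee,
#'       ankle, mtp, toe; attribute `fps`.}
#'     \item{ground_truth}{list with noiseless marker positions, per-frame
#'       `hip`/`knee`/`ankle` interior joint angles (deg), the true knee
#'       coordinates, `stance_onset_frames`, `swing_onset_frames`, `steps`
#'       (a step-cycle table) and the generating parameters.}
#'   }
#' @export
generate_kinematic_trial <- function(params) {
  stopifnot(inherits(params, "gait_params"))
  p <- params
  period <- 1 / p$step_freq
  u0 <- 0.5 * p$stance_fraction     # start mid-stance so extrema are interior
  total_t <- (p$n_steps - u0 + 0.9) * period
  frames <- 0:floor(total_t * p$fps)
  tt <- frames / p$fps
  u <- (tt * p$step_freq + u0) %% 1
  ang <- gait_angles_at(u, p$stance_fraction, p$joint_waveforms)

  hip_y <- 0.92 * (p$femur + p$tibia)
  H <- cbind(0, hip_y)[rep(1, length(tt)), , drop = FALSE]
  iliac <- cbind(-0.8, hip_y + 0.4)[rep(1, length(tt)), , drop = FALSE]
  a_rad <- ang$hip_sweep * pi / 180
  K <- cbind(H[, 1] + p$femur * sin(a_rad), H[, 2] - p$femur * cos(a_rad))
  # shank: rotate the knee->hip unit vector by the interior knee angle
  # (counter-clockwise), placing the ankle posterior-inferior to the knee
  n_fr <- length(tt)
  A <- M <- Tt <- matrix(0, n_fr, 2)
  for (i in seq_len(n_fr)) {
    ukh <- (H[i, ] - K[i, ]) / p$femur
    v <- rot2(ang$knee[i]) %*% ukh
    A[i, ] <- K[i, ] + p$tibia * as.numeric(v)
    uka <- (K[i, ] - A[i, ]) / p$tibia
    w <- rot2(-ang$ankle[i]) %*% uka
    M[i, ] <- A[i, ] + p$foot * as.numeric(w)
    Tt[i, ] <- M[i, ] + 0.4 * p$foot * as.numeric(w)
  }
  if (any(sqrt(rowSums((H - A)^2)) > p$femur + p$tibia + 1e-9))
    stop("joint waveforms imply |hip - ankle| > femur + tibia")

  # ground-truth stance onsets: times where u wraps to 0
  k <- 0:(p$n_steps - 1L)
  stance_t <- (1 - u0) / p$step_freq + k * period
  swing_t <- stance_t + p$stance_fraction * period
  stance_fr <- round(stance_t * p$fps)
  swing_fr <- round(swing_t * p$fps)
  steps <- data.frame(stance_onset = stance_fr[-length(stance_fr)],
                      swing_onset = swing_fr[-length(swing_fr)],
                      end = stance_fr[-1L])
  # interior angles at hip (iliac-hip-knee), knee, ankle
  hip_int <- joint_angle(iliac, H, K)
  knee_int <- joint_angle(H, K, A)
  ankle_int <- joint_angle(K, A, M)

  clean <- data.frame(frame = frames,
                      iliac_crest_x = iliac[, 1], iliac_crest_y = iliac[, 2],
                      hip_x = H[, 1], hip_y = H[, 2],
                      knee_x = K[, 1], knee_y = K[, 2],
                      ankle_x = A[, 1], ankle_y = A[, 2],
                      mtp_x = M[, 1], mtp_y = M[, 2],
                      toe_x = Tt[, 1], toe_y = Tt[, 2])
  markers <- clean
  if (p$marker_noise_sd > 0) {
    noisy_cols <- setdiff(names(markers), "frame")
    markers[noisy_cols] <- local_seed(
      substream_seed(p$seed, 6L),
      lapply(markers[noisy_cols],
             function(col) col + stats::rnorm(length(col),
                                              sd = p$marker_noise_sd)))
  }
  attr(markers, "fps") <- p$fps
  list(markers = markers,
       ground_truth = list(
         markers = clean,
         hip = hip_int, knee = knee_int, ankle = ankle_int,
         hip_sweep = ang$hip_sweep,
         knee_xy = K,
         stance_onset_frames = stance_fr,
         swing_onset_frames = swing_fr,
         steps = steps,
         params = p))
}

#' Hill recovery curve
#'
#' Evaluates `S(T) = s_max * T^h / (k_half^h + T^h)`, the sigmoid used to
#' model the time course of the hindlimb/forelimb step ratio after spinal
#' transection: `s_max` is the maximum step ratio, `h` the Hill slope
#' (recovery rate), and `k_half` the number of days to reach half the
#' maximal step ratio.
#'
#' @param T Days post-transection (>= 0).
#' @param s_max,h,k_half Hill parameters (> 0).
#' @return Step ratio value(s).
#' @examples
#' hill_curve(20, s_max = 0.9, h = 2, k_half = 20)  # = 0.45
#' @export
hill_curve <- function(T, s_max, h, k_half) {
  stopifnot(all(T >= 0), s_max > 0, h > 0, k_half > 0)
  ifelse(T == 0, 0, s_max * T^h / (k_half^h + T^h))
}

#' Simulate a step-ratio recovery time course
#'
#' Draws noisy step-ratio observations from a Hill recovery curve:
#' `S = hill_curve(T) + N(0, noise_sd)`, clipped below at 0.
#'
#' @param s_max,h,k_half True Hill parameters (> 0).
#' @param days Numeric vector of assessment days (>= 0), non-empty.
#' @param noise_sd Gaussian noise standard deviation on the ratio.
#' @param seed Integer seed.
#' @return A data frame with columns `T` (days) and `S` (step ratio), plus
#'   attribute `truth` holding the generating parameters.
#' @export
generate_recovery_series <- function(s_max, h, k_half, days,
                                     noise_sd = 0.05, seed = 1L) {
  if (length(days) == 0L) stop("`days` must be non-empty")
  stopifnot(all(is.finite(days)), all(days >= 0), noise_sd >= 0)
  check_scalar(s_max, "s_max", lower = 0, open_lower = TRUE)
  check_scalar(h, "h", lower = 0, open_lower = TRUE)
  check_scalar(k_half, "k_half", lower = 0, open_lower = TRUE)
  S <- hill_curve(days, s_max, h, k_half)
  if (noise_sd > 0)
    S <- S + local_seed(substream_seed(seed, 7L),
                        stats::rnorm(length(days), sd = noise_sd))
  out <- data.frame(T = as.numeric(days), S = pmax(S, 0))
  attr(out, "truth") <- list(s_max = s_max, h = h, k_half = k_half,
                             noise_sd = noise_sd, seed = seed)
  out
}
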