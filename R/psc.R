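#' Build a synaptic-current detection template
#'
#' Difference-of-exponentials waveform
#' `w(t) = (1 - exp(-t/rise_tau)) * exp(-t/decay_tau)`, peak-normalized to
#' 1, used for sliding scaled-template detection of postsynaptic currents.
#' The analytic peak time is `rise_tau * log(1 + decay_tau/rise_tau)`.
#'
#' @param rise_tau,decay_tau Rise and decay time constants in ms;
#'   `decay_tau > rise_tau > 0`. Defaults 1 and 5 ms.
#' @param duration Template duration in ms (default 30). A duration below
#'   `3 * decay_tau` truncates the tail and triggers a warning.
#' @param dt Sampling interval in ms (default 0.1, i.e. 10 kHz).
#' @return An object of class `"psc_template"`: list with `waveform`
#'   (peak 1), `rise_tau`, `decay_tau`, `duration`, `dt` (all ms), and
#'   `peak_time` (ms, analytic).
#' @export
make_template <- function(rise_tau = 1, decay_tau = 5, duration = 30,
                          dt = 0.1) {
  if (!(rise_tau > 0) || !(decay_tau > rise_tau))
    stop("need decay_tau > rise_tau > 0")
  check_scalar(dt, "dt", lower = 0, open_lower = TRUE)
  if (duration < 3 * decay_tau)
    warning("`duration` < 3 * decay_tau truncates the template tail")
  t <- seq(0, duration, by = dt)
  w <- (1 - exp(-t / rise_tau)) * exp(-t / decay_tau)
  w <- w / max(w)
  structure(list(waveform = w, rise_tau = rise_tau, decay_tau = decay_tau,
                 duration = duration, dt = dt,
                 peak_time = rise_tau * log(1 + decay_tau / rise_tau)),
            class = "psc_template")
}

# resample a template to a new sampling interval (ms)
resample_template <- function(template, dt_ms) {
  if (isTRUE(all.equal(template$dt, dt_ms))) return(template)
  make_template(template$rise_tau, template$decay_tau, template$duration,
                dt_ms)
}

#' Detect postsynaptic currents by sliding scaled-template matching
#'
#' Slides the template across the trace; at every offset the template is
#' fitted to the data window by an optimal scale and additive offset
#' (least squares), and the detection criterion is the fitted scale
#' divided by the standard error of the fit. Local maxima of the
#' criterion above `criterion` are emitted as events, with a refractory
#' gap of one template rise time between events. The event amplitude is
#' the fitted scale (the template is peak-normalized, so the scale is the
#' event's peak amplitude in trace units), signed by polarity: with
#' `polarity = "outward"` positive deflections are sought (IPSCs at a
#' -40 mV holding potential); with `"inward"`, negative ones (EPSCs).
#'
#' @param trace A [trace()] of holding current (pA). If its sampling does
#'   not match the template's, the template is resampled.
#' @param template A [make_template()] object.
#' @param criterion Detection-criterion threshold (default 3.5).
#' @param polarity `"outward"` or `"inward"` (required; never inferred).
#' @return A data frame of class `"psc_events"` with columns `time` (s,
#'   event onset), `amplitude` (pA, signed), `polarity`, `score`
#'   (criterion at detection), ordered by time.
#' @export
detect_events <- function(trace, template, criterion = 3.5,
                          polarity = c("outward", "inward")) {
  stopifnot(inherits(trace, "trace"), inherits(template, "psc_template"))
  polarity <- match.arg(polarity)
  template <- resample_template(template, trace$dt * 1000)
  w <- template$waveform
  m <- length(w)
  y <- trace$samples
  n <- length(y)
  if (n < m) stop("trace shorter than template")
  if (polarity == "inward") y <- -y

  # running sums over windows of length m via cumulative sums / filtering
  sum_w <- sum(w)
  sum_w2 <- sum(w^2)
  cs_y <- cumsum(c(0, y))
  cs_y2 <- cumsum(c(0, y^2))
  n_off <- n - m + 1L
  i <- seq_len(n_off)
  Sy <- cs_y[i + m] - cs_y[i]
  Sy2 <- cs_y2[i + m] - cs_y2[i]
  # Swy[i] = sum_j w[j] * y[i + j - 1]: cross-correlation via FFT convolve
  Swy <- stats::convolve(y, w, conj = TRUE, type = "filter")
  stopifnot(length(Swy) == n_off)

  denom <- sum_w2 - sum_w^2 / m
  scale <- (Swy - sum_w * Sy / m) / denom
  offset <- (Sy - scale * sum_w) / m
  sse <- Sy2 + scale^2 * sum_w2 + m * offset^2 -
    2 * scale * Swy - 2 * offset * Sy + 2 * scale * offset * sum_w
  sse <- pmax(sse, 0)
  se <- sqrt(sse / (m - 1))
  crit <- scale / pmax(se, .Machine$double.eps)
  # roundoff guard: a fitted scale indistinguishable from zero at the
  # trace's numerical resolution is not an event, however small its SE
  scale_tol <- 1e-9 * max(abs(y), 1e-12)
  crit[scale <= scale_tol] <- 0

  # local maxima of the criterion above threshold
  cand <- which(crit >= criterion)
  cand <- cand[cand > 1L & cand < n_off]
  cand <- cand[crit[cand] >= crit[cand - 1L] & crit[cand] >= crit[cand + 1L]]
  empty <- data.frame(time = numeric(0), amplitude = numeric(0),
                      polarity = character(0), score = numeric(0),
                      stringsAsFactors = FALSE)
  class(empty) <- c("psc_events", "data.frame")
  if (length(cand) == 0L) return(empty)
  # refractory: one template rise time between events, keep higher score
  refrac <- max(1L, round(template$rise_tau / 1000 / trace$dt))
  extent <- length(w)
  cand <- cand[order(-crit[cand])]
  kept <- integer(0)
  for (j in cand) {
    if (!all(abs(kept - j) > refrac)) next
    # tail guard: a small fit landing inside the extent of an already
    # accepted, much larger event is a re-fit of that event's decay
    inside <- kept[j > kept & j < kept + extent]
    if (length(inside) > 0L &&
        scale[j] < 0.1 * max(scale[inside])) next
    kept <- c(kept, j)
  }
  kept <- sort(kept)
  sgn <- if (polarity == "outward") 1 else -1
  out <- data.frame(time = trace$start_time + (kept - 1L) * trace$dt,
                    amplitude = sgn * scale[kept],
                    polarity = polarity,
                    score = crit[kept], stringsAsFactors = FALSE)
  class(out) <- c("psc_events", "data.frame")
  out
}

#' Bin synaptic events by step-cycle phase
#'
#' Maps each event time to its double-normalized phase with
#' [phase_of_time()] and counts events in `n_bins` equal phase bins.
#' Events outside all cycles are dropped and counted. With 50 bins, 2%
#' per bin marks the level expected if events were evenly distributed
#' through the step cycle.
#'
#' @param events A `psc_events` data frame (or any data frame with a
#'   `time` column, seconds).
#' @param cycles A cycle table from [segment_cycles()].
#' @param n_bins Number of phase bins (>= 2; default 50).
#' @return An object of class `"phase_histogram"`: list with `n_bins`,
#'   `breaks`, `counts`, `percent` (sums to 100), `total` (in-cycle
#'   events) and `n_dropped`.
#' @export
bin_events_by_phase <- function(events, cycles, n_bins = 50L) {
  if (n_bins < 2L) stop("`n_bins` must be >= 2")
  phases <- phase_of_time(events$time, cycles)
  dropped <- sum(is.na(phases))
  phases <- phases[!is.na(phases)]
  if (length(phases) == 0L) stop("no events fall inside a cycle")
  bin <- pmin(floor(phases * n_bins) + 1L, n_bins)
  counts <- tabulate(bin, nbins = n_bins)
  structure(list(n_bins = as.integer(n_bins),
                 breaks = seq(0, 1, length.out = n_bins + 1L),
                 counts = counts,
                 percent = 100 * counts / sum(counts),
                 total = sum(counts),
                 n_dropped = dropped),
            class = "phase_histogram")
}

#' @export
print.phase_histogram <- function(x, ...) {
  cat(sprintf("<phase_histogram> %d events in %d bins (%d dropped); peak bin %.1f%%\n",
              x$total, x$n_bins, x$n_dropped, max(x$percent)))
  invisible(x)
}

#' Uniform per-bin expectation for a phase histogram
#'
#' Percentage of events expected in each of `n_bins` equal bins if events
#' were evenly distributed through the step cycle: `100 / n_bins` (2% for
#' 50 bins).
#'
#' @param n_bins Number of bins (>= 1).
#' @return Percent per bin.
#' @examples
#' uniform_expectation(50)
#' @export
uniform_expectation <- function(n_bins) {
  stopifnot(n_bins >= 1)
  100 / n_bins
}

#' Average normalized envelope over the phase-bin grid
#'
#' Resamples a root envelope within each locomotor cycle to the phase-bin
#' grid and averages across cycles, for overlaying the motor pattern on a
#' phase histogram. A plotting aid, not a statistic.
#'
#' @param envelope A [trace()] envelope.
#' @param cycles A cycle table.
#' @param n_bins Number of phase bins (default 50).
#' @return Numeric vector of length `n_bins`: mean envelope (normalized to
#'   its maximum) per phase bin.
#' @export
average_cycle_envelope <- function(envelope, cycles, n_bins = 50L) {
  stopifnot(inherits(envelope, "trace"), nrow(cycles) > 0L)
  tt <- trace_times(envelope)
  centers <- (seq_len(n_bins) - 0.5) / n_bins
  acc <- matrix(NA_real_, nrow(cycles), n_bins)
  for (i in seq_len(nrow(cycles))) {
    t_bin <- time_of_phase(centers, cycles$ext_onset[i],
                           cycles$flex_onset[i], cycles$end[i])
    acc[i, ] <- stats::approx(tt, envelope$samples, xout = t_bin,
                              rule = 2)$y
  }
  prof <- colMeans(acc)
  if (max(prof) > 0) prof <- prof / max(prof)
  prof
}
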