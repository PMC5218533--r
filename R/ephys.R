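#' Rectify and integrate a root recording
#'
#' Converts a raw ventral-root trace into a smooth activity envelope:
#' the trace is centred on its median (robust baseline), full-wave
#' rectified, and smoothed with a centred moving average of the given
#' window. This is the standard "rectified and integrated" transform
#' used to display and segment root bursts.
#'
#' The moving average uses shrinking windows at the trace edges so the
#' output has the same length and sampling as the input. The transform is
#' invariant to adding a constant offset to the trace.
#'
#' @param trace A [trace()] object.
#' @param window Smoothing window in seconds; must cover at least 2 samples.
#'   Default 0.05 s.
#' @return A [trace()] envelope with the same `dt` and `start_time`.
#' @examples
#' tr <- trace(sin(2 * pi * 5 * seq(0, 2, by = 1e-3)), dt = 1e-3)
#' env <- rectify_integrate(tr, window = 0.5)
#' mean(env$samples[200:1800])  # ~ 2/pi for a unit sine
#' @export
rectify_integrate <- function(trace, window = 0.05) {
  stopifnot(inherits(trace, "trace"))
  if (!is.finite(window) || window < 2 * trace$dt)
    stop("`window` must be at least 2 sampling intervals")
  x <- abs(trace$samples - stats::median(trace$samples))
  half <- max(1L, floor(window / trace$dt / 2))
  n <- length(x)
  cs <- cumsum(c(0, x))
  i <- seq_len(n)
  lo <- pmax(i - half, 1L)
  hi <- pmin(i + half, n)
  out <- (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
  trace(out, dt = trace$dt, start_time = trace$start_time,
        channel = trace$channel)
}

#' Detect bursts in an activity envelope
#'
#' Hysteresis thresholding against a robust envelope maximum: a burst is any
#' run of samples above `off_frac * m` that contains at least one sample at
#' or above `on_frac * m`, where `m` is the 95th-percentile envelope value
#' (robust to spikes and stimulus artifacts). Bursts separated by gaps
#' shorter than `min_gap` are merged, then bursts shorter than
#' `min_duration` are dropped.
#'
#' @param envelope A [trace()] envelope, e.g. from [rectify_integrate()].
#' @param on_frac,off_frac Onset / offset thresholds as fractions of the
#'   robust maximum; must satisfy `0 < off_frac < on_frac <= 1`.
#' @param min_duration Minimum burst duration in seconds.
#' @param min_gap Gaps shorter than this (s) are merged.
#' @return A data frame of class `"burst_table"` with columns `onset`,
#'   `offset` (seconds) and `channel`; zero rows if the envelope is flat.
#' @export
detect_bursts <- function(envelope, on_frac = 0.5, off_frac = 0.3,
                          min_duration = 0.05, min_gap = 0.05) {
  stopifnot(inherits(envelope, "trace"))
  if (!(off_frac > 0 && off_frac < on_frac && on_frac <= 1))
    stop("need 0 < off_frac < on_frac <= 1")
  x <- envelope$samples
  m <- stats::quantile(x, 0.95, names = FALSE)
  empty <- data.frame(onset = numeric(0), offset = numeric(0),
                      channel = character(0), stringsAsFactors = FALSE)
  class(empty) <- c("burst_table", "data.frame")
  if (!is.finite(m) || m <= 0) return(empty)
  above_off <- x >= off_frac * m
  r <- rle(above_off)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values
  starts <- starts[keep]; ends <- ends[keep]
  if (length(starts) == 0L) return(empty)
  # hysteresis: runs must reach the onset threshold
  hit <- vapply(seq_along(starts), function(i)
    max(x[starts[i]:ends[i]]) >= on_frac * m, logical(1))
  starts <- starts[hit]; ends <- ends[hit]
  if (length(starts) == 0L) return(empty)
  t0 <- envelope$start_time
  dt <- envelope$dt
  onset <- t0 + (starts - 1L) * dt
  offset <- t0 + (ends - 1L) * dt
  # merge short gaps
  if (length(onset) > 1L) {
    merged_on <- onset[1]; merged_off <- offset[1]
    for (i in 2:length(onset)) {
      if (onset[i] - merged_off[length(merged_off)] < min_gap) {
        merged_off[length(merged_off)] <- offset[i]
      } else {
        merged_on <- c(merged_on, onset[i])
        merged_off <- c(merged_off, offset[i])
      }
    }
    onset <- merged_on; offset <- merged_off
  }
  long_enough <- (offset - onset) >= min_duration
  out <- data.frame(onset = onset[long_enough], offset = offset[long_enough],
                    channel = envelope$channel, stringsAsFactors = FALSE)
  if (nrow(out) == 0L) out$channel <- character(0)
  class(out) <- c("burst_table", "data.frame")
  out
}

#' Segment locomotor cycles from alternating bursts
#'
#' A locomotor cycle runs from one extensor-burst onset to the next and must
#' contain exactly one flexor-burst onset strictly inside it; candidate
#' cycles with zero or several flexor onsets (e.g. brief extra flexor bursts
#' during the extensor phase) are discarded and counted. Cycles whose period
#' exceeds 3x, or falls below 1/3x, the median period are flagged as
#' outliers and excluded from phase analysis by default.
#'
#' @param extensor_bursts,flexor_bursts Burst tables from [detect_bursts()]
#'   for the extensor-related and flexor-related root channels, time-ordered.
#' @param drop_outliers Exclude period outliers (default `TRUE`).
#' @return A data frame of class `"cycle_table"` with columns `ext_onset`,
#'   `flex_onset`, `end` (seconds; `ext_onset < flex_onset < end`), and
#'   attributes `n_discarded` (cycles failing the one-flexor-onset rule) and
#'   `n_outliers` (period outliers removed).
#' @export
segment_cycles <- function(extensor_bursts, flexor_bursts,
                           drop_outliers = TRUE) {
  e_on <- sort(extensor_bursts$onset)
  f_on <- sort(flexor_bursts$onset)
  empty <- data.frame(ext_onset = numeric(0), flex_onset = numeric(0),
                      end = numeric(0))
  class(empty) <- c("cycle_table", "data.frame")
  attr(empty, "n_discarded") <- 0L
  attr(empty, "n_outliers") <- 0L
  if (length(e_on) < 2L) return(empty)
  ext_onset <- flex_onset <- end <- numeric(0)
  n_discarded <- 0L
  for (i in seq_len(length(e_on) - 1L)) {
    inside <- f_on[f_on > e_on[i] & f_on < e_on[i + 1L]]
    if (length(inside) == 1L) {
      ext_onset <- c(ext_onset, e_on[i])
      flex_onset <- c(flex_onset, inside)
      end <- c(end, e_on[i + 1L])
    } else {
      n_discarded <- n_discarded + 1L
    }
  }
  out <- data.frame(ext_onset = ext_onset, flex_onset = flex_onset, end = end)
  n_outliers <- 0L
  if (drop_outliers && nrow(out) > 0L) {
    period <- out$end - out$ext_onset
    med <- stats::median(period)
    ok <- period <= 3 * med & period >= med / 3
    n_outliers <- sum(!ok)
    out <- out[ok, , drop = FALSE]
    rownames(out) <- NULL
  }
  class(out) <- c("cycle_table", "data.frame")
  attr(out, "n_discarded") <- n_discarded
  attr(out, "n_outliers") <- n_outliers
  out
}

#' Double-normalized phase of time points within locomotor cycles
#'
#' Maps each time to its double-normalized phase in the enclosing locomotor
#' cycle: phase 0 marks the extensor-phase onset, the extensor phase spans
#' \[0, 0.5) and the flexor phase spans \[0.5, 1), each linearly, regardless
#' of the real durations of the two phases. Intervals are half-open, so a
#' time exactly at a cycle end belongs to the next cycle.
#'
#' @param t Numeric vector of times (s).
#' @param cycles A cycle table from [segment_cycles()] (or any data frame
#'   with `ext_onset`, `flex_onset`, `end`), ordered and non-overlapping.
#' @return Numeric vector of phases in \[0, 1); `NA` for times outside all
#'   cycles.
#' @examples
#' cyc <- data.frame(ext_onset = 0, flex_onset = 0.6, end = 1)
#' phase_of_time(c(0, 0.3, 0.6, 0.8), cyc)
#' @export
phase_of_time <- function(t, cycles) {
  if (nrow(cycles) == 0L) return(rep(NA_real_, length(t)))
  idx <- findInterval(t, cycles$ext_onset)
  phase <- rep(NA_real_, length(t))
  ok <- idx >= 1L
  ok[ok] <- t[ok] < cycles$end[idx[ok]]
  i <- idx[ok]; ti <- t[ok]
  e <- cycles$ext_onset[i]; f <- cycles$flex_onset[i]; en <- cycles$end[i]
  p <- ifelse(ti < f,
              0.5 * (ti - e) / (f - e),
              0.5 + 0.5 * (ti - f) / (en - f))
  phase[ok] <- p
  phase
}
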