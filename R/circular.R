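#' Circular statistics of spike phases
#'
#' Computes the mean phase and angular concentration of a sample of
#' phases expressed as cycle fractions. Each phase `p` is mapped to the
#' angle `2*pi*p`; the mean phase Phi is the angle of the vector mean of
#' the unit phase vectors, and the angular concentration `r` is its
#' resultant length, i.e. `sqrt(mean(cos)^2 + mean(sin)^2)`. A neuron
#' firing once per cycle at precisely the same phase gives `r = 1`;
#' phases dispersed uniformly across the cycle give `r = 0`. The Rayleigh
#' p-value for non-uniformity is attached (see [rayleigh_p()]).
#'
#' @param phases Numeric vector of phases in \[0, 1); `n >= 1`.
#' @return An object of class `"circ_stat"`: list with `phi` (mean phase in
#'   \[0,1)), `r` (concentration in \[0,1\]), `n`, and `p` (Rayleigh).
#' @examples
#' circular_stats(rep(0.3, 50))       # r = 1, phi = 0.3
#' circular_stats((0:49) / 50)$r      # ~ 0
#' @export
circular_stats <- function(phases) {
  phases <- as.numeric(phases)
  if (length(phases) == 0L) stop("empty phase sample")
  if (any(!is.finite(phases)) || any(phases < 0) || any(phases >= 1))
    stop("phases must lie in [0, 1)")
  theta <- 2 * pi * phases
  mc <- mean(cos(theta))
  ms <- mean(sin(theta))
  r <- sqrt(mc^2 + ms^2)
  r <- min(r, 1)
  phi <- atan2(ms, mc) / (2 * pi)
  phi <- phi %% 1
  n <- length(phases)
  structure(list(phi = phi, r = r, n = n, p = rayleigh_p(n, r)),
            class = "circ_stat")
}

#' @export
print.circ_stat <- function(x, ...) {
  cat(sprintf("<circ_stat> phi=%.4f r=%.4f n=%d p=%.4g\n",
              x$phi, x$r, x$n, x$p))
  invisible(x)
}

#' Rayleigh test p-value for circular non-uniformity
#'
#' Large-sample Rayleigh approximation `p = exp(-n * r^2)`, clipped to
#' (0, 1]. A finite-sample corrected series is available with
#' `corrected = TRUE`.
#'
#' @param n Sample size (>= 1).
#' @param r Angular concentration in \[0, 1\].
#' @param corrected Use the higher-order series correction.
#' @return p-value in (0, 1].
#' @examples
#' rayleigh_p(50, 0.2448)  # ~ 0.05
#' @export
rayleigh_p <- function(n, r, corrected = FALSE) {
  stopifnot(n >= 1, r >= 0, r <= 1 + 1e-12)
  z <- n * r^2
  p <- exp(-z)
  if (corrected) {
    p <- p * (1 + (2 * z - z^2) / (4 * n) -
                (24 * z - 132 * z^2 + 76 * z^3 - 9 * z^4) / (288 * n^2))
  }
  min(max(p, .Machine$double.xmin), 1)
}

#' Critical angular concentration for the Rayleigh test
#'
#' Inverts the large-sample Rayleigh p-value: the smallest concentration
#' significant at level `alpha` with `n` phases is
#' `r* = sqrt(-log(alpha) / n)`. For 50 spikes at alpha = 0.05 this is
#' 0.2448, the value (rounded to 0.24) conventionally drawn as the inner
#' significance circle on spike-phase polar plots. The threshold is
#' monotone decreasing in `n` (quadrupling `n` halves it).
#'
#' @param n Number of phases (>= 1).
#' @param alpha Significance level in (0, 1).
#' @return Critical concentration threshold.
#' @examples
#' critical_r(50, 0.05)
#' @export
critical_r <- function(n, alpha = 0.05) {
  if (!(alpha > 0 && alpha < 1)) stop("`alpha` must be in (0, 1)")
  stopifnot(n >= 1)
  sqrt(-log(alpha) / n)
}

#' Rounded display threshold for 50 spikes
#'
#' The two-decimal value of `critical_r(50, 0.05)` used for display on
#' polar plots. Classification always uses the full-precision threshold.
#' @export
r_threshold_50 <- round(critical_r(50, 0.05), 2)

#' Classify a phase as extensor or flexor
#'
#' Under double normalization the extensor phase spans \[0, 0.5) and the
#' flexor phase \[0.5, 1); intervals are half-open, so a phase of exactly
#' 0.5 is flexor.
#'
#' @param phi Phase(s) in \[0, 1).
#' @return Character vector, `"extensor"` or `"flexor"`.
#' @export
phase_class <- function(phi) {
  stopifnot(all(phi >= 0 & phi < 1))
  ifelse(phi < 0.5, "extensor", "flexor")
}

#' Classify rhythmicity of a cell from its spike phases
#'
#' Applies the subsampled Rayleigh rule used for spike-phase polar plots:
#' if more than `n_sub` spikes were recorded, `n_sub` phases are drawn at
#' random without replacement (seeded, reproducible); otherwise all phases
#' are used and the critical concentration is recomputed for the actual
#' sample size (so rhythmicity can still be demonstrated for cells with
#' fewer spikes). The cell is called rhythmic when the angular
#' concentration of the (sub)sample exceeds `critical_r(n_used, alpha)`
#' at full precision, and is assigned to the extensor or flexor phase
#' class from its mean phase.
#'
#' @param phases Numeric vector of spike phases in \[0, 1).
#' @param n_sub Subsample size (default 50).
#' @param alpha Significance level (default 0.05).
#' @param seed Integer seed for the subsampling draw (mandatory).
#' @param cell_id Optional label carried into the result.
#' @return An object of class `"rhythmicity"`: list with `stat`
#'   (a [circular_stats()] result on the subsample), `n_total`,
#'   `n_subsampled`, `threshold`, `rhythmic` (logical), `phase_class`,
#'   `seed`, `cell_id`.
#' @export
classify_rhythmicity <- function(phases, n_sub = 50L, alpha = 0.05, seed,
                                 cell_id = NA_character_) {
  if (length(phases) == 0L) stop("empty phase sample")
  if (missing(seed)) stop("`seed` is required for reproducible subsampling")
  n <- length(phases)
  if (n > n_sub) {
    sub <- local_seed(seed, sample(phases, n_sub, replace = FALSE))
  } else {
    sub <- phases
  }
  st <- circular_stats(sub)
  thr <- critical_r(st$n, alpha)
  structure(list(
    stat = st,
    n_total = n,
    n_subsampled = st$n,
    threshold = thr,
    rhythmic = st$r > thr,
    phase_class = phase_class(st$phi),
    seed = seed,
    cell_id = cell_id
  ), class = "rhythmicity")
}

#' @export
print.rhythmicity <- function(x, ...) {
  cat(sprintf(
    "<rhythmicity> %s: %s (r=%.3f vs r*=%.3f, n=%d/%d, phi=%.3f, %s)\n",
    ifelse(is.na(x$cell_id), "cell", x$cell_id),
    if (x$rhythmic) "rhythmic" else "not rhythmic",
    x$stat$r, x$threshold, x$n_subsampled, x$n_total,
    x$stat$phi, x$phase_class))
  invisible(x)
}

#' Left-right (or any reference-target) phase coordination
#'
#' Maps each target burst onset to its fraction of the enclosing reference
#' cycle, where a reference cycle runs from one reference onset to the next
#' (plain single-segment normalization, not double normalization), and
#' summarizes the fractions with [circular_stats()]. Strict left-right
#' alternation gives a mean phase near 0.5.
#'
#' @param reference_onsets Numeric vector of reference burst onsets (s),
#'   at least 2.
#' @param target_onsets Numeric vector of target burst onsets (s).
#' @return A `"circ_stat"` object of the target-onset phases.
#' @export
interlimb_phase <- function(reference_onsets, target_onsets) {
  ref <- sort(reference_onsets)
  if (length(ref) < 2L) stop("need at least 2 reference onsets")
  idx <- findInterval(target_onsets, ref)
  ok <- idx >= 1L & idx < length(ref)
  if (!any(ok)) stop("no target onset falls inside a reference cycle")
  i <- idx[ok]
  frac <- (target_onsets[ok] - ref[i]) / (ref[i + 1L] - ref[i])
  circular_stats(frac %% 1)
}
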