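as_xy_matrix <- function(p) {
  if (is.matrix(p)) {
    stopifnot(ncol(p) == 2L)
    p
  } else {
    stopifnot(length(p) == 2L)
    matrix(as.numeric(p), 1L, 2L)
  }
}

#' Interior joint angle at a vertex
#'
#' Interior angle (degrees) at `p_vertex` between the segments running to
#' `p_prox` and `p_dist`, computed from the two limb vectors. Collinear
#' points give 180 degrees. All arguments may be single points (length-2
#' vectors) or n x 2 matrices for per-frame computation.
#'
#' @param p_prox,p_vertex,p_dist 2-D points (x, y) or n x 2 matrices.
#' @return Angle(s) in degrees, in (0, 360); here always in (0, 180\].
#' @examples
#' joint_angle(c(0, 1), c(0, 0), c(1, 0))  # 90
#' @export
joint_angle <- function(p_prox, p_vertex, p_dist) {
  a <- as_xy_matrix(p_prox); v <- as_xy_matrix(p_vertex)
  b <- as_xy_matrix(p_dist)
  n <- max(nrow(a), nrow(v), nrow(b))
  expand <- function(m) if (nrow(m) == n) m else m[rep(1L, n), , drop = FALSE]
  a <- expand(a); v <- expand(v); b <- expand(b)
  u1 <- a - v; u2 <- b - v
  n1 <- sqrt(rowSums(u1^2)); n2 <- sqrt(rowSums(u2^2))
  if (any(n1 == 0) || any(n2 == 0))
    stop("vertex coincides with a neighbouring point")
  cosang <- pmin(pmax(rowSums(u1 * u2) / (n1 * n2), -1), 1)
  acos(cosang) * 180 / pi
}

#' Reconstruct the knee from hip and ankle markers
#'
#' Skin movement over the knee makes a glued knee marker unreliable; the
#' true knee position is instead reconstructed geometrically as the
#' intersection of the circle of radius `femur_len` around the hip with
#' the circle of radius `tibia_len` around the ankle. Two intersections
#' exist in general; `branch` selects the solution on the requested side
#' of the hip-to-ankle chord (`"anterior"` = greater x, the direction of
#' travel, the usual configuration for a side-view rodent hindlimb).
#'
#' @param hip,ankle 2-D points (cm) or n x 2 matrices of per-frame
#'   positions.
#' @param femur_len,tibia_len Segment lengths in cm (> 0).
#' @param branch `"anterior"` (default) or `"posterior"`.
#' @return Knee position(s): a length-2 vector for single points, or an
#'   n x 2 matrix. The result satisfies both distance constraints to
#'   numerical precision.
#' @examples
#' reconstruct_knee(c(0, 0), c(0, -2), sqrt(2), sqrt(2))  # (1, -1)
#' @export
reconstruct_knee <- function(hip, ankle, femur_len, tibia_len,
                             branch = c("anterior", "posterior")) {
  branch <- match.arg(branch)
  check_scalar(femur_len, "femur_len", lower = 0, open_lower = TRUE)
  check_scalar(tibia_len, "tibia_len", lower = 0, open_lower = TRUE)
  single <- !is.matrix(hip) && !is.matrix(ankle)
  H <- as_xy_matrix(hip); A <- as_xy_matrix(ankle)
  n <- max(nrow(H), nrow(A))
  if (nrow(H) != n) H <- H[rep(1L, n), , drop = FALSE]
  if (nrow(A) != n) A <- A[rep(1L, n), , drop = FALSE]
  d <- sqrt(rowSums((A - H)^2))
  bad <- d > femur_len + tibia_len + 1e-9 |
    d < abs(femur_len - tibia_len) - 1e-9 | d == 0
  if (any(bad))
    stop(sprintf(
      "knee reconstruction impossible at frame(s) %s: |hip-ankle| outside [|femur-tibia|, femur+tibia]",
      paste(utils::head(which(bad), 5L), collapse = ", ")))
  d <- pmin(d, femur_len + tibia_len)  # clamp tangent roundoff
  # foot of the radical axis along the chord, and half-chord height
  a <- (femur_len^2 - tibia_len^2 + d^2) / (2 * d)
  hh <- sqrt(pmax(femur_len^2 - a^2, 0))
  ex <- (A - H) / d
  base <- H + a * ex
  perp <- cbind(-ex[, 2], ex[, 1])
  k1 <- base + hh * perp
  k2 <- base - hh * perp
  pick_first <- (k1[, 1] > k2[, 1]) |
    (k1[, 1] == k2[, 1] & k1[, 2] >= k2[, 2])
  if (branch == "posterior") pick_first <- !pick_first
  K <- ifelse(cbind(pick_first, pick_first), k1, k2)
  K <- matrix(K, ncol = 2L)
  colnames(K) <- c("x", "y")
  if (single) K[1L, ] else K
}

#' Detect stance onsets from the toe trajectory
#'
#' Stance onsets are the local maxima of the toe marker's horizontal
#' position (in the animal frame the toe is farthest forward at
#' touchdown); swing onsets are the minima between consecutive stance
#' onsets. Maxima must rise at least `min_prominence` above the higher of
#' the two flanking minima and be separated by at least `min_separation`.
#'
#' @param toe_x Per-frame horizontal toe position (cm), >= 3 frames.
#' @param fps Frame rate (frames/s).
#' @param min_prominence Minimum peak prominence (cm). Default: 10% of the
#'   trace's peak-to-peak amplitude.
#' @param min_separation Minimum separation between stance onsets (s).
#'   Default 0.1 s.
#' @return A list with `stance_onsets` and `swing_onsets`, 0-based frame
#'   indices. A flat or monotone trace yields empty vectors.
#' @export
detect_stance_onsets <- function(toe_x, fps,
                                 min_prominence = 0.1 * diff(range(toe_x)),
                                 min_separation = 0.1) {
  if (length(toe_x) < 3L) stop("need at least 3 frames")
  check_scalar(fps, "fps", lower = 0, open_lower = TRUE)
  x <- as.numeric(toe_x)
  n <- length(x)
  dx <- diff(x)
  s <- sign(dx)
  # carry flat runs so plateau peaks are found once
  for (i in seq_along(s)) if (s[i] == 0 && i > 1L) s[i] <- s[i - 1L]
  peaks <- which(diff(s) < 0) + 1L
  if (length(peaks) == 0L)
    return(list(stance_onsets = integer(0), swing_onsets = integer(0)))
  # prominence: height above the higher flanking minimum (trace ends count
  # as minima)
  prom <- vapply(peaks, function(p) {
    left <- min(x[1:p]); right <- min(x[p:n])
    x[p] - max(left, right)
  }, numeric(1))
  peaks <- peaks[prom >= min_prominence]
  # enforce separation, keeping the higher peak
  if (length(peaks) > 1L) {
    min_fr <- min_separation * fps
    ord <- peaks[order(-x[peaks])]
    kept <- integer(0)
    for (p in ord) if (all(abs(kept - p) >= min_fr)) kept <- c(kept, p)
    peaks <- sort(kept)
  }
  swing <- integer(0)
  if (length(peaks) > 1L) {
    swing <- vapply(seq_len(length(peaks) - 1L), function(i) {
      seg <- peaks[i]:peaks[i + 1L]
      seg[which.min(x[seg])]
    }, integer(1))
  }
  list(stance_onsets = as.integer(peaks - 1L),
       swing_onsets = as.integer(swing - 1L))
}

#' Build a step-cycle table from stance and swing onsets
#'
#' @param stance_onsets,swing_onsets 0-based frame indices from
#'   [detect_stance_onsets()].
#' @return Data frame with `stance_onset`, `swing_onset`, `end` frames,
#'   one row per complete cycle (`stance_onset < swing_onset < end`).
#' @export
step_cycles <- function(stance_onsets, swing_onsets) {
  st <- sort(stance_onsets)
  out <- data.frame(stance_onset = integer(0), swing_onset = integer(0),
                    end = integer(0))
  if (length(st) < 2L) return(out)
  for (i in seq_len(length(st) - 1L)) {
    sw <- swing_onsets[swing_onsets > st[i] & swing_onsets < st[i + 1L]]
    if (length(sw) == 1L)
      out <- rbind(out, data.frame(stance_onset = st[i], swing_onset = sw,
                                   end = st[i + 1L]))
  }
  out
}

#' Normalize a step cycle to a fixed number of points
#'
#' Resamples the stance and swing segments of one step cycle each to
#' `points_per_phase` samples by linear interpolation and concatenates
#' them (stance first, matching cycle order), giving a fixed-length
#' profile (100 points by default) so steps of different durations and
#' duty factors can be averaged with stance/swing landmarks aligned.
#' Phase endpoints are preserved exactly.
#'
#' @param signal Per-frame numeric signal (e.g. one joint-angle series).
#' @param step One row of a step-cycle table: list or data frame row with
#'   `stance_onset`, `swing_onset`, `end` (0-based frames within range).
#' @param points_per_phase Samples per phase (default 50; total output
#'   length `2 * points_per_phase`).
#' @return Numeric vector of length `2 * points_per_phase`.
#' @export
normalize_step <- function(signal, step, points_per_phase = 50L) {
  stopifnot(points_per_phase >= 2L)
  s0 <- step$stance_onset; s1 <- step$swing_onset; s2 <- step$end
  if (!(s0 < s1 && s1 < s2)) stop("degenerate step: need stance < swing < end")
  if (s0 < 0 || s2 > length(signal) - 1L) stop("step outside signal range")
  resamp <- function(from, to) {
    idx <- seq(from, to, length.out = points_per_phase)
    stats::approx(x = seq(from, to), y = signal[(from:to) + 1L],
                  xout = idx)$y
  }
  c(resamp(s0, s1), resamp(s1, s2))
}

#' Summarize gait from step cycles, foot contacts, and paw positions
#'
#' Computes per-step stance duration, swing duration, cycle period and
#' duty factor; the distribution of time spent with 0-4 feet in ground
#' contact; and front/rear foot spacing.
#'
#' @param steps Step-cycle table (frames; see [step_cycles()]).
#' @param fps Frame rate (frames/s).
#' @param contacts Optional per-frame logical/0-1 matrix or data frame
#'   with one column per foot, columns named `lf`, `rf`, `lh`, `rh`
#'   (left/right fore/hind).
#' @param paw_x Optional per-frame data frame of paw lateral positions
#'   (cm) with the same column names; spacing is the mean |left - right|
#'   distance over frames where both feet are in contact.
#' @return A list of class `"gait_summary"` with `per_step` (data frame:
#'   `stance_s`, `swing_s`, `period_s`, `duty_factor`),
#'   `mean_duty_factor`, `contact_proportions` (named vector for 0-4 feet,
#'   sums to 1; `NULL` without contacts), `front_spacing` and
#'   `rear_spacing` (cm; `NA` without positions).
#' @export
gait_summary <- function(steps, fps, contacts = NULL, paw_x = NULL) {
  if (nrow(steps) < 1L) stop("need at least one step")
  check_scalar(fps, "fps", lower = 0, open_lower = TRUE)
  per_step <- data.frame(
    stance_s = (steps$swing_onset - steps$stance_onset) / fps,
    swing_s = (steps$end - steps$swing_onset) / fps,
    period_s = (steps$end - steps$stance_onset) / fps)
  per_step$duty_factor <- per_step$stance_s / per_step$period_s
  contact_proportions <- NULL
  front_spacing <- rear_spacing <- NA_real_
  if (!is.null(contacts) && NROW(contacts) > 0L) {
    cm <- as.matrix(contacts) > 0
    n_down <- rowSums(cm)
    contact_proportions <- as.numeric(tabulate(n_down + 1L, 5L)) /
      length(n_down)
    names(contact_proportions) <- as.character(0:4)
    if (!is.null(paw_x)) {
      spacing <- function(l, r) {
        both <- cm[, l] & cm[, r]
        if (!any(both)) return(NA_real_)
        mean(abs(paw_x[[l]][both] - paw_x[[r]][both]))
      }
      front_spacing <- spacing("lf", "rf")
      rear_spacing <- spacing("lh", "rh")
    }
  }
  structure(list(per_step = per_step,
                 mean_duty_factor = mean(per_step$duty_factor),
                 contact_proportions = contact_proportions,
                 front_spacing = front_spacing,
                 rear_spacing = rear_spacing),
            class = "gait_summary")
}

#' @export
print.gait_summary <- function(x, ...) {
  cat(sprintf("<gait_summary> %d steps; mean period %.3f s; mean duty factor %.3f\n",
              nrow(x$per_step), mean(x$per_step$period_s),
              x$mean_duty_factor))
  invisible(x)
}

#' Compare regression slopes between two groups (ANCOVA on slopes)
#'
#' Fits per-group least-squares slopes of `y` on `x` (e.g. stance duration
#' against cycle period) and tests slope equality via the group-by-x
#' interaction term of a pooled linear model.
#'
#' @param x1,y1 Numeric vectors for group 1 (>= 3 points, `var(x1) > 0`).
#' @param x2,y2 Numeric vectors for group 2.
#' @return A list with `slope1`, `slope2`, `p` (interaction p-value) and
#'   `model` (the pooled `lm` fit).
#' @export
slope_comparison <- function(x1, y1, x2, y2) {
  if (length(x1) < 3L || length(x2) < 3L)
    stop("need at least 3 points per group")
  if (stats::var(x1) == 0 || stats::var(x2) == 0)
    stop("x must vary within each group")
  dat <- data.frame(x = c(x1, x2), y = c(y1, y2),
                    g = factor(rep(c("g1", "g2"), c(length(x1), length(x2)))))
  fit <- stats::lm(y ~ x * g, data = dat)
  co <- summary(fit)$coefficients
  if (qr(fit)$rank < 4L) stop("singular design")
  list(slope1 = unname(stats::coef(fit)["x"]),
       slope2 = unname(stats::coef(fit)["x"] + stats::coef(fit)["x:gg2"]),
       p = unname(co["x:gg2", "Pr(>|t|)"]),
       model = fit)
}
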