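#' Count forward toe excursions (steps)
#'
#' A hindlimb step is counted for every forward excursion of the toe: a
#' rise of the horizontal toe position by at least `min_excursion` above
#' the preceding local minimum. A hysteresis counter is used, so the
#' trace must fall back by the same margin before a new excursion can be
#' counted; this rejects tracking jitter while still counting minimal
#' forward movements. Counting is invariant to adding a constant to the
#' trace; a flat trace counts 0 steps.
#'
#' @param toe_x Per-frame horizontal toe position (cm), >= 2 frames.
#' @param min_excursion Minimum forward excursion to count as a step (cm).
#'   Default 0.1.
#' @return Integer step count.
#' @export
count_steps <- function(toe_x, min_excursion = 0.1) {
  x <- as.numeric(toe_x)
  if (length(x) < 2L) stop("need at least 2 frames")
  check_scalar(min_excursion, "min_excursion", lower = 0, open_lower = TRUE)
  count <- 0L
  rising <- FALSE
  ref <- x[1]
  for (v in x[-1]) {
    if (!rising) {
      if (v < ref) ref <- v
      if (v >= ref + min_excursion) {
        count <- count + 1L
        rising <- TRUE
        ref <- v
      }
    } else {
      if (v > ref) ref <- v
      if (v <= ref - min_excursion) {
        rising <- FALSE
        ref <- v
      }
    }
  }
  count
}

#' Hindlimb/forelimb step ratio
#'
#' `((left_hind + right_hind) / 2) / fore`: the number of hindlimb steps,
#' averaged between the two hindlimbs, divided by the number of forelimb
#' steps. Used as a recovery index after spinal transection (1 = every
#' forelimb step is matched by a hindlimb step).
#'
#' @param left_hind,right_hind Hindlimb step counts (>= 0).
#' @param fore Forelimb step count (> 0).
#' @return The step ratio (dimensionless, >= 0).
#' @examples
#' step_ratio(10, 12, 40)  # 0.275
#' @export
step_ratio <- function(left_hind, right_hind, fore) {
  stopifnot(left_hind >= 0, right_hind >= 0)
  if (fore <= 0) stop("`fore` must be positive")
  ((left_hind + right_hind) / 2) / fore
}

#' Fit a Hill recovery curve to step-ratio data
#'
#' Bounded nonlinear least-squares fit of
#' `S = S_max * T^h / (k_half^h + T^h)` to step-ratio recovery points.
#' Initialization is scale-aware: `S_max = max(S)`, `h = 1`,
#' `k_half = median(T)`; bounds are `S_max` in (0, 2], `h` in (0, 10],
#' `k_half` in (0, 10 * max(T)]. Fitting uses bounded
#' Levenberg-Marquardt.
#'
#' @param points Data frame with columns `T` (days, >= 0) and `S` (step
#'   ratio, >= 0); at least 4 points with at least 2 distinct `T > 0`.
#' @param init Optional named vector/list overriding starting values
#'   (`s_max`, `h`, `k_half`).
#' @param lower,upper Optional bound overrides, same names.
#' @return An object of class `"hill_fit"`: list with `s_max`, `h`,
#'   `k_half`, `r2`, `fitted`, `residuals`, `converged`, and the
#'   underlying `fit` object. On non-convergence an error is thrown
#'   carrying the best iterate in its `condition$best` field.
#' @examples
#' pts <- generate_recovery_series(0.9, 2, 20, seq(2, 60, by = 3),
#'                                 noise_sd = 0)
#' fit_hill(pts)
#' @export
fit_hill <- function(points, init = NULL, lower = NULL, upper = NULL) {
  stopifnot(all(c("T", "S") %in% names(points)))
  Td <- as.numeric(points$T); S <- as.numeric(points$S)
  if (length(Td) < 4L) stop("need at least 4 points")
  if (length(unique(Td[Td > 0])) < 2L)
    stop("need at least 2 distinct T > 0")
  stopifnot(all(Td >= 0), all(S >= 0))
  start <- list(s_max = max(S), h = 1, k_half = stats::median(Td))
  if (!is.null(init)) start <- utils::modifyList(start, as.list(init))
  lo <- c(s_max = 1e-8, h = 1e-8, k_half = 1e-8)
  hi <- c(s_max = 2, h = 10, k_half = 10 * max(Td))
  if (!is.null(lower)) lo[names(lower)] <- unlist(lower)
  if (!is.null(upper)) hi[names(upper)] <- unlist(upper)
  start$s_max <- min(max(start$s_max, lo["s_max"]), hi["s_max"])
  dat <- data.frame(T = Td, S = S)
  fit <- tryCatch(
    minpack.lm::nlsLM(
      S ~ hill_curve(T, s_max, h, k_half),
      data = dat, start = start, lower = lo, upper = hi,
      control = minpack.lm::nls.lm.control(maxiter = 500)),
    error = function(e) e)
  if (inherits(fit, "error")) {
    cond <- simpleError(paste0("Hill fit failed: ", conditionMessage(fit)))
    cond$best <- start
    stop(cond)
  }
  est <- stats::coef(fit)
  fitted <- hill_curve(Td, est["s_max"], est["h"], est["k_half"])
  ss_res <- sum((S - fitted)^2)
  ss_tot <- sum((S - mean(S))^2)
  structure(list(
    s_max = unname(est["s_max"]), h = unname(est["h"]),
    k_half = unname(est["k_half"]),
    r2 = if (ss_tot > 0) 1 - ss_res / ss_tot else NA_real_,
    fitted = fitted, residuals = S - fitted,
    converged = fit$convInfo$isConv, fit = fit), class = "hill_fit")
}

#' @export
print.hill_fit <- function(x, ...) {
  cat(sprintf(
    "<hill_fit> S_max=%.4g h=%.4g k_half=%.4g days (R2=%.3f)\n",
    x$s_max, x$h, x$k_half, x$r2))
  invisible(x)
}

#' Two-sided Fisher's exact test on a 2x2 table
#'
#' Exact test of association in a 2x2 contingency table (e.g. successful
#' vs failed preparations in two genotypes). The two-sided p-value is the
#' probability-mass definition: the sum of hypergeometric probabilities of
#' all tables with the same margins whose probability does not exceed that
#' of the observed table.
#'
#' @param a,b,c,d Cell counts (row-wise: `a`, `b` / `c`, `d`), all >= 0,
#'   table non-empty.
#' @return Two-sided p-value.
#' @examples
#' fisher_exact_2x2(13, 1, 6, 6)  # ~ 0.026
#' @export
fisher_exact_2x2 <- function(a, b, c, d) {
  counts <- c(a, b, c, d)
  if (any(counts < 0) || any(counts != round(counts)))
    stop("counts must be non-negative integers")
  if (sum(counts) == 0L) stop("empty table")
  stats::fisher.test(matrix(counts, 2, 2, byrow = TRUE))$p.value
}
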