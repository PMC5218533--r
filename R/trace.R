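#' Uniformly sampled signal trace
#'
#' Lightweight container for a uniformly sampled time series (a ventral-root
#' voltage recording, an intracellular current trace, an envelope...).
#'
#' @param samples Numeric vector of signal values (V or pA). Must be finite.
#' @param dt Sampling interval in seconds (> 0).
#' @param start_time Time of the first sample in seconds.
#' @param channel Channel label, e.g. `"L2"` or `"iL5"`.
#'
#' @return An object of class `"trace"`: a list with elements `samples`,
#'   `dt`, `start_time` and `channel`.
#' @examples
#' tr <- trace(sin(seq(0, 2 * pi, length.out = 100)), dt = 1e-3)
#' trace_times(tr)[1:3]
#' @export
trace <- function(samples, dt, start_time = 0, channel = "") {
  samples <- as.numeric(samples)
  if (!is.numeric(dt) || length(dt) != 1L || !is.finite(dt) || dt <= 0)
    stop("`dt` must be a single positive number")
  if (any(!is.finite(samples)))
    stop("`samples` must be finite")
  structure(
    list(samples = samples, dt = dt, start_time = as.numeric(start_time),
         channel = as.character(channel)),
    class = "trace"
  )
}

#' @return `trace_times()` returns the vector of sample times in seconds.
#' @rdname trace
#' @export
trace_times <- function(x) {
  stopifnot(inherits(x, "trace"))
  x$start_time + (seq_along(x$samples) - 1L) * x$dt
}

#' @export
print.trace <- function(x, ...) {
  cat(sprintf("<trace> channel=%s n=%d dt=%gs span=[%.6g, %.6g]s\n",
              if (nzchar(x$channel)) x$channel else "?",
              length(x$samples), x$dt, x$start_time,
              x$start_time + (length(x$samples) - 1L) * x$dt))
  invisible(x)
}

#' @export
length.trace <- function(x) length(x$samples)
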