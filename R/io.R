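#' Read uniformly sampled traces from CSV
#'
#' Reads a comma-separated file with a mandatory header consisting of a
#' `time_s` column plus one column per channel, as written by
#' [write_trace_csv()]. Sampling must be uniform: the sampling interval is
#' inferred from the median time difference and validated against every
#' row (maximum jitter 1% of dt).
#'
#' @param path Path to the CSV file.
#' @return A named list of [trace()] objects, one per channel column.
#' @export
read_trace_csv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path, check.names = FALSE)
  if (!"time_s" %in% names(df))
    stop("format error: header must contain a `time_s` column")
  if (ncol(df) < 2L) stop("format error: no channel columns")
  tt <- df$time_s
  if (length(tt) < 2L) stop("format error: need at least 2 rows")
  dts <- diff(tt)
  dt <- stats::median(dts)
  jitter <- abs(dts - dt)
  if (any(jitter > 0.01 * dt)) {
    row <- which.max(jitter) + 1L
    stop(sprintf("format error: non-uniform sampling at row %d (dt %.3g vs %.3g)",
                 row, dts[row - 1L], dt))
  }
  chans <- setdiff(names(df), "time_s")
  out <- lapply(chans, function(ch)
    trace(df[[ch]], dt = dt, start_time = tt[1], channel = ch))
  names(out) <- chans
  out
}

#' Write traces to CSV
#'
#' Writes one or more traces sharing a time base to a comma-separated
#' file with a `time_s` column and one column per channel. UTF-8,
#' '.' decimal, header mandatory.
#'
#' @param traces A [trace()] or named list of traces with identical `dt`,
#'   `start_time`, and length.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_trace_csv <- function(traces, path) {
  if (inherits(traces, "trace")) {
    nm <- if (nzchar(traces$channel)) traces$channel else "channel_1"
    traces <- stats::setNames(list(traces), nm)
  }
  stopifnot(length(traces) >= 1L)
  ref <- traces[[1L]]
  for (tr in traces) {
    stopifnot(inherits(tr, "trace"),
              isTRUE(all.equal(tr$dt, ref$dt)),
              length(tr$samples) == length(ref$samples))
  }
  df <- data.frame(time_s = trace_times(ref))
  for (nm in names(traces)) df[[nm]] <- traces[[nm]]$samples
  utils::write.csv(df, path, row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Read a marker table from CSV
#'
#' Expects a header row with a `frame` column plus `<marker>_x` /
#' `<marker>_y` coordinate pairs (cm), e.g. `toe_x,toe_y`.
#'
#' @param path Path to the CSV file.
#' @param fps Frame rate (frames/s) attached to the result.
#' @return The marker data frame with attribute `fps`.
#' @export
read_markers_csv <- function(path, fps) {
  if (!file.exists(path)) stop("file not found: ", path)
  check_scalar(fps, "fps", lower = 0, open_lower = TRUE)
  df <- utils::read.csv(path, check.names = FALSE)
  if (!"frame" %in% names(df))
    stop("format error: header must contain a `frame` column")
  xy <- grepl("_(x|y)$", setdiff(names(df), "frame"))
  if (!all(xy))
    stop("format error: marker columns must be named <marker>_x / <marker>_y")
  attr(df, "fps") <- fps
  df
}

#' Pipeline configuration
#'
#' Assembles the full parameter set of the fictive-locomotion analysis
#' pipeline, with defaults for every stage. The configuration round-trips
#' losslessly through JSON ([write_config()] / [read_config()]).
#'
#' @param fs Trace sampling rate (Hz).
#' @param flexor_channel,extensor_channel Channel-role map: names of the
#'   flexor-related (L1-L3) and extensor-related (L4-L6) root channels in
#'   the input trace file. Roles are configuration, never inferred.
#' @param envelope_window Rectify-integrate smoothing window (s).
#' @param on_frac,off_frac,min_burst_duration,min_burst_gap Burst-detector
#'   parameters (see [detect_bursts()]).
#' @param n_sub,alpha Rhythmicity-rule parameters (see
#'   [classify_rhythmicity()]).
#' @param n_bins Phase-histogram bin count.
#' @param psc_criterion,psc_polarity PSC detector parameters.
#' @param femur,tibia Segment lengths (cm) for knee reconstruction.
#' @param knee_branch Knee-reconstruction branch.
#' @param seed Master seed for all seeded steps.
#' @return A list of class `"pipeline_config"`.
#' @export
pipeline_config <- function(fs = 10000,
                            flexor_channel = "flexor_root",
                            extensor_channel = "extensor_root",
                            envelope_window = 0.05,
                            on_frac = 0.5, off_frac = 0.3,
                            min_burst_duration = 0.05, min_burst_gap = 0.05,
                            n_sub = 50L, alpha = 0.05, n_bins = 50L,
                            psc_criterion = 3.5, psc_polarity = "outward",
                            femur = 1.6, tibia = 1.8,
                            knee_branch = "anterior", seed = 1L) {
  cfg <- list(fs = as.numeric(fs),
              flexor_channel = as.character(flexor_channel),
              extensor_channel = as.character(extensor_channel),
              envelope_window = as.numeric(envelope_window),
              on_frac = as.numeric(on_frac),
              off_frac = as.numeric(off_frac),
              min_burst_duration = as.numeric(min_burst_duration),
              min_burst_gap = as.numeric(min_burst_gap),
              n_sub = as.integer(n_sub), alpha = as.numeric(alpha),
              n_bins = as.integer(n_bins),
              psc_criterion = as.numeric(psc_criterion),
              psc_polarity = as.character(psc_polarity),
              femur = as.numeric(femur), tibia = as.numeric(tibia),
              knee_branch = as.character(knee_branch),
              seed = as.integer(seed))
  class(cfg) <- "pipeline_config"
  cfg
}

#' @rdname pipeline_config
#' @param config A `pipeline_config`.
#' @param path JSON file path.
#' @export
write_config <- function(config, path) {
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname pipeline_config
#' @export
read_config <- function(path) {
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  do.call(pipeline_config, cfg)
}

#' Run the fictive-locomotion analysis pipeline
#'
#' Executes the full chain on one recording: rectify/integrate both root
#' traces, detect bursts, segment double-normalized locomotor cycles,
#' classify the rhythmicity of each supplied spike train, and (when an
#' intracellular trace is supplied) detect synaptic events and build their
#' phase histogram. Writes per-stage CSV/JSON outputs plus a
#' machine-readable run manifest (all parameters, seeds, package version)
#' sufficient to reproduce the run exactly; the same configuration and
#' seed give byte-identical reports.
#'
#' @param config A [pipeline_config()].
#' @param traces Named list of [trace()] objects containing at least the
#'   configured flexor and extensor channels.
#' @param spike_trains Optional named list of numeric spike-time vectors
#'   (s), one per cell.
#' @param intracellular Optional [trace()] of holding current (pA).
#' @param out_dir Optional output directory; created if needed. When
#'   `NULL` nothing is written.
#' @return A list of class `"pipeline_report"` with elements `cycles`,
#'   `n_discarded_cycles`, `rhythmicity` (list of
#'   [classify_rhythmicity()] results), `psc_events`, `psc_histogram`,
#'   and `manifest`.
#' @export
run_pipeline <- function(config, traces, spike_trains = NULL,
                         intracellular = NULL, out_dir = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  if (length(traces) == 0L) stop("validation error: no input traces")
  for (ch in c(config$flexor_channel, config$extensor_channel))
    if (!ch %in% names(traces))
      stop("validation error: missing configured channel `", ch, "`")

  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("stage `%s` failed: %s", name, conditionMessage(e)),
           call. = FALSE))
  }
  env_flex <- stage("envelope", rectify_integrate(
    traces[[config$flexor_channel]], config$envelope_window))
  env_ext <- stage("envelope", rectify_integrate(
    traces[[config$extensor_channel]], config$envelope_window))
  bursts_flex <- stage("bursts", detect_bursts(
    env_flex, config$on_frac, config$off_frac,
    config$min_burst_duration, config$min_burst_gap))
  bursts_ext <- stage("bursts", detect_bursts(
    env_ext, config$on_frac, config$off_frac,
    config$min_burst_duration, config$min_burst_gap))
  cycles <- stage("cycles", segment_cycles(bursts_ext, bursts_flex))

  rhythmicity <- NULL
  if (!is.null(spike_trains)) {
    rhythmicity <- lapply(seq_along(spike_trains), function(i) {
      id <- names(spike_trains)[i]
      if (is.null(id) || !nzchar(id)) id <- paste0("cell_", i)
      stage(paste0("rhythmicity:", id), {
        ph <- phase_of_time(spike_trains[[i]], cycles)
        ph <- ph[!is.na(ph)]
        if (length(ph) == 0L)
          stop("no spikes fall inside a locomotor cycle")
        classify_rhythmicity(ph, n_sub = config$n_sub,
                             alpha = config$alpha,
                             seed = config$seed + i, cell_id = id)
      })
    })
    names(rhythmicity) <- vapply(rhythmicity, `[[`, "", "cell_id")
  }

  psc_events <- psc_hist <- NULL
  if (!is.null(intracellular)) {
    psc_events <- stage("psc_detect", detect_events(
      intracellular, make_template(dt = intracellular$dt * 1000),
      criterion = config$psc_criterion, polarity = config$psc_polarity))
    psc_hist <- stage("psc_histogram",
                      bin_events_by_phase(psc_events, cycles,
                                          config$n_bins))
  }

  manifest <- list(
    package = "locokit",
    version = as.character(utils::packageVersion("locokit")),
    config = unclass(config),
    inputs = list(channels = names(traces),
                  n_spike_trains = length(spike_trains),
                  has_intracellular = !is.null(intracellular)))

  report <- structure(list(
    cycles = cycles,
    n_discarded_cycles = attr(cycles, "n_discarded"),
    bursts = list(flexor = bursts_flex, extensor = bursts_ext),
    rhythmicity = rhythmicity,
    psc_events = psc_events,
    psc_histogram = psc_hist,
    manifest = manifest), class = "pipeline_report")

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(as.data.frame(cycles),
                     file.path(out_dir, "cycles.csv"), row.names = FALSE)
    if (!is.null(psc_events))
      utils::write.csv(psc_events, file.path(out_dir, "psc_events.csv"),
                       row.names = FALSE)
    rj <- list(
      manifest = manifest,
      n_cycles = nrow(cycles),
      n_discarded_cycles = attr(cycles, "n_discarded"),
      rhythmicity = lapply(rhythmicity, function(r)
        list(cell_id = r$cell_id, phi = r$stat$phi, r = r$stat$r,
             n = r$n_subsampled, n_total = r$n_total, p = r$stat$p,
             threshold = r$threshold, rhythmic = r$rhythmic,
             phase_class = r$phase_class, seed = r$seed)),
      psc_histogram = if (!is.null(psc_hist)) unclass(psc_hist))
    jsonlite::write_json(rj, file.path(out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE,
                         null = "null")
  }
  report
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat(sprintf("<pipeline_report> %d cycles (%d discarded)",
              nrow(x$cycles), x$n_discarded_cycles))
  if (!is.null(x$rhythmicity))
    cat(sprintf("; %d/%d cells rhythmic",
                sum(vapply(x$rhythmicity, `[[`, TRUE, "rhythmic")),
                length(x$rhythmicity)))
  if (!is.null(x$psc_events))
    cat(sprintf("; %d PSC events", nrow(x$psc_events)))
  cat("\n")
  invisible(x)
}
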