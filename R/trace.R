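#' Uniformly sampled voltage trace
#'
#' Container for a single extracellular recording: a numeric vector of
#' voltages (mV), the sampling rate (Hz), the time of the first sample, and
#' free-form metadata (fly id, genotype, circadian time, stimulus
#' description).
#'
#' @param values numeric vector of voltages in mV; length >= 2.
#' @param sampling_rate_hz samples per second, > 0.
#' @param t0_s time of the first sample in seconds (default 0).
#' @param metadata named list of annotations.
#' @return an object of class `ts_trace`.
#' @export
ts_trace <- function(values, sampling_rate_hz, t0_s = 0, metadata = list()) {
  stopifnot(is.numeric(values), length(values) >= 2L, all(is.finite(values)),
            is.numeric(sampling_rate_hz), length(sampling_rate_hz) == 1L,
            sampling_rate_hz > 0, is.list(metadata))
  structure(list(values = as.numeric(values),
                 sampling_rate_hz = sampling_rate_hz,
                 t0_s = t0_s,
                 metadata = metadata),
            class = "ts_trace")
}

#' Sample times of a trace
#' @param trace a [ts_trace].
#' @return numeric vector of times in seconds.
#' @export
trace_times <- function(trace) {
  stopifnot(inherits(trace, "ts_trace"))
  trace$t0_s + (seq_along(trace$values) - 1L) / trace$sampling_rate_hz
}

#' Duration of a trace in seconds
#' @param trace a [ts_trace].
#' @export
trace_duration <- function(trace) {
  length(trace$values) / trace$sampling_rate_hz
}

#' @export
print.ts_trace <- function(x, ...) {
  cat(sprintf("Voltage trace: %d samples at %g Hz (%.3f s), range [%.3g, %.3g] mV\n",
              length(x$values), x$sampling_rate_hz, trace_duration(x),
              min(x$values), max(x$values)))
  if (length(x$metadata))
    cat("  metadata:", paste(names(x$metadata), collapse = ", "), "\n")
  invisible(x)
}

#' Write a trace to CSV with a JSON metadata sidecar
#'
#' The CSV has two columns, `time_s` and `mv`.  Stimulus and provenance
#' metadata (flash onset/duration, flicker frequencies and contrasts, fly id,
#' ...) go to `<path>.json`.
#'
#' @param trace a [ts_trace].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_trace <- function(trace, path) {
  stopifnot(inherits(trace, "ts_trace"))
  df <- data.frame(time_s = trace_times(trace), mv = trace$values)
  utils::write.csv(df, path, row.names = FALSE)
  meta <- c(trace$metadata, list(sampling_rate_hz = trace$sampling_rate_hz,
                                 t0_s = trace$t0_s))
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Read a trace written by [write_trace]
#'
#' @param path CSV path; `<path>.json` is read as metadata if present.
#' @return a [ts_trace].
#' @export
read_trace <- function(path) {
  df <- utils::read.csv(path)
  stopifnot(all(c("time_s", "mv") %in% names(df)), nrow(df) >= 2L)
  meta <- list()
  side <- paste0(path, ".json")
  if (file.exists(side)) meta <- jsonlite::read_json(side, simplifyVector = TRUE)
  fs <- meta$sampling_rate_hz
  if (is.null(fs)) fs <- 1 / stats::median(diff(df$time_s))
  meta$sampling_rate_hz <- NULL
  t0 <- if (!is.null(meta$t0_s)) meta$t0_s else df$time_s[1]
  meta$t0_s <- NULL
  ts_trace(df$mv, sampling_rate_hz = fs, t0_s = t0, metadata = meta)
}
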