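#' Extract flash-ERG features from a voltage trace
#'
#' Measures the classical fly flash-ERG parameters given known stimulus
#' timing:
#' \describe{
#'   \item{receptor_potential_mv}{magnitude of the sustained deflection,
#'     \eqn{|baseline - plateau|}, where baseline is the mean over the
#'     `baseline_window_s` before pulse onset and the plateau is the mean
#'     over the last `plateau_window_s` of the pulse.}
#'   \item{off_transient_mv}{magnitude of the largest deviation from the
#'     plateau level within `off_window_s` after light offset.}
#'   \item{peak_to_peak_mv}{max minus min over the response window
#'     (onset to offset + `p2p_window_s`).}
#'   \item{latency_ms}{time from onset to the first crossing of half the
#'     receptor potential (baseline minus half the sustained deflection);
#'     `NA` when the receptor potential is zero or never half-crossed.}
#' }
#' All amplitudes are reported as nonnegative magnitudes, matching the
#' usual bar-chart convention for the corneal-negative ERG.
#'
#' @param trace a [ts_trace] covering at least
#'   `[onset - 0.1 s, offset + 0.3 s]`.
#' @param pulse_onset_s,pulse_duration_s stimulus timing in seconds; taken
#'   from the trace metadata when omitted.
#' @param baseline_window_s,plateau_window_s,off_window_s,p2p_window_s
#'   analysis window lengths (defaults 0.1, 0.05, 0.1, 0.3 s).
#' @return a one-row data.frame of class `ferg_features` with columns
#'   `peak_to_peak_mv`, `receptor_potential_mv`, `off_transient_mv`,
#'   `latency_ms`, `baseline_mv`.
#' @export
extract_ferg_features <- function(trace,
                                  pulse_onset_s = NULL,
                                  pulse_duration_s = NULL,
                                  baseline_window_s = 0.1,
                                  plateau_window_s = 0.05,
                                  off_window_s = 0.1,
                                  p2p_window_s = 0.3) {
  stopifnot(inherits(trace, "ts_trace"))
  if (is.null(pulse_onset_s)) pulse_onset_s <- trace$metadata$pulse_onset_s
  if (is.null(pulse_duration_s))
    pulse_duration_s <- trace$metadata$pulse_duration_s
  if (is.null(pulse_onset_s) || is.null(pulse_duration_s))
    stop("pulse timing not supplied and not present in trace metadata")
  t <- trace_times(trace)
  v <- trace$values
  onset <- pulse_onset_s
  offset <- pulse_onset_s + pulse_duration_s
  if (t[1] > onset - baseline_window_s + 1e-9 ||
      t[length(t)] < offset + p2p_window_s - 1e-9)
    stop("trace too short: must cover [onset - ", baseline_window_s,
         " s, offset + ", p2p_window_s, " s]")

  base_idx <- t >= onset - baseline_window_s & t < onset
  baseline <- mean(v[base_idx])
  plat_idx <- t >= offset - plateau_window_s & t < offset
  plateau <- mean(v[plat_idx])
  rp <- abs(baseline - plateau)

  off_idx <- t >= offset & t < offset + off_window_s
  dev <- v[off_idx] - plateau
  off_tr <- max(abs(dev))

  p2p_idx <- t >= onset & t <= offset + p2p_window_s
  p2p <- max(v[p2p_idx]) - min(v[p2p_idx])

  latency <- NA_real_
  if (rp > 0) {
    # deflection is signed: half-crossing level lies between baseline and
    # plateau
    half <- (baseline + plateau) / 2
    after <- which(t >= onset)
    crossed <- if (plateau < baseline) v[after] <= half else v[after] >= half
    k <- which(crossed)[1]
    if (!is.na(k)) latency <- (t[after[k]] - onset) * 1000
  }

  structure(data.frame(peak_to_peak_mv = p2p,
                       receptor_potential_mv = rp,
                       off_transient_mv = off_tr,
                       latency_ms = latency,
                       baseline_mv = baseline),
            class = c("ferg_features", "data.frame"))
}

#' Extract fERG features for a batch of traces
#'
#' @param traces list of [ts_trace]s carrying flash metadata.
#' @param ... passed to [extract_ferg_features].
#' @return data.frame with one row per trace plus any `fly`, `genotype` and
#'   `ct_h` metadata found on the traces.
#' @export
extract_ferg_batch <- function(traces, ...) {
  rows <- lapply(traces, function(tr) {
    f <- extract_ferg_features(tr, ...)
    for (key in c("fly", "genotype", "ct_h"))
      f[[key]] <- if (!is.null(tr$metadata[[key]])) tr$metadata[[key]] else NA
    f
  })
  do.call(rbind, rows)
}
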