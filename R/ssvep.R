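#' Single-sided amplitude spectrum of a trace
#'
#' Rectangular-window DFT amplitude spectrum, normalized so a pure sinusoid
#' of amplitude `a` yields `a` at its frequency bin.  The trace must span an
#' integer number of seconds so that integer-Hz stimulus frequencies fall on
#' exact bins; with exact-bin frequencies no windowing is needed and
#' broadband noise stays confined to its own bins.
#'
#' @param trace a [ts_trace] of integer-second duration.
#' @return data.frame of class `amplitude_spectrum` with columns
#'   `frequency_hz` (0 .. Nyquist) and `amplitude_mv`; the bin resolution
#'   (Hz) is attached as attribute `resolution_hz`.
#' @export
amplitude_spectrum <- function(trace) {
  stopifnot(inherits(trace, "ts_trace"))
  n <- length(trace$values)
  fs <- trace$sampling_rate_hz
  dur <- n / fs
  if (abs(dur - round(dur)) > 1e-9)
    stop("trace duration must be an integer number of seconds")
  X <- stats::fft(trace$values)
  half <- floor(n / 2)
  amp <- Mod(X[seq_len(half + 1L)]) / n
  amp[-1L] <- 2 * amp[-1L]
  if (n %% 2L == 0L) amp[half + 1L] <- amp[half + 1L] / 2  # Nyquist bin
  freq <- (0:half) * fs / n
  structure(data.frame(frequency_hz = freq, amplitude_mv = amp),
            resolution_hz = fs / n,
            class = c("amplitude_spectrum", "data.frame"))
}

# Amplitude at an exact frequency bin; errors if the frequency is not on
# the grid or beyond Nyquist.
spectrum_at <- function(spectrum, f_hz) {
  res <- attr(spectrum, "resolution_hz")
  k <- f_hz / res
  if (abs(k - round(k)) > 1e-6)
    stop("frequency ", f_hz, " Hz is not an exact spectral bin")
  k <- as.integer(round(k)) + 1L
  if (k > nrow(spectrum)) stop("frequency ", f_hz, " Hz is beyond Nyquist")
  spectrum$amplitude_mv[k]
}

# All harmonic/intermodulation frequencies |a*f1 + b*f2| for small a, b;
# used to exclude structured bins from noise-floor estimation.  Memoized:
# the same stimulus pair recurs for every trial of a protocol.
.structured_cache <- new.env(parent = emptyenv())
structured_freqs <- function(f1, f2, max_order = 4L) {
  key <- paste(f1, f2, max_order)
  if (!is.null(.structured_cache[[key]])) return(.structured_cache[[key]])
  ab <- expand.grid(a = -max_order:max_order, b = -max_order:max_order)
  out <- sort(unique(abs(ab$a * f1 + ab$b * f2)))
  .structured_cache[[key]] <- out
  out
}

#' Extract SSVEP harmonic and intermodulation components
#'
#' Reads the amplitudes at 1F1, 2F1, 1F2-1F1, 1F1+1F2 and 2F1+2F2 (for the
#' default 12/15 Hz stimulus: 12, 24, 3, 27 and 54 Hz) and estimates a
#' per-component noise floor as the mean amplitude over the two flanking
#' bins on each side, skipping any flanking bin that is itself a harmonic
#' or intermodulation frequency of the stimulus pair.
#'
#' @param spectrum an [amplitude_spectrum].
#' @param f1_hz,f2_hz stimulus frequencies (integer Hz).
#' @param n_flank flanking bins per side for the noise floor (default 2).
#' @return data.frame of class `ssvep_components` with columns `component`,
#'   `frequency_hz`, `amplitude_mv`, `noise_floor_mv`.
#' @export
extract_components <- function(spectrum, f1_hz = 12, f2_hz = 15,
                               n_flank = 2L) {
  stopifnot(inherits(spectrum, "amplitude_spectrum"))
  res <- attr(spectrum, "resolution_hz")
  if (res > 1 + 1e-9)
    stop("spectral resolution coarser than 1 Hz; use a longer trace")
  comp <- c(`1F1` = f1_hz, `2F1` = 2 * f1_hz, `1F2-1F1` = f2_hz - f1_hz,
            `1F1+1F2` = f1_hz + f2_hz, `2F1+2F2` = 2 * f1_hz + 2 * f2_hz)
  nyq <- spectrum$frequency_hz[nrow(spectrum)]
  if (any(comp > nyq)) stop("component frequency beyond Nyquist")
  excl <- structured_freqs(f1_hz, f2_hz)
  amp <- vapply(comp, function(f) spectrum_at(spectrum, f), 0)
  nbin <- nrow(spectrum)
  floor_est <- vapply(comp, function(f) {
    k0 <- as.integer(round(f / res)) + 1L
    # walk outward on each side collecting n_flank clean bins
    cand <- unlist(lapply(c(-1L, 1L), function(dir) {
      k <- k0 + dir * seq_len(n_flank + 8L)
      k <- k[k >= 2L & k <= nbin]
      fk <- spectrum$frequency_hz[k]
      clean <- vapply(fk, function(fv) min(abs(fv - excl)) >= res / 2, TRUE)
      utils::head(k[clean], n_flank)
    }))
    if (!length(cand)) return(NA_real_)
    mean(spectrum$amplitude_mv[cand])
  }, 0)
  structure(data.frame(component = names(comp), frequency_hz = unname(comp),
                       amplitude_mv = unname(amp),
                       noise_floor_mv = unname(floor_est),
                       stringsAsFactors = FALSE),
            class = c("ssvep_components", "data.frame"))
}

#' Decompose an 18-trial SSVEP block
#'
#' Decomposes every trial into its spectral components and flags trials
#' 10-18 as the analysis set; the first half of the protocol is discarded
#' from all downstream summaries to remove adaptation to the flicker.
#'
#' @param trials list of `list(stimulus =, trace =)` pairs ordered by
#'   `trial_index` (e.g. from [simulate_trial_block]); normally exactly 18.
#' @param allow_partial set TRUE to accept a block of a different size (the
#'   last half is then the analysis set).
#' @param ... passed to [extract_components].
#' @return data.frame of class `trial_components`: one row per trial x
#'   component with columns `trial`, `c1`, `c2`, `component`,
#'   `frequency_hz`, `amplitude_mv`, `noise_floor_mv`, `analyzed`.
#' @export
analyze_trial_block <- function(trials, allow_partial = FALSE, ...) {
  n <- length(trials)
  if (n != 18L && !allow_partial)
    stop("expected exactly 18 trials (got ", n,
         "); set allow_partial = TRUE to override")
  idx <- vapply(trials, function(tr) tr$stimulus$trial_index, 0L)
  if (any(diff(idx) <= 0)) stop("trials must be ordered by trial_index")
  first_analyzed <- floor(n / 2) + 1L
  cmps <- lapply(trials, function(tr) {
    st <- tr$stimulus
    extract_components(amplitude_spectrum(tr$trace),
                       f1_hz = st$f1_hz, f2_hz = st$f2_hz, ...)
  })
  k <- vapply(cmps, nrow, 0L)
  meta <- data.frame(
    trial = rep(idx, k),
    c1 = rep(vapply(trials, function(tr) tr$stimulus$c1, 0), k),
    c2 = rep(vapply(trials, function(tr) tr$stimulus$c2, 0), k),
    stringsAsFactors = FALSE)
  out <- cbind(meta, do.call(rbind, cmps))
  out$analyzed <- rep(seq_len(n) >= first_analyzed, k)
  class(out) <- c("trial_components", "data.frame")
  out
}

#' Contrast-response functions from an analyzed trial block
#'
#' For each spectral component, pairs the per-trial amplitude with its
#' driving contrast (c1 for the f1 harmonics 1F1 and 2F1, and the product
#' c1*c2 for the intermodulation terms, whose drive requires both inputs)
#' and summarizes steepness as the least-squares slope of the
#' origin-anchored line through the points.  Only analyzed trials enter.
#'
#' @param components a `trial_components` data.frame from
#'   [analyze_trial_block].
#' @return data.frame of class `contrast_response` with one row per
#'   component: `component`, `slope`, `n_trials`, plus the underlying
#'   points as attribute `points`.
#' @export
contrast_response <- function(components) {
  stopifnot(inherits(components, "trial_components"))
  an <- components[components$analyzed, , drop = FALSE]
  if (nrow(an) == 0L) stop("no analyzed trials")
  drive <- ifelse(an$component %in% c("1F1", "2F1"), an$c1, an$c1 * an$c2)
  pts <- data.frame(component = an$component, contrast = drive,
                    amplitude_mv = an$amplitude_mv,
                    stringsAsFactors = FALSE)
  out <- do.call(rbind, lapply(split(pts, pts$component), function(d) {
    slope <- if (length(unique(d$contrast)) < 2L) {
      NA_real_   # a single contrast level cannot define steepness
    } else {
      sum(d$contrast * d$amplitude_mv) / sum(d$contrast^2)
    }
    data.frame(component = d$component[1], slope = slope,
               n_trials = nrow(d), stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  structure(out, points = pts,
            class = c("contrast_response", "data.frame"))
}

#' Per-fly summary response: the maximum amplitude per component
#'
#' The per-fly value carried into circadian period fitting is the maximum
#' component amplitude across the analyzed trials.
#'
#' @param components a `trial_components` data.frame.
#' @param how `"max"` (default) or `"mean"` over analyzed trials.
#' @return data.frame with columns `component`, `frequency_hz`,
#'   `amplitude_mv`.
#' @export
fly_summary <- function(components, how = c("max", "mean")) {
  stopifnot(inherits(components, "trial_components"))
  how <- match.arg(how)
  an <- components[components$analyzed, , drop = FALSE]
  if (nrow(an) == 0L) stop("no analyzed trials")
  agg <- stats::aggregate(amplitude_mv ~ component + frequency_hz, data = an,
                          FUN = if (how == "max") max else mean)
  agg[order(agg$frequency_hz), c("component", "frequency_hz", "amplitude_mv")]
}
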