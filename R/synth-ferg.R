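#' Flash-ERG template parameters
#'
#' Parameterizes the stereotyped fly flash electroretinogram evoked by a
#' light pulse (default 750 ms): a sustained corneal-negative receptor
#' potential that rises exponentially during the pulse, a fast negative
#' on-transient at light onset, and a fast positive off-transient at light
#' offset.  All amplitudes are signed deflections from baseline in mV;
#' features are later reported as magnitudes.
#'
#' @param baseline_mv resting potential, mV.
#' @param receptor_potential_mv sustained deflection during the pulse;
#'   corneal-negative, so normally negative.
#' @param on_transient_mv additive transient at pulse onset (normally
#'   negative).
#' @param off_transient_mv additive transient at pulse offset (normally
#'   positive).
#' @param pulse_onset_s time of light onset, s.
#' @param pulse_duration_s pulse length, s (default 0.75).
#' @param tau_rise_s time constant of the receptor-potential rise, s.
#' @param tau_decay_s time constant of the post-offset return to baseline, s.
#' @param tau_transient_s decay time constant of the on/off transients, s.
#' @param noise_sd_mv standard deviation of additive Gaussian noise, mV.
#' @param sampling_rate_hz sampling rate, Hz.
#' @return an object of class `ferg_params`.
#' @export
ferg_params <- function(baseline_mv = 0,
                        receptor_potential_mv = -8,
                        on_transient_mv = -2,
                        off_transient_mv = 3,
                        pulse_onset_s = 0.2,
                        pulse_duration_s = 0.75,
                        tau_rise_s = 0.03,
                        tau_decay_s = 0.08,
                        tau_transient_s = 0.02,
                        noise_sd_mv = 0,
                        sampling_rate_hz = 1000) {
  stopifnot(pulse_duration_s > 0, pulse_onset_s >= 0,
            tau_rise_s > 0, tau_decay_s > 0, tau_transient_s > 0,
            noise_sd_mv >= 0)
  if (sampling_rate_hz <= 0) stop("sampling_rate_hz must be positive")
  structure(list(baseline_mv = baseline_mv,
                 receptor_potential_mv = receptor_potential_mv,
                 on_transient_mv = on_transient_mv,
                 off_transient_mv = off_transient_mv,
                 pulse_onset_s = pulse_onset_s,
                 pulse_duration_s = pulse_duration_s,
                 tau_rise_s = tau_rise_s,
                 tau_decay_s = tau_decay_s,
                 tau_transient_s = tau_transient_s,
                 noise_sd_mv = noise_sd_mv,
                 sampling_rate_hz = sampling_rate_hz),
            class = "ferg_params")
}

# Noiseless fERG template at given times (seconds), without baseline.
# Transients are alpha-functions (peak amplitude = the parameter, peak time
# = tau_transient after the transition) so the trace leaves baseline
# smoothly and the nominal transient amplitude is recoverable.
ferg_template <- function(params, t) {
  on <- params$pulse_onset_s
  off <- on + params$pulse_duration_s
  alpha_shape <- function(tau, tt) ifelse(tau >= 0, (tau / tt) * exp(1 - tau / tt), 0)
  v <- numeric(length(t))
  during <- t >= on & t < off
  after <- t >= off
  # sustained receptor potential: exponential rise during the pulse,
  # exponential return after offset
  v[during] <- params$receptor_potential_mv *
    (1 - exp(-(t[during] - on) / params$tau_rise_s))
  plateau <- params$receptor_potential_mv *
    (1 - exp(-params$pulse_duration_s / params$tau_rise_s))
  v[after] <- plateau * exp(-(t[after] - off) / params$tau_decay_s)
  # fast transients at the light transitions
  v <- v + params$on_transient_mv * alpha_shape(t - on, params$tau_transient_s)
  v <- v + params$off_transient_mv * alpha_shape(t - off, params$tau_transient_s)
  v
}

#' Generate a synthetic flash-ERG trace
#'
#' Produces baseline + `gain`-scaled fERG template + white Gaussian noise.
#' The trace runs from 0 to at least `pulse_onset + pulse_duration + 0.5` s.
#' Bit-reproducible for a given (params, gain, seed).
#'
#' @param params a [ferg_params].
#' @param gain dimensionless multiplicative gain (e.g. from
#'   [circadian_gain]); >= 0.
#' @param seed integer RNG seed.
#' @param duration_s total trace duration; defaults to
#'   `pulse_onset + pulse_duration + 0.5`.
#' @return a [ts_trace] with flash metadata.
#' @export
generate_ferg_trace <- function(params, gain = 1, seed = 1L,
                                duration_s = NULL) {
  stopifnot(inherits(params, "ferg_params"), gain >= 0)
  min_dur <- params$pulse_onset_s + params$pulse_duration_s + 0.5
  if (is.null(duration_s)) duration_s <- min_dur
  if (duration_s < min_dur)
    stop("duration_s must cover the pulse plus 0.5 s")
  n <- round(duration_s * params$sampling_rate_hz)
  t <- (seq_len(n) - 1L) / params$sampling_rate_hz
  v <- params$baseline_mv + gain * ferg_template(params, t)
  if (params$noise_sd_mv > 0) {
    v <- v + withr::with_seed(seed,
      stats::rnorm(n, sd = params$noise_sd_mv))
  }
  ts_trace(v, params$sampling_rate_hz, t0_s = 0,
           metadata = list(stimulus = "flash",
                           pulse_onset_s = params$pulse_onset_s,
                           pulse_duration_s = params$pulse_duration_s,
                           gain = gain, seed = seed))
}
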