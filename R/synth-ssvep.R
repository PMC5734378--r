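#' Visual cascade parameters for SSVEP simulation
#'
#' The simulated eye is a three-stage cascade driven by the summed
#' square-wave contrast stimulus: a linear photoreceptor stage, a lamina
#' stage that squares its (synaptically low-pass filtered) input, and a
#' medulla stage that squares the filtered lamina output.  Squaring after
#' filtering creates response energy exactly at the second harmonics (2F1 =
#' 24 Hz, 2F2 = 30 Hz) and intermodulation frequencies (1F2-1F1 = 3 Hz,
#' 1F1+1F2 = 27 Hz) in the lamina stage and at 2F1+2F2 = 54 Hz in the
#' medulla stage, mirroring the anatomical attribution of those spectral
#' components.  An ideal square wave squares to a constant, so the synaptic
#' low-pass (first-order, default 50 Hz cutoff) is what lets the harmonic
#' and intermodulation terms survive; the photoreceptor stage itself is
#' broadband and strictly linear.
#'
#' @param photoreceptor_gain mV per unit contrast, >= 0.
#' @param lamina_gain,medulla_gain dimensionless stage weights, >= 0.
#' @param mix_weights nonnegative length-3 weights summing the three stage
#'   outputs into the recorded trace.
#' @param noise_sd_mv additive Gaussian noise SD, mV.
#' @param sampling_rate_hz sampling rate; must be at least 4x the highest
#'   analyzed frequency (>= 216 Hz for the 54 Hz medulla term).
#' @param synapse_cutoff_hz cutoff of the first-order low-pass applied
#'   before each squaring nonlinearity.
#' @return an object of class `cascade_params`.
#' @export
cascade_params <- function(photoreceptor_gain = 10,
                           lamina_gain = 0.1,
                           medulla_gain = 0.05,
                           mix_weights = c(1, 0.5, 0.25),
                           noise_sd_mv = 0,
                           sampling_rate_hz = 1000,
                           synapse_cutoff_hz = 50) {
  stopifnot(photoreceptor_gain >= 0, lamina_gain >= 0, medulla_gain >= 0,
            length(mix_weights) == 3L, all(mix_weights >= 0),
            noise_sd_mv >= 0, synapse_cutoff_hz > 0)
  if (sampling_rate_hz < 4 * 54)
    stop("sampling_rate_hz must be >= 216 Hz (4x the 54 Hz medulla term)")
  structure(list(photoreceptor_gain = photoreceptor_gain,
                 lamina_gain = lamina_gain,
                 medulla_gain = medulla_gain,
                 mix_weights = as.numeric(mix_weights),
                 noise_sd_mv = noise_sd_mv,
                 sampling_rate_hz = sampling_rate_hz,
                 synapse_cutoff_hz = synapse_cutoff_hz),
            class = "cascade_params")
}

#' Two-frequency flicker stimulus description
#'
#' @param c1,c2 contrasts of the 12 Hz and 15 Hz square-wave components, in
#'   [0, 1].
#' @param f1_hz,f2_hz flicker frequencies (integer Hz, distinct).
#' @param duration_s trial length; must be an integer number of seconds so
#'   all analyzed frequencies fall on exact spectral bins.
#' @param trial_index position within an 18-trial protocol (1..18), or NA.
#' @return an object of class `flicker_stimulus`.
#' @export
flicker_stimulus <- function(c1, c2, f1_hz = 12, f2_hz = 15, duration_s = 3,
                             trial_index = NA_integer_) {
  stopifnot(c1 >= 0, c1 <= 1, c2 >= 0, c2 <= 1,
            f1_hz == round(f1_hz), f2_hz == round(f2_hz), f1_hz != f2_hz)
  if (duration_s != round(duration_s) || duration_s < 1)
    stop("duration_s must be a positive integer number of seconds ",
         "(non-integer durations leak spectral power across bins)")
  structure(list(c1 = c1, c2 = c2, f1_hz = f1_hz, f2_hz = f2_hz,
                 duration_s = as.integer(duration_s),
                 trial_index = as.integer(trial_index)),
            class = "flicker_stimulus")
}

#' Square wave samples
#'
#' +/-1 square wave with 50% duty cycle starting at +1 at t = 0.
#'
#' @param f_hz frequency in Hz.
#' @param t times in seconds.
#' @return numeric vector of +1/-1.
#' @export
square_wave <- function(f_hz, t) {
  1 - 2 * ((t * f_hz) %% 1 >= 0.5)
}

# First-order low-pass filter applied in the frequency domain (exact for
# the periodic, integer-second traces used here).
lowpass_fd <- function(x, fs, cutoff_hz) {
  n <- length(x)
  k <- 0:(n - 1)
  f <- ifelse(k <= n / 2, k, k - n) * fs / n
  h <- 1 / (1 + 1i * f / cutoff_hz)
  Re(stats::fft(stats::fft(x) * h, inverse = TRUE)) / n
}

#' Generate a synthetic SSVEP trace from the nonlinear cascade
#'
#' The stimulus is `s(t) = c1 * sq(f1) + c2 * sq(f2)` (sum of two +/-1
#' square waves).  Stage outputs are
#' `y1 = g1 * s` (photoreceptor, linear),
#' `y2 = g2 * lowpass(y1)^2` (lamina) and
#' `y3 = g3 * lowpass(y2)^2` (medulla); the trace is
#' `w1*y1 + w2*y2 + w3*y3` plus white Gaussian noise.  Per-stage circadian
#' gains multiply `g1..g3`, so genotype-specific rhythms can modulate each
#' anatomical stage independently.
#'
#' @param stimulus a [flicker_stimulus].
#' @param cascade a [cascade_params].
#' @param stage_gains length-3 multiplicative circadian gains for the
#'   photoreceptor, lamina and medulla stages (default all 1).
#' @param seed integer RNG seed for the noise.
#' @return a [ts_trace] with flicker metadata.
#' @export
generate_ssvep_trace <- function(stimulus, cascade, stage_gains = c(1, 1, 1),
                                 seed = 1L) {
  stopifnot(inherits(stimulus, "flicker_stimulus"),
            inherits(cascade, "cascade_params"),
            length(stage_gains) == 3L, all(stage_gains >= 0))
  fs <- cascade$sampling_rate_hz
  n <- as.integer(round(stimulus$duration_s * fs))
  t <- (seq_len(n) - 1L) / fs
  s <- stimulus$c1 * square_wave(stimulus$f1_hz, t) +
       stimulus$c2 * square_wave(stimulus$f2_hz, t)
  g1 <- cascade$photoreceptor_gain * stage_gains[1]
  g2 <- cascade$lamina_gain * stage_gains[2]
  g3 <- cascade$medulla_gain * stage_gains[3]
  fc <- cascade$synapse_cutoff_hz
  y1 <- g1 * s
  y2 <- g2 * lowpass_fd(y1, fs, fc)^2
  y3 <- g3 * lowpass_fd(y2, fs, fc)^2
  w <- cascade$mix_weights
  v <- w[1] * y1 + w[2] * y2 + w[3] * y3
  if (cascade$noise_sd_mv > 0) {
    v <- v + withr::with_seed(seed,
      stats::rnorm(n, sd = cascade$noise_sd_mv))
  }
  ts_trace(v, fs, t0_s = 0,
           metadata = list(stimulus = "flicker",
                           f1_hz = stimulus$f1_hz, f2_hz = stimulus$f2_hz,
                           c1 = stimulus$c1, c2 = stimulus$c2,
                           duration_s = stimulus$duration_s,
                           trial_index = stimulus$trial_index,
                           seed = seed))
}

#' Simulate an 18-trial random-contrast SSVEP protocol
#'
#' Each trial draws the two contrasts independently and uniformly from
#' `contrast_levels`, then records a trace through the cascade.  Only the
#' last 9 trials are meant for analysis (the first 9 allow for adaptation);
#' that bookkeeping is applied downstream by [analyze_trial_block].
#'
#' @param cascade a [cascade_params].
#' @param stage_gains length-3 circadian stage gains.
#' @param n_trials number of trials (default 18).
#' @param duration_s per-trial duration, integer seconds.
#' @param contrast_levels candidate contrasts (default 0.1..0.9 by 0.1).
#' @param seed integer seed controlling both contrast draws and noise.
#' @return list of `list(stimulus =, trace =)` pairs, one per trial.
#' @export
simulate_trial_block <- function(cascade, stage_gains = c(1, 1, 1),
                                 n_trials = 18L, duration_s = 3,
                                 contrast_levels = seq(0.1, 0.9, by = 0.1),
                                 seed = 1L) {
  stopifnot(n_trials >= 1)
  cs <- withr::with_seed(seed, matrix(
    contrast_levels[sample.int(length(contrast_levels), 2L * n_trials,
                               replace = TRUE)], ncol = 2L))
  noise_seeds <- withr::with_seed(seed + 1L,
    sample.int(.Machine$integer.max - 1L, n_trials))
  lapply(seq_len(n_trials), function(i) {
    stim <- flicker_stimulus(cs[i, 1], cs[i, 2], duration_s = duration_s,
                             trial_index = i)
    list(stimulus = stim,
         trace = generate_ssvep_trace(stim, cascade, stage_gains,
                                      seed = noise_seeds[i]))
  })
}
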