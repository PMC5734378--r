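# Shared synthetic fixtures for the test suite.

# Unimodal "clock-mutant-like" profile: 25.2 h period peaking at CT4.
unimodal_profile <- function(amplitude = 0.3) {
  gain_profile(1, data.frame(amplitude = amplitude, period_h = 25.2,
                             peak_ct_h = 4))
}

# "Control-like" profile: 14.6 h period (two peaks per day), peak CT6.
bimodal_profile <- function(amplitude = 0.3) {
  gain_profile(1, data.frame(amplitude = amplitude, period_h = 14.6,
                             peak_ct_h = 6))
}

# fERG template with a slow post-offset decay, so the nominal transient and
# sustained amplitudes are recoverable by the windowed feature definitions.
slow_decay_ferg <- function(noise_sd_mv = 0) {
  ferg_params(receptor_potential_mv = -8, on_transient_mv = -2,
              off_transient_mv = 3, tau_rise_s = 0.03, tau_decay_s = 50,
              noise_sd_mv = noise_sd_mv)
}

# Direct DFT amplitude at one frequency: independent of the fft-based path.
dft_amplitude <- function(x, fs, f_hz) {
  n <- length(x)
  t <- (seq_len(n) - 1) / fs
  2 * Mod(sum(x * exp(-2i * pi * f_hz * t))) / n
}

# Exact least-squares sinusoid coefficients via explicit normal equations.
normal_equation_fit <- function(t_days, y, omega_days) {
  X <- cbind(1, sin(2 * pi * t_days / omega_days),
             cos(2 * pi * t_days / omega_days))
  beta <- solve(crossprod(X), crossprod(X, y))
  list(coef = drop(beta), rss = sum((y - X %*% beta)^2))
}
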