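test_that("fERG generator produces the stereotyped waveform", {
  p <- slow_decay_ferg()

  # gain 0 with no noise is flat at baseline
  flat <- generate_ferg_trace(p, gain = 0)
  expect_true(all(flat$values == p$baseline_mv))

  # sustained negativity plateaus at the receptor-potential amplitude
  tr <- generate_ferg_trace(p, gain = 1)
  t <- trace_times(tr)
  off <- p$pulse_onset_s + p$pulse_duration_s
  plateau <- mean(tr$values[t >= off - 0.05 & t < off])
  expect_lt(abs(plateau - (p$baseline_mv - 8)), 0.01 * 8)

  # duration and sampling contract
  expect_gte(trace_duration(tr), p$pulse_onset_s + p$pulse_duration_s + 0.5)
  expect_error(generate_ferg_trace(p, duration_s = 0.5), "duration")
  expect_error(ferg_params(sampling_rate_hz = 0), "positive")
})

test_that("fERG noise is seed-deterministic", {
  p <- slow_decay_ferg(noise_sd_mv = 0.1)
  a <- generate_ferg_trace(p, gain = 1, seed = 7L)
  b <- generate_ferg_trace(p, gain = 1, seed = 7L)
  c <- generate_ferg_trace(p, gain = 1, seed = 8L)
  expect_identical(a$values, b$values)
  expect_false(identical(a$values, c$values))
})

test_that("SSVEP cascade produces the harmonic/intermodulation taxonomy", {
  casc <- cascade_params(noise_sd_mv = 0)

  # no stimulus, no noise: identically zero
  z <- generate_ssvep_trace(flicker_stimulus(0, 0), casc)
  expect_true(all(z$values == 0))

  # single 12 Hz input: energy at 12 and 24 Hz, none at 27/30/54 Hz
  one <- generate_ssvep_trace(flicker_stimulus(0.5, 0), casc)
  sp <- amplitude_spectrum(one)
  amp <- function(f) sp$amplitude_mv[sp$frequency_hz == f]
  expect_gt(amp(12), 1)
  expect_gt(amp(24), 0.01)
  expect_lt(amp(27), 1e-9)
  expect_lt(amp(30), 1e-9)
  expect_lt(amp(54), 1e-9)

  # both inputs through the medulla stage: 54 Hz appears
  both <- generate_ssvep_trace(flicker_stimulus(0.5, 0.5), casc)
  sp2 <- amplitude_spectrum(both)
  expect_gt(sp2$amplitude_mv[sp2$frequency_hz == 54], 0.01)

  # with the medulla weight off, no 54 Hz even with both inputs
  casc0 <- cascade_params(noise_sd_mv = 0, mix_weights = c(1, 0.5, 0))
  none <- generate_ssvep_trace(flicker_stimulus(0.5, 0.5), casc0)
  sp3 <- amplitude_spectrum(none)
  expect_lt(sp3$amplitude_mv[sp3$frequency_hz == 54], 1e-9)

  expect_error(flicker_stimulus(0.5, 0.5, duration_s = 2.5), "integer")
  expect_error(cascade_params(sampling_rate_hz = 100), "216")
})

test_that("stage-1-only cascade is exactly linear in contrast", {
  casc <- cascade_params(noise_sd_mv = 0, mix_weights = c(1, 0, 0))
  tr1 <- generate_ssvep_trace(flicker_stimulus(0.3, 0.2), casc)
  tr2 <- generate_ssvep_trace(flicker_stimulus(0.6, 0.4), casc)
  expect_equal(2 * tr1$values, tr2$values, tolerance = 1e-12)
})

test_that("square-wave fundamental matches the analytic Fourier series", {
  # 12 Hz square wave of contrast c1 through the linear stage: amplitude
  # (4/pi) * c1 * g1 * w1 at the fundamental
  casc <- cascade_params(photoreceptor_gain = 3, noise_sd_mv = 0,
                         mix_weights = c(0.7, 0, 0))
  tr <- generate_ssvep_trace(flicker_stimulus(0.5, 0, duration_s = 3), casc)
  sp <- amplitude_spectrum(tr)
  expect_equal(sp$amplitude_mv[sp$frequency_hz == 12],
               (4 / pi) * 0.5 * 3 * 0.7, tolerance = 1e-3)
})

test_that("SSVEP generation is bit-reproducible given a seed", {
  casc <- cascade_params(noise_sd_mv = 0.3)
  st <- flicker_stimulus(0.4, 0.7)
  expect_identical(generate_ssvep_trace(st, casc, seed = 3L)$values,
                   generate_ssvep_trace(st, casc, seed = 3L)$values)
  blk1 <- simulate_trial_block(casc, seed = 5L)
  blk2 <- simulate_trial_block(casc, seed = 5L)
  expect_identical(lapply(blk1, function(x) x$trace$values),
                   lapply(blk2, function(x) x$trace$values))
})

test_that("circadian series generator matches its profile", {
  p <- unimodal_profile()
  s <- generate_circadian_series(p, noise_sd = 0, n_flies = 2L)
  expect_equal(nrow(s), 24L)          # 12 time points x 2 flies
  expect_equal(s$response, circadian_gain(p, s$ct_h))
  expect_equal(unique(s$ct_h), seq(0, 44, by = 4))

  a <- generate_circadian_series(p, noise_sd = 0.1, seed = 9L)
  b <- generate_circadian_series(p, noise_sd = 0.1, seed = 9L)
  expect_identical(a$response, b$response)
  expect_error(generate_circadian_series(p, n_flies = 0), "n_flies")
})

test_that("activity generator honours rhythmic-fraction bookkeeping", {
  spec <- activity_spec(baseline_rate = 5, dd_period_h = 24.4,
                        rhythmic_fraction = 0.69)
  recs <- generate_activity(spec, n_days_ld = 1, n_days_dd = 3,
                            n_flies = 100, seed = 4L)
  expect_equal(sum(vapply(recs, `[[`, TRUE, "rhythmic_true")), 69L)

  none <- generate_activity(activity_spec(rhythmic_fraction = 0),
                            n_days_ld = 0, n_days_dd = 3, n_flies = 5,
                            seed = 4L)
  expect_true(all(!vapply(none, `[[`, TRUE, "rhythmic_true")))

  again <- generate_activity(spec, 1, 3, n_flies = 100, seed = 4L)
  expect_identical(lapply(recs, `[[`, "counts"),
                   lapply(again, `[[`, "counts"))
  expect_error(activity_spec(lights_off_step = -2), "lights_off_step")
})

test_that("trace CSV and DAM round trips preserve the data", {
  tmp <- withr::local_tempdir()
  p <- slow_decay_ferg(noise_sd_mv = 0.05)
  tr <- generate_ferg_trace(p, gain = 1.2, seed = 2L)
  f <- file.path(tmp, "trace.csv")
  write_trace(tr, f)
  back <- read_trace(f)
  expect_equal(back$values, tr$values, tolerance = 1e-9)
  expect_equal(back$sampling_rate_hz, tr$sampling_rate_hz)
  expect_equal(back$metadata$pulse_onset_s, tr$metadata$pulse_onset_s)

  recs <- generate_activity(activity_spec(baseline_rate = 8,
                                          lights_off_step = 0.6),
                            n_days_ld = 2, n_days_dd = 3, n_flies = 3,
                            seed = 6L)
  dam <- file.path(tmp, "monitor.txt")
  write_dam(recs, dam)
  back2 <- read_dam(dam)
  expect_length(back2, 3L)
  expect_identical(back2[[1]]$counts, recs[[1]]$counts)
  expect_equal(back2[[2]]$n_days_ld, 2L)   # recovered from lights column
})
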