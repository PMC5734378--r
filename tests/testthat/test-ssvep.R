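test_that("amplitude spectrum recovers pure tones and square waves", {
  fs <- 1000
  t <- (0:(3 * fs - 1)) / fs
  tone <- ts_trace(2 * sin(2 * pi * 12 * t), fs)
  sp <- amplitude_spectrum(tone)
  expect_equal(sp$amplitude_mv[sp$frequency_hz == 12], 2, tolerance = 1e-9)
  expect_lt(max(sp$amplitude_mv[sp$frequency_hz != 12]), 1e-9)

  sq <- ts_trace(square_wave(12, t), fs)
  sps <- amplitude_spectrum(sq)
  expect_equal(sps$amplitude_mv[sps$frequency_hz == 12], 4 / pi,
               tolerance = 1e-3)
  expect_equal(sps$amplitude_mv[sps$frequency_hz == 36], 4 / (3 * pi),
               tolerance = 1e-3)
  expect_lt(sps$amplitude_mv[sps$frequency_hz == 24], 1e-9)

  zero <- ts_trace(rep(0, 2 * fs), fs)
  expect_true(all(amplitude_spectrum(zero)$amplitude_mv == 0))

  frac <- ts_trace(rep(1, 1500), fs)
  expect_error(amplitude_spectrum(frac), "integer")
})

test_that("Parseval's identity holds on noiseless cascade traces", {
  tr <- generate_ssvep_trace(flicker_stimulus(0.6, 0.4),
                             cascade_params(noise_sd_mv = 0))
  sp <- amplitude_spectrum(tr)
  a <- sp$amplitude_mv
  power <- a[1]^2 + sum(a[-1]^2) / 2
  n <- length(tr$values)
  if (n %% 2 == 0) power <- power + a[length(a)]^2 / 2  # Nyquist not doubled
  expect_equal(power, mean(tr$values^2), tolerance = 1e-6)
})

test_that("component extraction reads the exact stimulus bins", {
  cmp <- extract_components(amplitude_spectrum(
    generate_ssvep_trace(flicker_stimulus(0.5, 0.5),
                         cascade_params(noise_sd_mv = 0))))
  expect_equal(cmp$frequency_hz, c(12, 24, 3, 27, 54))
  expect_equal(cmp$component, c("1F1", "2F1", "1F2-1F1", "1F1+1F2",
                                "2F1+2F2"))
  expect_true(all(cmp$amplitude_mv >= 0))

  # noiseless cascade: amplitudes match an independent direct-DFT oracle
  tr <- generate_ssvep_trace(flicker_stimulus(0.3, 0.8),
                             cascade_params(noise_sd_mv = 0))
  cmp2 <- extract_components(amplitude_spectrum(tr))
  oracle <- vapply(cmp2$frequency_hz, function(f)
    dft_amplitude(tr$values, tr$sampling_rate_hz, f), 0)
  expect_equal(cmp2$amplitude_mv, oracle, tolerance = 1e-9)

  # DC offsets do not touch the nonzero-frequency components
  off <- ts_trace(tr$values + 11, tr$sampling_rate_hz)
  cmp3 <- extract_components(amplitude_spectrum(off))
  expect_equal(cmp3$amplitude_mv, cmp2$amplitude_mv, tolerance = 1e-9)
})

test_that("a silent medulla keeps 2F1+2F2 at the noise floor", {
  casc <- cascade_params(noise_sd_mv = 0.2, mix_weights = c(1, 0.5, 0))
  tr <- generate_ssvep_trace(flicker_stimulus(0.8, 0.8), casc, seed = 21L)
  cmp <- extract_components(amplitude_spectrum(tr))
  im <- cmp[cmp$component == "2F1+2F2", ]
  expect_lte(im$amplitude_mv, 2 * im$noise_floor_mv)
})

test_that("longer recordings tighten noisy component estimates", {
  casc <- cascade_params(noise_sd_mv = 1, mix_weights = c(1, 0, 0))
  true_amp <- (4 / pi) * 0.5 * casc$photoreceptor_gain
  err <- function(dur) {
    mean(vapply(1:10, function(s) {
      tr <- generate_ssvep_trace(flicker_stimulus(0.5, 0, duration_s = dur),
                                 casc, seed = 100L + s)
      cmp <- extract_components(amplitude_spectrum(tr))
      abs(cmp$amplitude_mv[cmp$component == "1F1"] - true_amp)
    }, 0))
  }
  expect_lt(err(9), err(1))
})

test_that("trial-block analysis uses only the last half of the protocol", {
  casc <- cascade_params(noise_sd_mv = 0)
  blk <- simulate_trial_block(casc, seed = 2L)
  expect_error(analyze_trial_block(blk[1:10]), "18")
  res <- analyze_trial_block(blk)
  expect_equal(sort(unique(res$trial[res$analyzed])), 10:18)

  # inflating the early (adaptation) trials must not move the summary
  blk_inflated <- blk
  for (i in 1:9) blk_inflated[[i]]$trace$values <-
    blk_inflated[[i]]$trace$values * 10
  expect_equal(fly_summary(analyze_trial_block(blk_inflated)),
               fly_summary(res))

  # permuting the analyzed trials leaves the fly summary unchanged
  blk_perm <- blk
  perm <- withr::with_seed(1, sample(10:18))
  blk_perm[10:18] <- blk[perm]
  for (i in 10:18) blk_perm[[i]]$stimulus$trial_index <- i
  expect_equal(fly_summary(analyze_trial_block(blk_perm)),
               fly_summary(res))

  # identical noiseless trials: the analysis-set mean equals any trial
  stim <- flicker_stimulus(0.5, 0.5, trial_index = 1L)
  one <- generate_ssvep_trace(stim, casc)
  same <- lapply(1:18, function(i) {
    st <- stim; st$trial_index <- i
    list(stimulus = st, trace = one)
  })
  res_same <- analyze_trial_block(same)
  m <- fly_summary(res_same, how = "mean")
  single <- extract_components(amplitude_spectrum(one))
  expect_equal(m$amplitude_mv[order(m$frequency_hz)],
               single$amplitude_mv[order(single$frequency_hz)],
               tolerance = 1e-12)
})

test_that("contrast-response slopes recover linear amplitudes", {
  # stage-1-only, noiseless: 1F1 amplitude is exactly k * c1
  casc <- cascade_params(photoreceptor_gain = 5, noise_sd_mv = 0,
                         mix_weights = c(1, 0, 0))
  blk <- simulate_trial_block(casc, seed = 3L)
  crf <- contrast_response(analyze_trial_block(blk))
  k <- (4 / pi) * 5
  slope_1f1 <- crf$slope[crf$component == "1F1"]
  expect_equal(slope_1f1, k, tolerance = 2e-3)

  # doubling every stage gain doubles the slope
  casc2 <- cascade_params(photoreceptor_gain = 10, noise_sd_mv = 0,
                          mix_weights = c(1, 0, 0))
  crf2 <- contrast_response(analyze_trial_block(
    simulate_trial_block(casc2, seed = 3L)))
  expect_equal(crf2$slope[crf2$component == "1F1"], 2 * slope_1f1,
               tolerance = 1e-9)

  # origin-anchored slope equals the brute-force least-squares oracle
  pts <- attr(crf, "points")
  d <- pts[pts$component == "2F1", ]
  oracle <- unname(coef(lm(amplitude_mv ~ 0 + contrast, data = d)))
  expect_equal(crf$slope[crf$component == "2F1"], oracle, tolerance = 1e-9)
})

test_that("fly summary is the maximum over analyzed trials", {
  casc <- cascade_params(noise_sd_mv = 0.1)
  res <- analyze_trial_block(simulate_trial_block(casc, seed = 8L))
  smry <- fly_summary(res)
  an <- res[res$analyzed, ]
  brute <- vapply(split(an$amplitude_mv, an$component), max, 0)
  expect_equal(smry$amplitude_mv,
               unname(brute[smry$component]), tolerance = 1e-12)
})
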