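test_that("fixed-period linear fit is the exact least-squares solution", {
  tt <- seq(0, 44, by = 4) / 24

  # constant series
  s <- circadian_series(tt, rep(2.5, length(tt)))
  f <- linear_fit_at_period(s, 1.0)
  expect_equal(f$C, 2.5, tolerance = 1e-12)
  expect_equal(f$alpha, 0, tolerance = 1e-12)
  expect_equal(f$beta, 0, tolerance = 1e-12)
  expect_equal(f$residual_ss, 0, tolerance = 1e-12)

  # exact model class: coefficients recovered at the true period
  y <- 1.0 + 0.3 * sin(2 * pi * tt / 1.05) - 0.2 * cos(2 * pi * tt / 1.05)
  f2 <- linear_fit_at_period(circadian_series(tt, y), 1.05)
  expect_equal(c(f2$C, f2$alpha, f2$beta), c(1.0, 0.3, -0.2),
               tolerance = 1e-9)

  # normal-equation oracle on random data
  withr::with_seed(11, {
    for (i in 1:20) {
      yr <- rnorm(length(tt))
      w <- runif(1, 0.4, 1.6)
      mine <- linear_fit_at_period(circadian_series(tt, yr), w)
      ora <- normal_equation_fit(tt, yr, w)
      expect_equal(c(mine$C, mine$alpha, mine$beta), unname(ora$coef),
                   tolerance = 1e-9)
      expect_equal(mine$residual_ss, ora$rss, tolerance = 1e-9)
    }
  })

  expect_error(linear_fit_at_period(circadian_series(tt[1:3], y[1:3]), 1),
               "4 samples")
  expect_error(linear_fit_at_period(
    circadian_series(rep(0.5, 6), rnorm(6)), 1), "rank")
})

test_that("residual profile localizes noiseless rhythms on the grid", {
  tt <- seq(0, 44, by = 4) / 24
  y <- 1.0 + 0.3 * sin(2 * pi * tt / 1.05) - 0.2 * cos(2 * pi * tt / 1.05)
  prof <- residual_profile(circadian_series(tt, y))
  best <- prof$omega_days[which.min(prof$residual_ss)]
  expect_equal(best, 1.05, tolerance = 1e-9)   # exact grid point
  expect_lt(min(prof$residual_ss), 1e-12)

  # 14.6 h rhythm: global minimum at the grid point nearest 0.608 days,
  # cross-checked against a dense-grid normal-equation search
  y2 <- circadian_gain(bimodal_profile(), tt * 24)
  s2 <- circadian_series(tt, y2)
  prof2 <- residual_profile(s2)
  best2 <- prof2$omega_days[which.min(prof2$residual_ss)]
  dense <- seq(0.4, 1.6, by = 1e-4)
  dense_rss <- vapply(dense, function(w) normal_equation_fit(tt, y2, w)$rss,
                      0)
  expect_equal(best2, round(dense[which.min(dense_rss)] / 0.01) * 0.01,
               tolerance = 1e-9)
  expect_equal(best2, 0.61, tolerance = 1e-9)  # nearest grid point to 14.6 h
  # the profile reports its local minima
  lm <- attr(prof2, "local_minima")
  expect_true(best2 %in% lm$omega_days)
})

test_that("pure-noise series do not fake strong rhythms", {
  tt <- seq(0, 44, by = 4) / 24
  n <- length(tt)
  ratio <- withr::with_seed(99, vapply(1:200, function(i) {
    y <- rnorm(n)
    s <- circadian_series(tt, y)
    prof <- residual_profile(s, step_days = 0.02)
    # independent oracle: normal-equation RSS minimum over the same grid
    ora <- min(vapply(prof$omega_days, function(w)
      normal_equation_fit(tt, y, w)$rss, 0))
    expect_equal(min(prof$residual_ss), ora, tolerance = 1e-9)
    min(prof$residual_ss) / sum((y - mean(y))^2)
  }, 0))
  # the best-of-grid fit absorbs part of the variance (3 linear df plus the
  # period search), but most of it must remain: no spurious strong rhythm
  expect_gt(median(ratio), 0.4)
  expect_lt(median(ratio), 1 - 3 / n)
})

test_that("refinement matches nls and never degrades the grid solution", {
  tt <- seq(0, 44, by = 4) / 24
  y <- 1.0 + 0.3 * sin(2 * pi * tt / 1.05) - 0.2 * cos(2 * pi * tt / 1.05)
  s <- circadian_series(tt, y)
  fit <- refine_fit(s, 1.05)
  expect_equal(fit$omega_days, 1.05, tolerance = 1e-6)
  expect_lt(fit$se_omega_days, 1e-4)
  expect_true(fit$converged)

  # on noisy data the variable-projection refinement agrees with nls
  withr::with_seed(5, {
    for (i in 1:10) {
      yn <- y + rnorm(length(y), sd = 0.05)
      sn <- circadian_series(tt, yn)
      res <- fit_period(sn)
      o <- stats::nls(yn ~ C + a * sin(2 * pi * tt / W) +
                        b * cos(2 * pi * tt / W),
                      start = list(C = mean(yn), a = 0.3, b = -0.2,
                                   W = res$fit$omega_days))
      expect_equal(res$fit$omega_days, coef(o)[["W"]], tolerance = 1e-5)
      expect_equal(res$fit$se_omega_days,
                   summary(o)$coefficients["W", "Std. Error"],
                   tolerance = 1e-3)
      # descent: refined residual no worse than any grid point
      expect_lte(res$fit$residual_ss, min(res$profile$residual_ss) + 1e-12)
    }
  })
})

test_that("fitted amplitude is invariant to time shifts; phase follows", {
  tt <- seq(0, 44, by = 4) / 24
  y <- 2 + 0.4 * sin(2 * pi * tt / 1.05) + 0.1 * cos(2 * pi * tt / 1.05)
  f0 <- refine_fit(circadian_series(tt, y), 1.05)
  shift <- 0.3
  f1 <- refine_fit(circadian_series(tt + shift, y), 1.05)
  expect_equal(f1$amplitude, f0$amplitude, tolerance = 1e-9)
  expect_equal((f1$phase_h - f0$phase_h) %% (f0$omega_days * 24),
               (shift * 24) %% (f0$omega_days * 24), tolerance = 1e-6)
})

test_that("period recovery works at realistic noise on the 4-h design", {
  # unimodal 25.2 h profile, 12 samples, noise 20% of amplitude, 50 seeds
  err <- vapply(1:50, function(s) {
    ser <- generate_circadian_series(unimodal_profile(), noise_sd = 0.06,
                                     seed = 1000L + s)
    abs(fit_period(ser)$fit$omega_days * 24 - 25.2)
  }, 0)
  expect_lt(median(err), 1.5)

  # bimodal 14.6 h profile lands in the half-day band
  hits <- vapply(1:50, function(s) {
    ser <- generate_circadian_series(bimodal_profile(), noise_sd = 0.06,
                                     seed = 2000L + s)
    w <- fit_period(ser)$fit$omega_days
    w >= 0.55 && w <= 0.70
  }, TRUE)
  expect_gte(mean(hits), 0.8)
})

test_that("fit_period defaults and tie-breaking are deterministic", {
  tt <- seq(0, 44, by = 4) / 24
  y <- circadian_gain(unimodal_profile(), tt * 24)
  s <- circadian_series(tt, y)
  a <- fit_period(s)
  b <- fit_period(s, 0.4, 1.6, 0.01)
  expect_identical(a$fit$omega_days, b$fit$omega_days)
  expect_equal(a$fit$omega_days, 25.2 / 24, tolerance = 1e-6)
})
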