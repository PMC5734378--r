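#' Average daily activity profile in 30-min bins
#'
#' Sums the 2-min counts of the selected days into 48 30-min bins and
#' averages across days.  LD days are aligned to ZT0 (lights-on); DD days
#' are aligned to projected CT0 assuming 24-h cycles continuing from the
#' last lights-on.
#'
#' @param record an [activity_record].
#' @param days integer day numbers to average (1-based over the whole
#'   recording, LD days first); e.g. `3` for the third LD day or
#'   `record$n_days_ld + 3` for DD day 3.
#' @return numeric vector of 48 mean counts per 30-min bin, named by bin
#'   start hour.
#' @export
rebin_profile <- function(record, days) {
  stopifnot(inherits(record, "activity_record"), length(days) >= 1L)
  n_days <- record$n_days_ld + record$n_days_dd
  if (any(days < 1 | days > n_days))
    stop("day selection outside the recording (", n_days, " days)")
  per_day <- vapply(days, function(d) {
    x <- record$counts[((d - 1L) * 720L + 1L):(d * 720L)]
    colSums(matrix(x, nrow = 15L))       # 15 x 2-min bins per 30-min bin
  }, numeric(48L))
  prof <- rowMeans(per_day)
  names(prof) <- sprintf("%.1f", seq(0, 23.5, by = 0.5))
  prof
}

#' Lomb-Scargle periodogram of locomotor activity
#'
#' Classical normalized Lomb-Scargle power over a circadian band of test
#' periods, computed on the DD (free-running) portion of the record after
#' rebinning the 2-min counts into coarser bins.  The significance
#' threshold uses the standard M-independent-frequencies approximation,
#' `z = -log(1 - (1 - alpha)^(1/M))` with M the number of scanned periods.
#'
#' @param record an [activity_record] with >= 3 DD days, or a numeric
#'   count vector (then `times_h` must be given).
#' @param period_range_h search band in hours (default c(16, 32)).
#' @param step_h period grid step (default 0.1 h).
#' @param alpha significance level (default 0.05).
#' @param bin_h analysis bin width in hours for rebinned counts (default
#'   0.5).
#' @param times_h sample times in hours when `record` is a plain vector.
#' @return object of class `ls_periodogram`: data.frame with `period_h`,
#'   `power`; attributes `threshold`, `alpha`, `peak_period_h`,
#'   `peak_power`, `degenerate`.
#' @export
lomb_scargle <- function(record, period_range_h = c(16, 32), step_h = 0.1,
                         alpha = 0.05, bin_h = 0.5, times_h = NULL) {
  if (inherits(record, "activity_record")) {
    if (record$n_days_dd < 3)
      stop("need at least 3 days of DD data for a circadian periodogram")
    dd <- record$counts[(record$n_days_ld * 720L + 1L):
                        ((record$n_days_ld + record$n_days_dd) * 720L)]
    per_bin <- as.integer(round(bin_h * 30))  # 2-min bins per analysis bin
    nb <- length(dd) %/% per_bin
    x <- colSums(matrix(dd[seq_len(nb * per_bin)], nrow = per_bin))
    t_h <- (seq_len(nb) - 0.5) * bin_h
  } else {
    x <- as.numeric(record)
    t_h <- times_h
    stopifnot(!is.null(t_h), length(t_h) == length(x))
  }
  periods <- seq(period_range_h[1], period_range_h[2], by = step_h)
  M <- length(periods)
  threshold <- -log(1 - (1 - alpha)^(1 / M))
  xm <- x - mean(x)
  ssx <- sum(xm^2)
  if (ssx == 0) {
    out <- data.frame(period_h = periods, power = rep(NA_real_, M))
    return(structure(out, threshold = threshold, alpha = alpha,
                     peak_period_h = NA_real_, peak_power = NA_real_,
                     degenerate = TRUE,
                     class = c("ls_periodogram", "data.frame")))
  }
  sigma2 <- ssx / (length(x) - 1)
  power <- vapply(periods, function(p) {
    w <- 2 * pi / p
    tau <- atan2(sum(sin(2 * w * t_h)), sum(cos(2 * w * t_h))) / (2 * w)
    ct <- cos(w * (t_h - tau)); st <- sin(w * (t_h - tau))
    (sum(xm * ct)^2 / sum(ct^2) + sum(xm * st)^2 / sum(st^2)) / (2 * sigma2)
  }, 0)
  k <- which.max(power)
  structure(data.frame(period_h = periods, power = power),
            threshold = threshold, alpha = alpha,
            peak_period_h = periods[k], peak_power = power[k],
            degenerate = FALSE,
            class = c("ls_periodogram", "data.frame"))
}

#' @export
plot.ls_periodogram <- function(x, ...) {
  graphics::plot(x$period_h, x$power, type = "l",
                 xlab = "test period (h)", ylab = "normalized power", ...)
  graphics::abline(h = attr(x, "threshold"), lty = 2)
  invisible(x)
}

#' Classify a fly as rhythmic or arrhythmic
#'
#' Rhythmic iff the peak Lomb-Scargle power within the scanned circadian
#' band exceeds the periodogram's significance threshold; the free-running
#' period is then the peak period.
#'
#' @param periodogram an `ls_periodogram`.
#' @return list with `rhythmic` (logical), `period_h` (NA unless
#'   rhythmic), `peak_power`, `threshold`, `degenerate`.
#' @export
classify_rhythmicity <- function(periodogram) {
  stopifnot(inherits(periodogram, "ls_periodogram"))
  if (isTRUE(attr(periodogram, "degenerate")))
    return(list(rhythmic = FALSE, period_h = NA_real_,
                peak_power = NA_real_,
                threshold = attr(periodogram, "threshold"),
                degenerate = TRUE))
  rhythmic <- attr(periodogram, "peak_power") > attr(periodogram, "threshold")
  list(rhythmic = rhythmic,
       period_h = if (rhythmic) attr(periodogram, "peak_period_h") else NA_real_,
       peak_power = attr(periodogram, "peak_power"),
       threshold = attr(periodogram, "threshold"),
       degenerate = FALSE)
}

#' Cohort rhythmicity summary
#'
#' Runs [lomb_scargle] and [classify_rhythmicity] per fly and summarizes
#' the fraction rhythmic and the mean free-running period among rhythmic
#' flies.
#'
#' @param records list of [activity_record]s.
#' @param ... passed to [lomb_scargle].
#' @return list with `calls` (data.frame: fly, rhythmic, period_h,
#'   peak_power), `fraction_rhythmic`, `mean_period_h` (NA if none
#'   rhythmic), `n`.
#' @export
cohort_rhythmicity <- function(records, ...) {
  calls <- do.call(rbind, lapply(records, function(r) {
    cl <- classify_rhythmicity(lomb_scargle(r, ...))
    data.frame(fly = r$fly_id, rhythmic = cl$rhythmic,
               period_h = cl$period_h, peak_power = cl$peak_power,
               stringsAsFactors = FALSE)
  }))
  per <- calls$period_h[calls$rhythmic]
  list(calls = calls,
       fraction_rhythmic = mean(calls$rhythmic),
       mean_period_h = if (length(per)) mean(per) else NA_real_,
       n = nrow(calls))
}

#' Fractional activity step after lights-off
#'
#' From an LD daily profile (48 30-min bins aligned to ZT0), computes
#' `(first 30-min bin after lights-off - mean daytime rate) / mean daytime
#' rate`, where daytime is ZT0-ZT12.
#'
#' @param profile 48-bin daily profile from [rebin_profile] (ZT-aligned),
#'   or a matrix with one profile per column (averaged first).
#' @param zt_lights_off lights-off time, default 12 h.
#' @return fractional change (e.g. 0.6 for a 60% increase).
#' @export
lights_off_step <- function(profile, zt_lights_off = 12) {
  if (is.matrix(profile)) profile <- rowMeans(profile)
  if (length(profile) != 48L || anyNA(profile))
    stop("profile must be 48 complete 30-min bins")
  k_off <- as.integer(zt_lights_off * 2) + 1L    # first bin after lights-off
  day <- mean(profile[seq_len(as.integer(zt_lights_off * 2))])
  if (day == 0) stop("zero daytime activity; step undefined")
  unname((profile[k_off] - day) / day)
}
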