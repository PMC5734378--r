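#' Locomotor activity profile specification
#'
#' Describes the expected activity of a genotype in the Drosophila activity
#' monitor: a baseline rate per 2-min bin, optional morning/evening activity
#' peaks in LD, a step increase after lights-off (nocturnality), and the
#' free-running behaviour in DD (period and the fraction of flies that
#' remain rhythmic).
#'
#' @param baseline_rate expected counts per 2-min bin, >= 0.
#' @param ld_peaks data.frame with columns `zt_h` and `height` (relative
#'   peak height, e.g. 1 doubles the rate at the peak) describing Gaussian
#'   activity peaks (SD `peak_sd_h`); NULL for none.
#' @param lights_off_step fractional rate increase applied through the dark
#'   phase (ZT12-ZT24), e.g. 0.6 for a 60% increase.
#' @param dd_period_h free-running period in hours, or `"arrhythmic"`.
#' @param rhythmic_fraction fraction of flies rhythmic in DD, in [0, 1].
#' @param dd_depth fractional modulation depth of the DD rhythm, in [0, 1).
#' @param dd_peak_ct_h circadian time of the DD activity peak.
#' @param peak_sd_h SD of the LD peak shaping Gaussians, hours.
#' @return an object of class `activity_spec`.
#' @export
activity_spec <- function(baseline_rate = 10,
                          ld_peaks = NULL,
                          lights_off_step = 0,
                          dd_period_h = 24,
                          rhythmic_fraction = 1,
                          dd_depth = 0.5,
                          dd_peak_ct_h = 12,
                          peak_sd_h = 1.5) {
  stopifnot(baseline_rate >= 0, lights_off_step >= -1,
            rhythmic_fraction >= 0, rhythmic_fraction <= 1,
            dd_depth >= 0, dd_depth < 1, peak_sd_h > 0)
  if (!identical(dd_period_h, "arrhythmic"))
    stopifnot(is.numeric(dd_period_h), dd_period_h > 0)
  if (!is.null(ld_peaks)) {
    ld_peaks <- as.data.frame(ld_peaks)
    stopifnot(all(c("zt_h", "height") %in% names(ld_peaks)))
  }
  obj <- structure(list(baseline_rate = baseline_rate, ld_peaks = ld_peaks,
                        lights_off_step = lights_off_step,
                        dd_period_h = dd_period_h,
                        rhythmic_fraction = rhythmic_fraction,
                        dd_depth = dd_depth, dd_peak_ct_h = dd_peak_ct_h,
                        peak_sd_h = peak_sd_h),
                   class = "activity_spec")
  zt <- seq(0, 24, by = 1 / 30)
  if (any(ld_rate(obj, zt) < 0) || baseline_rate * (1 - dd_depth) < 0)
    stop("activity spec implies negative expected counts")
  obj
}

# Expected counts per 2-min bin at zeitgeber time zt (hours) in LD.
ld_rate <- function(spec, zt_h) {
  zt <- zt_h %% 24
  shape <- rep.int(1, length(zt))
  pk <- spec$ld_peaks
  for (i in seq_len(NROW(pk))) {
    d <- abs(zt - pk$zt_h[i])
    d <- pmin(d, 24 - d)                       # circular distance
    shape <- shape + pk$height[i] * exp(-0.5 * (d / spec$peak_sd_h)^2)
  }
  spec$baseline_rate * shape * (1 + spec$lights_off_step * (zt >= 12))
}

# Expected counts per 2-min bin at time t_h since DD onset, for a rhythmic
# or arrhythmic fly.
dd_rate <- function(spec, t_h, rhythmic) {
  if (!rhythmic || identical(spec$dd_period_h, "arrhythmic"))
    return(rep.int(spec$baseline_rate, length(t_h)))
  spec$baseline_rate *
    (1 + spec$dd_depth *
       cos(2 * pi * (t_h - spec$dd_peak_ct_h) / spec$dd_period_h))
}

#' Binned locomotor activity record for one fly
#'
#' @param counts nonnegative integer counts, one per 2-min bin, covering
#'   `n_days_ld + n_days_dd` whole days starting at ZT0 of the first LD day.
#' @param n_days_ld,n_days_dd numbers of entrained and free-running days.
#' @param fly_id,genotype identifiers.
#' @param rhythmic_true ground-truth rhythmicity flag (NA for real data).
#' @return an object of class `activity_record`.
#' @export
activity_record <- function(counts, n_days_ld, n_days_dd, fly_id = "fly1",
                            genotype = "unknown", rhythmic_true = NA) {
  n_days <- n_days_ld + n_days_dd
  stopifnot(n_days >= 1, all(counts >= 0), all(counts == round(counts)),
            length(counts) == n_days * 720L)
  structure(list(counts = as.integer(counts), bin_min = 2L,
                 n_days_ld = as.integer(n_days_ld),
                 n_days_dd = as.integer(n_days_dd),
                 fly_id = fly_id, genotype = genotype,
                 rhythmic_true = rhythmic_true),
            class = "activity_record")
}

#' @export
print.activity_record <- function(x, ...) {
  cat(sprintf("Activity record %s (%s): %d LD + %d DD days, %d counts total\n",
              x$fly_id, x$genotype, x$n_days_ld, x$n_days_dd, sum(x$counts)))
  invisible(x)
}

#' Generate synthetic locomotor activity for a cohort
#'
#' Draws per-fly Poisson counts in 2-min bins.  During LD days the expected
#' rate follows the spec's peak shaping and lights-off step; during DD a
#' seed-deterministic subset of `floor(rhythmic_fraction * n_flies)` flies
#' (chosen by a seeded shuffle) gets sinusoidal rate modulation at
#' `dd_period_h` while the rest run at a constant rate.
#'
#' @param spec an [activity_spec].
#' @param n_days_ld,n_days_dd days of entrainment and free run
#'   (`n_days_ld + n_days_dd >= 1`).
#' @param n_flies cohort size.
#' @param seed integer RNG seed.
#' @param genotype label attached to every record.
#' @return list of [activity_record]s with ground-truth `rhythmic_true`
#'   flags.
#' @export
generate_activity <- function(spec, n_days_ld = 3, n_days_dd = 9,
                              n_flies = 1L, seed = 1L,
                              genotype = "synthetic") {
  stopifnot(inherits(spec, "activity_spec"), n_flies >= 1)
  if (n_days_ld + n_days_dd < 1) stop("need at least one recording day")
  n_rhythmic <- floor(spec$rhythmic_fraction * n_flies + 1e-9)
  shuffle <- withr::with_seed(seed, sample.int(n_flies))
  rhythmic <- seq_len(n_flies) %in% shuffle[seq_len(n_rhythmic)]
  bins_per_day <- 720L
  zt_ld <- if (n_days_ld > 0)
    (seq_len(n_days_ld * bins_per_day) - 0.5) * 2 / 60 else numeric(0)
  t_dd <- if (n_days_dd > 0)
    (seq_len(n_days_dd * bins_per_day) - 0.5) * 2 / 60 else numeric(0)
  mu_ld <- ld_rate(spec, zt_ld)
  fly_seeds <- withr::with_seed(seed + 1L,
    sample.int(.Machine$integer.max - 1L, n_flies))
  lapply(seq_len(n_flies), function(i) {
    mu_dd <- dd_rate(spec, t_dd, rhythmic[i])
    counts <- withr::with_seed(fly_seeds[i],
      stats::rpois(length(mu_ld) + length(mu_dd), c(mu_ld, mu_dd)))
    activity_record(counts, n_days_ld, n_days_dd,
                    fly_id = sprintf("fly%03d", i), genotype = genotype,
                    rhythmic_true = rhythmic[i])
  })
}

#' Write activity records in the Trikinetics DAM monitor dialect
#'
#' Tab-separated text, one row per 2-min bin: reading index, date, time,
#' status flag, a lights column (1 while lights are on), then one count
#' column per fly (channel).
#'
#' @param records list of [activity_record]s with identical day structure.
#' @param path output file.
#' @param start_date first recording date (class Date).
#' @return `path`, invisibly.
#' @export
write_dam <- function(records, path, start_date = as.Date("2026-01-01")) {
  stopifnot(length(records) >= 1L,
            all(vapply(records, inherits, TRUE, "activity_record")))
  n_ld <- records[[1]]$n_days_ld
  n_dd <- records[[1]]$n_days_dd
  n_bins <- (n_ld + n_dd) * 720L
  stopifnot(all(vapply(records, function(r)
    r$n_days_ld == n_ld && r$n_days_dd == n_dd, TRUE)))
  minute <- (seq_len(n_bins) - 1L) * 2L
  day <- minute %/% 1440L
  mod <- minute %% 1440L
  lights <- as.integer(day < n_ld & mod < 720L)
  tstr <- sprintf("%02d:%02d:00", mod %/% 60L, mod %% 60L)
  dstr <- format(start_date + day, "%d %b %y")
  counts <- vapply(records, `[[`, integer(n_bins), "counts")
  df <- data.frame(index = seq_len(n_bins), date = dstr, time = tstr,
                   status = 1L, lights = lights, counts,
                   check.names = FALSE)
  names(df)[-(1:5)] <- vapply(records, `[[`, "", "fly_id")
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a DAM-dialect monitor file written by [write_dam]
#'
#' @param path monitor file.
#' @param n_days_ld number of leading LD days (the DAM file itself encodes
#'   lights in column 5; this is used as a cross-check when present).
#' @param genotype genotype label for the resulting records.
#' @return list of [activity_record]s (ground truth flags are NA).
#' @export
read_dam <- function(path, n_days_ld = NULL, genotype = "unknown") {
  df <- utils::read.table(path, sep = "\t", stringsAsFactors = FALSE)
  n_bins <- nrow(df)
  if (n_bins %% 720L != 0L) stop("monitor file does not cover whole days")
  n_days <- n_bins %/% 720L
  lights <- df[[5]]
  ld_days <- sum(vapply(seq_len(n_days), function(d)
    any(lights[((d - 1L) * 720L + 1L):(d * 720L)] > 0), TRUE))
  if (is.null(n_days_ld)) n_days_ld <- ld_days
  lapply(seq_len(ncol(df) - 5L), function(j) {
    activity_record(df[[j + 5L]], n_days_ld, n_days - n_days_ld,
                    fly_id = paste0("ch", j), genotype = genotype)
  })
}
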