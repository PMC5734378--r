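#' Circadian gain profile
#'
#' A gain profile describes how the responsiveness of a neural stage (or a
#' measured response) is modulated over circadian time: a mesor (baseline
#' gain) plus one or two cosine components, each with an amplitude, a period
#' in hours and a peak circadian time.  A single component with a ~25 h
#' period gives a unimodal ("circadian") profile; a single component with a
#' ~14-15 h period produces roughly two peaks per 24 h day ("bimodal" in the
#' daily profile).
#'
#' The profile must be nonnegative everywhere: this is validated on a 0.1 h
#' grid over [0, 48) at construction time.
#'
#' @param mesor baseline gain, dimensionless, >= 0.
#' @param components a data.frame (or list coercible to one) with columns
#'   `amplitude` (>= 0), `period_h` (> 0) and `peak_ct_h` (in [0, 24)); zero,
#'   one or two rows.
#' @return an object of class `gain_profile`.
#' @examples
#' p <- gain_profile(1, data.frame(amplitude = 0.5, period_h = 25.2,
#'                                 peak_ct_h = 4))
#' circadian_gain(p, 4)    # 1.5 at the peak
#' @export
gain_profile <- function(mesor, components = NULL) {
  stopifnot(is.numeric(mesor), length(mesor) == 1L, is.finite(mesor),
            mesor >= 0)
  if (is.null(components)) {
    components <- data.frame(amplitude = numeric(0), period_h = numeric(0),
                             peak_ct_h = numeric(0))
  }
  components <- as.data.frame(components)
  need <- c("amplitude", "period_h", "peak_ct_h")
  if (!all(need %in% names(components)))
    stop("components must have columns amplitude, period_h, peak_ct_h")
  components <- components[, need, drop = FALSE]
  if (nrow(components) > 2L)
    stop("at most two cosine components are supported")
  if (nrow(components) > 0L) {
    stopifnot(all(is.finite(as.matrix(components))),
              all(components$amplitude >= 0),
              all(components$period_h > 0),
              all(components$peak_ct_h >= 0),
              all(components$peak_ct_h < 24))
  }
  obj <- structure(list(mesor = mesor, components = components),
                   class = "gain_profile")
  ct <- seq(0, 48 - 0.1, by = 0.1)
  if (any(circadian_gain(obj, ct) < 0))
    stop("gain profile is negative at some circadian time; ",
         "reduce component amplitudes or raise the mesor")
  obj
}

#' Evaluate a circadian gain profile
#'
#' @param profile a [gain_profile].
#' @param ct_h circadian time(s) in hours; any finite real (the cosine wraps
#'   each component at its own period).
#' @return numeric vector of gains, same length as `ct_h`.
#' @export
circadian_gain <- function(profile, ct_h) {
  stopifnot(inherits(profile, "gain_profile"), is.numeric(ct_h),
            all(is.finite(ct_h)))
  g <- rep.int(profile$mesor, length(ct_h))
  cmp <- profile$components
  for (i in seq_len(nrow(cmp))) {
    g <- g + cmp$amplitude[i] *
      cos(2 * pi * (ct_h - cmp$peak_ct_h[i]) / cmp$period_h[i])
  }
  g
}

#' @export
print.gain_profile <- function(x, ...) {
  cat("Circadian gain profile: mesor =", format(x$mesor), "\n")
  if (nrow(x$components) == 0L) {
    cat("  (constant; no rhythmic components)\n")
  } else {
    for (i in seq_len(nrow(x$components)))
      cat(sprintf("  component %d: amplitude %.3g, period %.3g h, peak CT%.3g\n",
                  i, x$components$amplitude[i], x$components$period_h[i],
                  x$components$peak_ct_h[i]))
  }
  invisible(x)
}
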