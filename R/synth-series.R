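#' Generate a circadian response series for a cohort of flies
#'
#' Samples one response value per fly per circadian time point: the profile
#' gain at that CT plus white Gaussian noise.  The default design mirrors a
#' free-running sampling scheme of every 4 h over two days in constant
#' darkness (CT0, 4, ..., 44).
#'
#' @param profile a [gain_profile] giving the ground-truth rhythm.
#' @param ct_samples circadian times in hours (nonempty); default
#'   `seq(0, 44, by = 4)`.
#' @param noise_sd response noise SD.
#' @param n_flies flies per time point, >= 1.
#' @param seed integer RNG seed.
#' @param genotype genotype label carried in the table.
#' @return a `circadian_series`: a data.frame with columns `ct_h`, `t_days`,
#'   `response`, `fly`, `genotype`; the generating profile and parameters
#'   are attached as attributes `profile`, `noise_sd` and `seed`.
#' @export
generate_circadian_series <- function(profile, ct_samples = seq(0, 44, by = 4),
                                      noise_sd = 0, n_flies = 1L, seed = 1L,
                                      genotype = "synthetic") {
  stopifnot(inherits(profile, "gain_profile"), length(ct_samples) >= 1L,
            noise_sd >= 0)
  if (n_flies < 1) stop("n_flies must be >= 1")
  ct <- rep(ct_samples, each = n_flies)
  fly <- paste0("fly", rep(seq_len(n_flies), times = length(ct_samples)))
  mu <- circadian_gain(profile, ct)
  eps <- if (noise_sd > 0) {
    withr::with_seed(seed, stats::rnorm(length(ct), sd = noise_sd))
  } else 0
  out <- data.frame(ct_h = ct, t_days = ct / 24, response = mu + eps,
                    fly = fly, genotype = genotype,
                    stringsAsFactors = FALSE)
  structure(out, profile = profile, noise_sd = noise_sd, seed = seed,
            class = c("circadian_series", "data.frame"))
}

#' Build a circadian series from explicit samples
#'
#' Assembles measured (or extracted) responses into the table understood by
#' the period-fitting routines.
#'
#' @param t_days times in days since DD onset.
#' @param response response values (e.g. SSVEP component amplitude, mV).
#' @param fly fly identifiers (recycled).
#' @param genotype genotype label.
#' @return a `circadian_series` data.frame.
#' @export
circadian_series <- function(t_days, response, fly = "fly1",
                             genotype = "unknown") {
  stopifnot(length(t_days) == length(response), length(t_days) >= 1L,
            all(is.finite(t_days)), all(is.finite(response)))
  out <- data.frame(ct_h = t_days * 24, t_days = t_days, response = response,
                    fly = rep_len(fly, length(t_days)),
                    genotype = genotype, stringsAsFactors = FALSE)
  structure(out, class = c("circadian_series", "data.frame"))
}
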