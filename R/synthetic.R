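# Seeded synthetic-data generators: noisy vulnerability observations on the
# standard air-injection pressure schedule, raw injection-time series, and
# group samples around chosen key points.

#' Default air-injection pressure schedule
#'
#' The 24-level schedule used to build the vulnerability curve: 0.00 to
#' 4.00 MPa in 0.20 MPa steps, then 4.50, 5.00 and 6.00 MPa (injection
#' indices 0 to 23).
#'
#' @return Numeric vector of 24 pressures in MPa.
#' @export
default_pressure_schedule <- function() {
  c(seq(0, 4, by = 0.2), 4.5, 5, 6)
}

#' Generate noisy vulnerability observations
#'
#' For each sample and each pressure of the schedule, draws
#' `lc = weibull_lc(params, psi) + N(0, noise_sd^2)` censored to `[0, 1]`.
#' Deterministic given the seed.
#'
#' @param params True [weibull_params()] generating the curve.
#' @param n_samples Number of stem samples (replicate curves).
#' @param pressure_schedule Injection pressures, MPa, strictly increasing;
#'   default [default_pressure_schedule()].
#' @param noise_sd Standard deviation of the additive Gaussian LC noise
#'   (fraction); 0 gives exact curve values.
#' @param seed Integer seed; required whenever `noise_sd > 0`.
#' @return Data frame with columns `sample_id`, `psi` (MPa tension), `lc`.
#' @examples
#' generate_vc_observations(weibull_params(2.23, 2.5), n_samples = 1,
#'                          noise_sd = 0)
#' @export
generate_vc_observations <- function(params, n_samples = 10L,
                                     pressure_schedule =
                                       default_pressure_schedule(),
                                     noise_sd = 0.02, seed = NULL) {
  params <- as_weibull_params(params)
  if (is.unsorted(pressure_schedule, strictly = TRUE))
    stop("`pressure_schedule` must be strictly increasing", call. = FALSE)
  if (noise_sd < 0)
    stop("`noise_sd` must be >= 0", call. = FALSE)
  if (noise_sd > 0 && is.null(seed))
    stop("`seed` is required when noise_sd > 0", call. = FALSE)
  if (!is.null(seed)) set.seed(as.integer(seed))
  n_p <- length(pressure_schedule)
  ids <- sprintf("S%02d", seq_len(n_samples))
  obs <- data.frame(
    sample_id = rep(ids, each = n_p),
    psi = rep(pressure_schedule, times = n_samples))
  lc <- weibull_lc(params, obs$psi)
  if (noise_sd > 0)
    lc <- pmin(pmax(lc + stats::rnorm(nrow(obs), 0, noise_sd), 0), 1)
  obs$lc <- lc
  obs
}

#' Generate a raw air-injection time series
#'
#' Inverts the time-ratio identity `LC_i = 1 - T/t_i`: noisy LC values are
#' drawn as in [generate_vc_observations()], capped below 1 at
#' `lc_cap` to keep conductance times finite, and converted to per-step
#' times `t_i = T / (1 - LC_i)`.  Passing the result back through
#' [lc_from_times()] reproduces the LC values exactly (up to the cap).
#'
#' @inheritParams generate_vc_observations
#' @param reference_time_s Conductance time at the flushed maximum, s.
#' @param sample_id Label for the generated series.
#' @param lc_cap Upper cap on LC before inversion (default `1 - 1e-4`);
#'   capped steps are reported in a message.
#' @return Object of class `injection_series`: list with `sample_id`,
#'   `reference_time_s`, and a data frame `steps` with `step_index`
#'   (0-based), `pressure_mpa`, `time_s`.
#' @export
generate_injection_series <- function(params, reference_time_s = 120,
                                      pressure_schedule =
                                        default_pressure_schedule(),
                                      noise_sd = 0, seed = NULL,
                                      sample_id = "S01",
                                      lc_cap = 1 - 1e-4) {
  params <- as_weibull_params(params)
  if (reference_time_s <= 0)
    stop("`reference_time_s` must be > 0", call. = FALSE)
  if (noise_sd > 0 && is.null(seed))
    stop("`seed` is required when noise_sd > 0", call. = FALSE)
  if (!is.null(seed)) set.seed(as.integer(seed))
  lc <- weibull_lc(params, pressure_schedule)
  if (noise_sd > 0)
    lc <- pmin(pmax(lc + stats::rnorm(length(lc), 0, noise_sd), 0), 1)
  capped <- lc > lc_cap
  if (any(capped))
    message(sum(capped), " step(s) capped at LC = ", lc_cap,
            " to keep conductance times finite")
  lc <- pmin(lc, lc_cap)
  structure(
    list(sample_id = sample_id,
         reference_time_s = reference_time_s,
         steps = data.frame(
           step_index = seq_along(pressure_schedule) - 1L,
           pressure_mpa = pressure_schedule,
           time_s = reference_time_s / (1 - lc))),
    class = "injection_series")
}

#' @export
print.injection_series <- function(x, ...) {
  cat(sprintf("Air-injection series '%s': %d steps, reference time %g s\n",
              x$sample_id, nrow(x$steps), x$reference_time_s))
  invisible(x)
}

#' Generate a group of measurements around a centre
#'
#' Draws `n` Gaussian measurements about `center`; emulates the per-group
#' stem water potential or LC samples (n = 10, mean +/- SE) used to
#' validate calculated key points.
#'
#' @param center Group mean (MPa tension or LC fraction).
#' @param sd Between-measurement standard deviation, `>= 0`.
#' @param n Group size, at least 2.
#' @param seed Integer seed; required when `sd > 0`.
#' @param label Optional group label, attached as the `"label"` attribute.
#' @return Numeric vector of length `n`.
#' @export
generate_group_samples <- function(center, sd, n = 10L, seed = NULL,
                                   label = NULL) {
  if (sd < 0) stop("`sd` must be >= 0", call. = FALSE)
  if (n < 2L) stop("`n` must be at least 2", call. = FALSE)
  if (sd > 0 && is.null(seed))
    stop("`seed` is required when sd > 0", call. = FALSE)
  if (!is.null(seed)) set.seed(as.integer(seed))
  x <- if (sd == 0) rep(center, n) else stats::rnorm(n, center, sd)
  if (!is.null(label)) attr(x, "label") <- label
  x
}
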