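# Seeded synthetic weather and phenology generator. Daily means follow a
# sinusoidal annual cycle plus stationary AR(1) noise (multi-day warm/cold
# spells are what trigger realistic chill, deacclimation and freeze-event
# dynamics); tmin/tmax sit a constant diurnal half-range below/above the
# daily mean. Observations are model predictions plus rounded Gaussian
# noise. All randomness is governed by the spec's integer seed (R's
# default Mersenne-Twister generator).

#' Construct a synthetic climate specification
#'
#' @param annual_mean_c Annual mean temperature, degC.
#' @param seasonal_amplitude_c Half peak-to-trough seasonal amplitude, degC
#'   (>= 0). Default 12 degC, a cool-temperate continental cycle.
#' @param coldest_day_doy Day of year of the coldest mean temperature
#'   (default 15, mid-January).
#' @param diurnal_range_c Constant tmax - tmin, degC (default 8).
#' @param ar1_rho Lag-1 autocorrelation of daily noise in \[0, 1)
#'   (default 0.7, multi-day synoptic spells).
#' @param noise_sd_c Stationary standard deviation of daily noise, degC
#'   (default 3).
#' @param latitude_deg Site latitude (default 45 N).
#' @param n_years Number of complete dormant seasons to cover (default 10).
#' @param seed Integer seed fixing all randomness.
#' @param start_year First July's calendar year (default 2000).
#' @return A `climate_spec` list.
#' @export
climate_spec <- function(annual_mean_c, seasonal_amplitude_c = 12,
                         coldest_day_doy = 15, diurnal_range_c = 8,
                         ar1_rho = 0.7, noise_sd_c = 3, latitude_deg = 45,
                         n_years = 10, seed = 1, start_year = 2000) {
  stopifnot(seasonal_amplitude_c >= 0, noise_sd_c >= 0,
            ar1_rho >= 0, ar1_rho < 1, diurnal_range_c >= 0,
            n_years >= 1, abs(latitude_deg) <= 66.6)
  structure(list(annual_mean_c = annual_mean_c,
                 seasonal_amplitude_c = seasonal_amplitude_c,
                 coldest_day_doy = coldest_day_doy,
                 diurnal_range_c = diurnal_range_c,
                 ar1_rho = ar1_rho, noise_sd_c = noise_sd_c,
                 latitude_deg = latitude_deg, n_years = n_years,
                 seed = as.integer(seed), start_year = start_year),
            class = "climate_spec")
}

# Evaluate code under a fixed seed without disturbing the caller's RNG.
with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  force(code)
}

# Deterministic part of the daily mean temperature for a day of year.
.seasonal_mean <- function(spec, doy) {
  spec$annual_mean_c - spec$seasonal_amplitude_c *
    cos(2 * pi * (doy - spec$coldest_day_doy) / 365)
}

#' Generate synthetic daily weather
#'
#' Produces a `site_series` covering `n_years` complete dormant seasons
#' (1 July `start_year` through 30 June `start_year + n_years`). The daily
#' mean is the seasonal sinusoid (coldest at `coldest_day_doy`) plus AR(1)
#' noise with stationary standard deviation `noise_sd_c`;
#' `tmin = mean - diurnal_range/2`, `tmax = mean + diurnal_range/2`.
#' Deterministic under `spec$seed`.
#'
#' @param spec A `climate_spec`.
#' @param site_id Site identifier for the emitted series.
#' @return A `site_series`.
#' @export
generate_weather <- function(spec, site_id = "synthetic") {
  stopifnot(inherits(spec, "climate_spec"))
  dates <- seq(as.Date(sprintf("%d-07-01", spec$start_year)),
               as.Date(sprintf("%d-06-30", spec$start_year + spec$n_years)),
               by = "day")
  doy <- as.POSIXlt(dates)$yday + 1
  det <- .seasonal_mean(spec, doy)
  n <- length(dates)
  noise <- with_seed(spec$seed, {
    e <- numeric(n)
    innov_sd <- spec$noise_sd_c * sqrt(1 - spec$ar1_rho^2)
    e[1] <- stats::rnorm(1, 0, spec$noise_sd_c)
    innov <- stats::rnorm(n - 1, 0, innov_sd)
    for (i in 2:n) e[i] <- spec$ar1_rho * e[i - 1] + innov[i - 1]
    e
  })
  mean_c <- det + if (spec$noise_sd_c > 0) noise else 0
  site_series(data.frame(date = dates,
                         tmin_c = mean_c - spec$diurnal_range_c / 2,
                         tmax_c = mean_c + spec$diurnal_range_c / 2),
              site_id = site_id, latitude_deg = spec$latitude_deg)
}

#' Calibrate a climate spec to a target mean dormant-season temperature
#'
#' Shifts `annual_mean_c` so that the deterministic (noise-free) MDST over
#' 1 Nov - 30 Apr equals the target; closed-form up to direct summation of
#' the sinusoid over the window (noise has zero mean, so the expected MDST
#' matches the target).
#'
#' @param target_mdst_c Target MDST, degC.
#' @param template A `climate_spec` providing all other fields.
#' @return A new `climate_spec` with adjusted `annual_mean_c`.
#' @export
calibrate_spec_for_mdst <- function(target_mdst_c, template) {
  stopifnot(inherits(template, "climate_spec"))
  window <- seq(as.Date("2001-11-01"), as.Date("2002-04-30"), by = "day")
  doy <- as.POSIXlt(window)$yday + 1
  # MDST(annual_mean) = annual_mean - amplitude * mean(cos term)
  k <- mean(.seasonal_mean(template, doy) - template$annual_mean_c)
  mean_new <- target_mdst_c - k
  if (!is.finite(mean_new) || abs(mean_new) > 60) {
    stop("target MDST unreachable within plausible temperature bounds")
  }
  out <- template
  out$annual_mean_c <- mean_new
  out
}

#' Generate noisy synthetic phenology observations from predictions
#'
#' Observed day of year equals the predicted day of year plus rounded
#' Gaussian noise; FAILED predictions are skipped. Deterministic under
#' `seed`.
#'
#' @param predictions data.frame from `predict_budbreak_many()`-style
#'   output (`site_id`, `cultivar`, `season_year`, `convention`,
#'   `doy_fdc`, `status`), or any data.frame with those columns.
#' @param obs_noise_sd_days Observation noise standard deviation, days.
#' @param seed Integer seed.
#' @param doy_col Which prediction column to perturb (default `doy_fdc`).
#' @return data.frame with `site_id`, `cultivar`, `season_year`,
#'   `observed_doy`, `convention`.
#' @export
generate_observations <- function(predictions, obs_noise_sd_days = 3,
                                  seed = 1, doy_col = "doy_fdc") {
  stopifnot(obs_noise_sd_days >= 0)
  keep <- predictions$status == "OK" & !is.na(predictions[[doy_col]])
  p <- predictions[keep, , drop = FALSE]
  noise <- with_seed(seed, round(stats::rnorm(nrow(p), 0, obs_noise_sd_days)))
  data.frame(site_id = p$site_id, cultivar = p$cultivar,
             season_year = p$season_year,
             observed_doy = as.integer(p[[doy_col]] + noise),
             convention = p$convention)
}
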