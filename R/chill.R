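# Dynamic Model rate constants (two-intermediate precursor/portion process),
# as published for the canonical chill-portion formulation. Temperatures are
# converted to Kelvin inside the step; the API is degC-only.
dynamic_model_constants <- list(
  slp = 1.6,         # slope of the precursor formation equilibrium
  tetmlt = 277,      # transition temperature (K)
  a0 = 139500,       # pre-exponential, formation
  a1 = 2.567e18,     # pre-exponential, destruction
  e0 = 4153.5,       # activation energy, formation (K)
  e1 = 12888.8       # activation energy, destruction (K)
)

#' One hourly step of the Dynamic Model
#'
#' Advances the two-step precursor/portion process by one hour at the given
#' temperature. The precursor pool `x` relaxes toward its temperature-
#' dependent equilibrium; when it reaches 1, a fraction (set by the
#' temperature-dependent transfer probability) is banked irreversibly as
#' chill portions and removed from the pool.
#'
#' @param state List with `precursor_x` (>= 0) and `portions` (>= 0).
#' @param hourly_temp_c Temperature for the hour, degC.
#' @return Updated state list.
#' @export
dynamic_model_step <- function(state, hourly_temp_c) {
  stopifnot(is.finite(hourly_temp_c))
  k <- dynamic_model_constants
  TK <- hourly_temp_c + 273
  sr <- exp(k$slp * k$tetmlt * (TK - k$tetmlt) / TK)
  xi <- sr / (1 + sr)
  xs <- (k$a0 / k$a1) * exp((k$e1 - k$e0) / TK)
  ak1 <- k$a1 * exp(-k$e1 / TK)
  x <- xs - (xs - state$precursor_x) * exp(-ak1)
  portions <- state$portions
  if (x >= 1) {
    portions <- portions + x * xi
    x <- x * (1 - xi)
  }
  list(precursor_x = x, portions = portions)
}

# Vectorised hourly chill-portion accumulation (same recursion as
# dynamic_model_step, loop kept scalar-minimal for speed). `shift_c` moves
# the temperature response: the submodel is evaluated on (T - shift_c).
chill_portions_hourly <- function(temp_c, shift_c = 0) {
  k <- dynamic_model_constants
  TK <- temp_c - shift_c + 273
  sr <- exp(k$slp * k$tetmlt * (TK - k$tetmlt) / TK)
  xi <- sr / (1 + sr)
  xs <- (k$a0 / k$a1) * exp((k$e1 - k$e0) / TK)
  ek <- exp(-k$a1 * exp(-k$e1 / TK))
  n <- length(temp_c)
  delt <- numeric(n)
  x <- 0
  for (i in seq_len(n)) {
    x <- xs[i] - (xs[i] - x) * ek[i]
    if (x >= 1) {
      delt[i] <- x * xi[i]
      x <- x * (1 - xi[i])
    }
  }
  cumsum(delt)
}

#' Accumulate Dynamic Model chill portions over a season
#'
#' Runs the chill submodel over an hourly temperature series starting 1 July
#' and reports the cumulative portions at the end of each day. An optional
#' phase shift `shift_c` displaces the temperature response: with shift `s`
#' the submodel is evaluated on `T - s`, so the constant-temperature optimum
#' moves from its native position (about 7.5 degC) to native `+ s`.
#'
#' @param hourly data.frame from [hourly_temperatures()] (`date`, `hour`,
#'   `temp_c`) covering consecutive days.
#' @param shift_c Phase shift in degC (the paper-style experiments use
#'   -6..+6).
#' @return A `chill_series`: data.frame with `date` and
#'   `chill_portions_cum` (non-decreasing, one row per day).
#' @export
accumulate_chill <- function(hourly, shift_c = 0) {
  stopifnot(is.data.frame(hourly), all(c("date", "hour", "temp_c") %in% names(hourly)))
  days <- unique(hourly$date)
  if (length(days) > 1 && any(diff(days) != 1)) {
    stop("hourly series must cover consecutive days")
  }
  if (nrow(hourly) != 24L * length(days)) {
    stop("hourly series must have exactly 24 values per day")
  }
  cum <- chill_portions_hourly(hourly$temp_c, shift_c = shift_c)
  out <- data.frame(date = days,
                    chill_portions_cum = cum[seq(24, length(cum), by = 24)])
  class(out) <- c("chill_series", "data.frame")
  out
}

#' Chill portions per season from daily weather
#'
#' Convenience wrapper: interpolates hourly temperatures for a dormant
#' season's records and accumulates chill portions from 1 July.
#'
#' @param season A `dormant_season`.
#' @param shift_c Phase shift in degC, see [accumulate_chill()].
#' @return A `chill_series` aligned to the season's dates.
#' @export
chill_for_season <- function(season, shift_c = 0) {
  stopifnot(inherits(season, "dormant_season"))
  hr <- hourly_temperatures(season$records, season$latitude_deg)
  accumulate_chill(hr, shift_c = shift_c)
}

#' Constant-temperature chill response sweep
#'
#' Runs the chill submodel on constant hourly temperature series across a
#' grid and returns total portions per temperature; used to locate the
#' temperature response optimum (natively about 7.5 degC) and its phase-
#' shifted displacements.
#'
#' @param grid Temperatures to evaluate (degC).
#' @param days Length of each constant series in days.
#' @param shift_c Phase shift in degC.
#' @return data.frame with `temp_c` and `portions`.
#' @export
chill_response_sweep <- function(grid = seq(0, 16, by = 0.1), days = 60,
                                 shift_c = 0) {
  n <- days * 24L
  portions <- vapply(grid, function(tc) {
    cum <- chill_portions_hourly(rep(tc, n), shift_c = shift_c)
    cum[n]
  }, numeric(1))
  data.frame(temp_c = grid, portions = portions)
}

#' Temperature of maximal chill accumulation
#'
#' @inheritParams chill_response_sweep
#' @return The grid temperature with maximal total portions (degC).
#' @export
chill_optimum <- function(grid = seq(0, 16, by = 0.1), days = 60, shift_c = 0) {
  sw <- chill_response_sweep(grid = grid, days = days, shift_c = shift_c)
  sw$temp_c[which.max(sw$portions)]
}
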