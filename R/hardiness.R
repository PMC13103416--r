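# Cold-hardiness engine: daily integration of acclimation (hardiness gain,
# driven by cold temperatures and gated by chill state and remaining
# capacity) and deacclimation (hardiness loss, a monotone temperature
# response scaled by the chill-dependent deacclimation potential).
#
# Hardiness is on the lethal-temperature scale (degC): more negative =
# hardier. The daily update is
#   CH(d) = CH(d-1) - gain(d) + loss(d)
# clamped at the cultivar x percentile maximum-hardiness bound, and in
# bounded mode additionally capped at the spring floor (the minimum
# hardiness of growing green tissue).
#
# The original fitted parameter values and exact supplement equations were
# not available when this package was written; the packaged table
# (inst/extdata/nyus1_parameters_synthetic.csv) is a synthetic stand-in
# whose values were chosen once to reproduce the documented qualitative
# behavior of the three cultivars (see the methods vignette).

.cultivars <- c("Cabernet-Sauvignon", "Riesling", "Concord")
.percentiles <- c(10, 50, 90)
.param_names <- c("ch_max", "ch_init", "acc_rate", "acc_t0", "acc_t1",
                  "acc_tk", "deacc_rate", "deacc_mid", "deacc_b",
                  "dp_mid", "dp_slope")

#' Load the cultivar x percentile parameter table
#'
#' Reads the long-format parameter CSV (columns `cultivar`, `percentile`,
#' `param_name`, `value`, `source`) and checks that all three cultivars x
#' three percentiles are fully populated and that every maximum-hardiness
#' bound is negative.
#'
#' @param path CSV path; defaults to the packaged synthetic table.
#' @return The validated long-format data.frame.
#' @export
load_cultivar_params <- function(path = system.file("extdata",
                                                    "nyus1_parameters_synthetic.csv",
                                                    package = "budfreeze")) {
  tbl <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("cultivar", "percentile", "param_name", "value")
  stopifnot(all(need %in% names(tbl)))
  for (cv in .cultivars) {
    for (p in .percentiles) {
      sub <- tbl[tbl$cultivar == cv & tbl$percentile == p, ]
      miss <- setdiff(.param_names, sub$param_name)
      if (length(miss) > 0) {
        stop(sprintf("parameter table incomplete for %s p%d: missing %s",
                     cv, p, paste(miss, collapse = ", ")))
      }
      if (sub$value[sub$param_name == "ch_max"] >= 0) {
        stop(sprintf("ch_max must be < 0 (%s p%d)", cv, p))
      }
    }
  }
  tbl
}

#' Extract one percentile's parameter set
#'
#' @param tbl Long-format table from [load_cultivar_params()].
#' @param cultivar One of Cabernet-Sauvignon, Riesling, Concord.
#' @param percentile 10, 50 or 90.
#' @return Named list of parameter values.
#' @export
cultivar_params <- function(tbl, cultivar, percentile) {
  if (!cultivar %in% .cultivars) stop("unknown cultivar: ", cultivar)
  if (!percentile %in% .percentiles) stop("unknown percentile: ", percentile)
  sub <- tbl[tbl$cultivar == cultivar & tbl$percentile == percentile, ]
  p <- as.list(stats::setNames(sub$value, sub$param_name))
  p$cultivar <- cultivar
  p$percentile <- percentile
  p
}

#' Deacclimation potential: logistic chill response in \[0, 1\]
#'
#' Fraction of the full deacclimation rate realized at a given chill level.
#' Near 0 at zero chill (deep dormancy: warm spells cause no hardiness
#' loss), saturating toward 1 once chilling is satisfied.
#'
#' @param params Parameter set from [cultivar_params()].
#' @param chill_portions Accumulated chill portions (>= 0), vectorised.
#' @return Values in \[0, 1\], non-decreasing in chill.
#' @export
deacclimation_potential <- function(params, chill_portions) {
  stopifnot(all(chill_portions >= 0))
  stats::plogis(params$dp_slope * (chill_portions - params$dp_mid))
}

#' Daily acclimation gain (degC of hardiness gained, >= 0)
#'
#' Gain is proportional to how far the daily minimum temperature sits below
#' a chill-dependent acclimation threshold (the threshold declines as chill
#' accumulates, so progressively colder nights are needed), and to the
#' remaining hardening capacity, which vanishes as the bud approaches its
#' maximum-hardiness bound.
#'
#' @param params Parameter set.
#' @param chill_portions Accumulated chill portions.
#' @param tmin_c Daily minimum temperature, degC.
#' @param ch_prev_c Previous day's hardiness, degC.
#' @return Gain in degC (>= 0).
#' @export
acclimation_gain <- function(params, chill_portions, tmin_c, ch_prev_c) {
  thr <- params$acc_t0 -
    params$acc_t1 * chill_portions / (chill_portions + params$acc_tk)
  drive <- pmax(0, thr - tmin_c)
  capacity <- pmin(1, pmax(0, (ch_prev_c - params$ch_max) / (0 - params$ch_max)))
  params$acc_rate * drive * capacity
}

#' Daily deacclimation loss (degC of hardiness lost, >= 0)
#'
#' A monotone logistic temperature response evaluated at the daily minimum
#' and maximum temperatures (two half-day contributions, averaged), scaled
#' by the deacclimation potential — so no hardiness is lost before chilling
#' accumulates, regardless of warmth.
#'
#' @param params Parameter set.
#' @param chill_portions Accumulated chill portions.
#' @param tmin_c,tmax_c Daily minimum / maximum temperature, degC.
#' @return Loss in degC (>= 0).
#' @export
deacclimation_loss <- function(params, chill_portions, tmin_c, tmax_c) {
  stopifnot(all(tmin_c <= tmax_c))
  rate <- function(tc) {
    params$deacc_rate * stats::plogis(params$deacc_b * (tc - params$deacc_mid))
  }
  pot <- deacclimation_potential(params, chill_portions)
  pot * (rate(tmin_c) + rate(tmax_c)) / 2
}

#' Default spring floor configuration
#'
#' Per-percentile minimum cold hardiness of growing green tissue (degC),
#' used to cap bounded-mode trajectories in spring. Defaults sit inside the
#' 0 to -4 degC range spanned by published controlled freeze tests on
#' newly emerged shoots; they are configuration, not fitted values.
#'
#' @param floor10,floor50,floor90 Floors for the 10th/50th/90th percentile.
#' @return Named list with `p10`, `p50`, `p90`.
#' @export
spring_floor <- function(floor10 = -1, floor50 = -2, floor90 = -3) {
  if (!(floor10 >= floor50 && floor50 >= floor90)) {
    stop("spring floors must satisfy floor10 >= floor50 >= floor90")
  }
  list(p10 = floor10, p50 = floor50, p90 = floor90)
}

.floor_for <- function(floor, percentile) {
  floor[[paste0("p", percentile)]]
}

#' Simulate one percentile's cold-hardiness trajectory over a season
#'
#' Integrates the daily update from the parameterized initial hardiness on
#' the season start date (1 July). In `projected` mode the trajectory may
#' rise freely into positive values (used for budbreak extraction); in
#' `bounded` mode it is capped at the spring floor (used for damage and
#' risk analyses).
#'
#' @param params Parameter set from [cultivar_params()].
#' @param season A `dormant_season`.
#' @param chill `chill_series` aligned to the season's dates.
#' @param mode `"projected"` or `"bounded"`.
#' @param floor Spring floor configuration, see [spring_floor()].
#' @return data.frame with `date`, `ch_c`, `gain_c`, `loss_c` (the raw
#'   pre-clamp increments, so `ch_raw(d) - ch(d-1) == loss - gain` exactly).
#' @export
simulate_hardiness <- function(params, season, chill,
                               mode = c("projected", "bounded"),
                               floor = spring_floor()) {
  mode <- match.arg(mode)
  d <- season$records
  if (nrow(d) != nrow(chill) || any(d$date != chill$date)) {
    stop("chill series is not aligned to the season's weather")
  }
  n <- nrow(d)
  ch <- numeric(n)
  gain <- numeric(n)
  loss <- numeric(n)
  cap <- if (mode == "bounded") .floor_for(floor, params$percentile) else Inf
  prev <- params$ch_init
  for (i in seq_len(n)) {
    cp <- chill$chill_portions_cum[i]
    gain[i] <- acclimation_gain(params, cp, d$tmin_c[i], prev)
    loss[i] <- deacclimation_loss(params, cp, d$tmin_c[i], d$tmax_c[i])
    x <- prev - gain[i] + loss[i]
    x <- max(x, params$ch_max)
    x <- min(x, cap)
    ch[i] <- x
    prev <- x
  }
  data.frame(date = d$date, ch_c = ch, gain_c = gain, loss_c = loss)
}

#' Simulate all three percentiles for a cultivar
#'
#' Runs [simulate_hardiness()] for the 10th, 50th and 90th percentiles and
#' enforces the per-day ordering invariant `ch10 >= ch50 >= ch90` (the 10th
#' percentile is the least hardy and is damaged first); a violation
#' indicates a corrupt parameter table and is a hard error.
#'
#' @param cultivar Cultivar name.
#' @param season A `dormant_season`.
#' @param chill Aligned `chill_series`.
#' @param mode `"projected"` or `"bounded"`.
#' @param floor Spring floor configuration.
#' @param params_tbl Long-format parameter table.
#' @return A `hardiness_trajectory`: data.frame with `date`, `tmin_c`,
#'   `tmax_c`, `chill_portions_cum`, `ch10_c`, `ch50_c`, `ch90_c`;
#'   attributes `mode` and `cultivar`.
#' @export
simulate_all_percentiles <- function(cultivar, season, chill,
                                     mode = c("projected", "bounded"),
                                     floor = spring_floor(),
                                     params_tbl = load_cultivar_params()) {
  mode <- match.arg(mode)
  runs <- lapply(.percentiles, function(p) {
    simulate_hardiness(cultivar_params(params_tbl, cultivar, p),
                       season, chill, mode = mode, floor = floor)
  })
  out <- data.frame(date = season$records$date,
                    tmin_c = season$records$tmin_c,
                    tmax_c = season$records$tmax_c,
                    chill_portions_cum = chill$chill_portions_cum,
                    ch10_c = runs[[1]]$ch_c,
                    ch50_c = runs[[2]]$ch_c,
                    ch90_c = runs[[3]]$ch_c)
  bad <- which(out$ch10_c < out$ch50_c - 1e-9 | out$ch50_c < out$ch90_c - 1e-9)
  if (length(bad) > 0) {
    stop(sprintf("percentile ordering violated on %s (parameter table bug?)",
                 format(out$date[bad[1]])))
  }
  structure(out, mode = mode, cultivar = cultivar,
            season_year = season$season_year, site_id = season$site_id,
            class = c("hardiness_trajectory", "data.frame"))
}
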