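# Freeze-damage detection and correction. A freeze event occurs on a day
# whose minimum air temperature drops strictly below the predicted
# 10th-percentile hardiness. Percent damage of the existing population is a
# piecewise-linear interpolation along the quantile curve through
# (10, CH10), (50, CH50), (90, CH90); the survivor population's percentiles
# are then re-read from that curve at the post-event quantile positions
# (a survivor at percentile p of the new population sat at
# d + p * (100 - d) / 100 of the old one).

#' Detect a freeze event
#'
#' TRUE iff the daily minimum temperature is strictly below the
#' 10th-percentile hardiness. Equality is no event: at `tmin == ch10`
#' exactly the nominal 10% tail is at its lethal temperature, which the
#' percentile representation already carries.
#'
#' @param tmin_c Daily minimum temperature, degC.
#' @param ch10_c 10th-percentile hardiness, degC.
#' @return Logical (vectorised).
#' @export
detect_freeze_event <- function(tmin_c, ch10_c) {
  tmin_c < ch10_c
}

#' Percent of the existing bud population damaged by a freeze
#'
#' Linear interpolation between percentile anchors: when `tmin` lies
#' between the 10th- and 50th-percentile hardiness,
#' `10 + (50 - 10) / (CH50 - CH10) * (Tmin - CH10)`; below the
#' 50th-percentile value, `50 + (90 - 50) / (CH90 - CH50) * (Tmin - CH50)`
#' capped at 90. The two bands agree exactly at `tmin == CH50`.
#'
#' @param tmin_c Daily minimum temperature (must satisfy `tmin_c <= ch10_c`).
#' @param ch10_c,ch50_c,ch90_c Pre-event percentile hardiness values
#'   (ordered `ch10 >= ch50 >= ch90`, strictly separated).
#' @return Percent damage in \[10, 90\].
#' @export
percent_damage <- function(tmin_c, ch10_c, ch50_c, ch90_c) {
  if (!(ch10_c >= ch50_c && ch50_c >= ch90_c)) {
    stop("percentile ordering violated: need ch10 >= ch50 >= ch90")
  }
  if (ch10_c == ch50_c || ch50_c == ch90_c) {
    stop("degenerate percentile spread (equal values): cannot interpolate")
  }
  if (tmin_c > ch10_c) {
    stop("percent_damage requires tmin_c <= ch10_c (no freeze event)")
  }
  if (tmin_c >= ch50_c) {
    10 + (50 - 10) / (ch50_c - ch10_c) * (tmin_c - ch10_c)
  } else {
    min(50 + (90 - 50) / (ch90_c - ch50_c) * (tmin_c - ch50_c), 90)
  }
}

#' Adjust hardiness percentiles for the surviving population
#'
#' After `d` percent of the existing population is killed, the survivor
#' population's percentile p corresponds to position `d + p (100 - d) / 100`
#' on the old quantile curve; the new CH10/CH50/CH90 linearly
#' interpolate/extrapolate the old curve at those positions:
#' \deqn{CH50^* = CH50 + (CH90 - CH50)/40 ((100 - d) 0.5 + d - 50)}
#' \deqn{CH90^* = CH90 + (CH90 - CH50)/40 ((100 - d) 0.9 + d - 90)}
#' and CH10* uses the 10-50 segment slope when `d <= 50`, the 10-90 chord
#' when `d > 50`. Survivors are always at least as hardy: each adjusted
#' value is `<=` its pre-event counterpart, and ordering is preserved.
#'
#' @param ch10_c,ch50_c,ch90_c Pre-event percentile values (ordered).
#' @param pct_damage Percent damage `d` in \[0, 90\].
#' @return List with `ch10_adj_c`, `ch50_adj_c`, `ch90_adj_c`.
#' @export
adjust_percentiles <- function(ch10_c, ch50_c, ch90_c, pct_damage) {
  if (!(ch10_c >= ch50_c && ch50_c >= ch90_c)) {
    stop("percentile ordering violated: need ch10 >= ch50 >= ch90")
  }
  d <- pct_damage
  if (!is.finite(d) || d < 0 || d > 90) {
    stop("pct_damage must be in [0, 90]")
  }
  ch50_adj <- ch50_c + (ch90_c - ch50_c) / 40 * ((100 - d) * 0.5 + d - 50)
  ch90_adj <- ch90_c + (ch90_c - ch50_c) / 40 * ((100 - d) * 0.9 + d - 90)
  ch10_adj <- if (d <= 50) {
    ch10_c + (ch50_c - ch10_c) / 40 * ((100 - d) * 0.1 + d - 10)
  } else {
    ch10_c + (ch90_c - ch10_c) / 80 * ((100 - d) * 0.1 + d - 10)
  }
  list(ch10_adj_c = ch10_adj, ch50_adj_c = ch50_adj, ch90_adj_c = ch90_adj)
}

#' Season simulation with freeze-damage detection and correction
#'
#' Integrates the three percentile trajectories day by day in both
#' projected and bounded (spring-floored) variants. On each day where the
#' minimum temperature drops below the bounded 10th-percentile prediction,
#' percent damage is computed from that day's pre-event bounded values, all
#' percentile states (both variants) are replaced by their survivor-adjusted
#' values, and integration continues from the adjusted states. The initial
#' budbreak prediction comes from the unadjusted projected trajectory; the
#' freeze-damage-corrected (FDC) prediction from the adjusted one. Because
#' adjustment only ever deepens hardiness, events after the FDC crossing
#' cannot move it; they are still recorded for risk analyses.
#'
#' @param cultivar Cultivar name.
#' @param season A `dormant_season`.
#' @param chill Aligned `chill_series`.
#' @param convention Observation convention (sets the budbreak threshold).
#' @param floor Spring floor configuration.
#' @param params_tbl Long-format parameter table.
#' @param damage_correction If FALSE, no adjustments are applied (events are
#'   still detected and recorded; FDC equals the initial prediction).
#' @return List with `trajectory` (per-day data.frame: weather, chill,
#'   adjusted projected `ch10_c/ch50_c/ch90_c` for budbreak, adjusted
#'   bounded `ch10_bnd_c/ch50_bnd_c/ch90_bnd_c` for risk, and the
#'   unadjusted projected `ch50_uncorrected_c`), `events` (one row per
#'   freeze event), `budbreak_initial`, `budbreak_fdc`.
#' @export
simulate_with_damage <- function(cultivar, season, chill,
                                 convention = "BBCH07_50",
                                 floor = spring_floor(),
                                 params_tbl = load_cultivar_params(),
                                 damage_correction = TRUE) {
  d <- season$records
  if (nrow(d) != nrow(chill) || any(d$date != chill$date)) {
    stop("chill series is not aligned to the season's weather")
  }
  n <- nrow(d)
  params <- lapply(.percentiles, function(p) cultivar_params(params_tbl, cultivar, p))
  floors <- vapply(.percentiles, function(p) .floor_for(floor, p), numeric(1))
  chmax <- vapply(params, function(p) p$ch_max, numeric(1))
  init <- vapply(params, function(p) p$ch_init, numeric(1))

  proj <- matrix(NA_real_, n, 3)   # adjusted projected
  bnd <- matrix(NA_real_, n, 3)    # adjusted bounded
  raw <- matrix(NA_real_, n, 3)    # unadjusted projected
  prev_proj <- init; prev_bnd <- init; prev_raw <- init
  events <- list()
  surv <- 1

  step1 <- function(prev, k, i, cap) {
    cp <- chill$chill_portions_cum[i]
    g <- acclimation_gain(params[[k]], cp, d$tmin_c[i], prev)
    l <- deacclimation_loss(params[[k]], cp, d$tmin_c[i], d$tmax_c[i])
    min(max(prev - g + l, chmax[k]), cap)
  }

  for (i in seq_len(n)) {
    for (k in 1:3) {
      proj[i, k] <- step1(prev_proj[k], k, i, Inf)
      bnd[i, k] <- step1(prev_bnd[k], k, i, floors[k])
      raw[i, k] <- step1(prev_raw[k], k, i, Inf)
    }
    if (damage_correction && detect_freeze_event(d$tmin_c[i], bnd[i, 1])) {
      pct <- percent_damage(d$tmin_c[i], bnd[i, 1], bnd[i, 2], bnd[i, 3])
      surv <- surv * (1 - pct / 100)
      events[[length(events) + 1]] <- data.frame(
        date = d$date[i], tmin_c = d$tmin_c[i],
        ch10_c = bnd[i, 1], ch50_c = bnd[i, 2], ch90_c = bnd[i, 3],
        pct_damage = pct, surviving_fraction_cum = surv)
      adjb <- adjust_percentiles(bnd[i, 1], bnd[i, 2], bnd[i, 3], pct)
      bnd[i, ] <- unlist(adjb, use.names = FALSE)
      adjp <- adjust_percentiles(proj[i, 1], proj[i, 2], proj[i, 3], pct)
      proj[i, ] <- unlist(adjp, use.names = FALSE)
      ev <- events[[length(events)]]
      ev$ch10_adj_c <- adjb$ch10_adj_c
      ev$ch50_adj_c <- adjb$ch50_adj_c
      ev$ch90_adj_c <- adjb$ch90_adj_c
      events[[length(events)]] <- ev
    } else if (!damage_correction && detect_freeze_event(d$tmin_c[i], bnd[i, 1])) {
      pct <- percent_damage(d$tmin_c[i], bnd[i, 1], bnd[i, 2], bnd[i, 3])
      surv <- surv * (1 - pct / 100)
      events[[length(events) + 1]] <- data.frame(
        date = d$date[i], tmin_c = d$tmin_c[i],
        ch10_c = bnd[i, 1], ch50_c = bnd[i, 2], ch90_c = bnd[i, 3],
        pct_damage = pct, surviving_fraction_cum = surv,
        ch10_adj_c = bnd[i, 1], ch50_adj_c = bnd[i, 2], ch90_adj_c = bnd[i, 3])
    }
    prev_proj <- proj[i, ]; prev_bnd <- bnd[i, ]; prev_raw <- raw[i, ]
  }

  traj <- data.frame(date = d$date, tmin_c = d$tmin_c, tmax_c = d$tmax_c,
                     chill_portions_cum = chill$chill_portions_cum,
                     ch10_c = proj[, 1], ch50_c = proj[, 2], ch90_c = proj[, 3],
                     ch10_bnd_c = bnd[, 1], ch50_bnd_c = bnd[, 2],
                     ch90_bnd_c = bnd[, 3],
                     ch50_uncorrected_c = raw[, 2])
  traj <- structure(traj, mode = "projected", cultivar = cultivar,
                    season_year = season$season_year, site_id = season$site_id,
                    class = c("hardiness_trajectory", "data.frame"))

  thr <- threshold_for(cultivar, convention)
  raw_traj <- traj
  raw_traj$ch50_c <- traj$ch50_uncorrected_c
  bb_initial <- extract_budbreak(raw_traj, thr)
  bb_fdc <- extract_budbreak(traj, thr)
  bb_fdc$corrected <- TRUE

  events_df <- if (length(events) > 0) {
    do.call(rbind, events)
  } else {
    data.frame(date = as.Date(character()), tmin_c = numeric(),
               ch10_c = numeric(), ch50_c = numeric(), ch90_c = numeric(),
               pct_damage = numeric(), surviving_fraction_cum = numeric(),
               ch10_adj_c = numeric(), ch50_adj_c = numeric(),
               ch90_adj_c = numeric())
  }
  list(trajectory = traj, events = events_df,
       budbreak_initial = bb_initial, budbreak_fdc = bb_fdc)
}
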