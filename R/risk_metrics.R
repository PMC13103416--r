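# Dormant-season risk indicators built on the damage-adjusted, bounded
# (spring-floored) trajectories: daily safety margins, freeze-risk and
# near-miss day counts, MDST risk bands, and budbreak-aligned series.

#' Daily safety margin
#'
#' `tmin_c - ch50_c`: a margin at or below zero predicts at least 50%
#' freezing damage; small positive margins are near misses.
#'
#' @param tmin_c Daily minimum air temperature, degC.
#' @param ch50_c 50th-percentile hardiness prediction, degC.
#' @return Margin in degC (vectorised).
#' @export
safety_margin <- function(tmin_c, ch50_c) {
  tmin_c - ch50_c
}

#' Number of freeze-risk days in a season
#'
#' Counts days whose safety margin is `<= 0` (the indicator-sum convention,
#' boundary day included).
#'
#' @param margins Numeric vector of daily safety margins for a complete
#'   season (no missing values).
#' @return Integer count.
#' @export
count_risk_days <- function(margins) {
  if (anyNA(margins)) stop("incomplete season: missing safety margins")
  sum(margins <= 0)
}

#' Number of near-miss days in a season
#'
#' Counts days with a narrow safety margin, `0 < margin <= 2` degC.
#'
#' @inheritParams count_risk_days
#' @return Integer count.
#' @export
count_near_miss_days <- function(margins) {
  if (anyNA(margins)) stop("incomplete season: missing safety margins")
  sum(margins > 0 & margins <= 2)
}

#' Classify mean dormant-season temperature into a freeze-risk band
#'
#' Band 1 (high risk): MDST < 1; band 2 (moderate): 1 <= MDST <= 3;
#' band 3 (increased, spring-frost mismatch): 3 < MDST <= 8; band 4 (low):
#' MDST > 8. Boundary values belong to the lower band.
#'
#' @param mdst_c Mean dormant-season temperature, degC (vectorised).
#' @return Integer band 1..4.
#' @export
classify_mdst_band <- function(mdst_c) {
  ifelse(mdst_c < 1, 1L,
         ifelse(mdst_c <= 3, 2L,
                ifelse(mdst_c <= 8, 3L, 4L)))
}

#' Align a season's daily series to its FDC budbreak day
#'
#' @param dates Vector of dates for the season.
#' @param fdc_date The freeze-damage-corrected budbreak date (status must
#'   be OK; a failed prediction excludes the season).
#' @return Integer offsets in days from budbreak (0 = budbreak day).
#' @export
align_to_budbreak <- function(dates, fdc_date) {
  if (is.na(fdc_date)) {
    stop("season excluded: FDC budbreak prediction FAILED")
  }
  as.integer(dates - as.Date(fdc_date))
}

#' Season risk summary
#'
#' @param season A `dormant_season` (provides MDST and identity).
#' @param result Output of [simulate_with_damage()] for that season.
#' @return One-row data.frame: `site_id`, `cultivar`, `season_year`,
#'   `mdst_c`, `band`, `n_risk_days`, `n_near_miss_days`, `n_events`.
#' @export
risk_summary <- function(season, result) {
  traj <- result$trajectory
  margins <- safety_margin(traj$tmin_c, traj$ch50_bnd_c)
  data.frame(site_id = season$site_id,
             cultivar = attr(traj, "cultivar"),
             season_year = season$season_year,
             mdst_c = season$mdst_c,
             band = classify_mdst_band(season$mdst_c),
             n_risk_days = count_risk_days(margins),
             n_near_miss_days = count_near_miss_days(margins),
             n_events = nrow(result$events))
}
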