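# Budbreak extraction: the projected 50th-percentile hardiness trajectory is
# allowed to run into positive lethal temperatures; budbreak is predicted on
# the first day it reaches a cultivar- and observation-convention-specific
# threshold.

.conventions <- c("BBCH07_50", "BBCH05_50", "BBCH05_first")

#' Cold-hardiness-at-budbreak threshold for a cultivar and convention
#'
#' Thresholds follow the published rules: with 50%-of-buds BBCH 07
#' observations, +10 degC for Cabernet-Sauvignon and Riesling and +5 degC
#' for Concord; 50%-of-buds BBCH 05 observations use +5 degC for the two
#' V. vinifera cultivars (buds at the wool stage are hardier), and
#' first-bud BBCH 05 observations use 0 degC. No adjusted thresholds exist
#' for Concord under the BBCH 05 conventions, so that combination is an
#' explicit error.
#'
#' @param cultivar Cultivar name.
#' @param convention One of `"BBCH07_50"`, `"BBCH05_50"`, `"BBCH05_first"`.
#' @return Threshold in degC.
#' @export
threshold_for <- function(cultivar, convention) {
  if (!cultivar %in% .cultivars) stop("unknown cultivar: ", cultivar)
  if (!convention %in% .conventions) stop("unknown convention: ", convention)
  vinifera <- cultivar %in% c("Cabernet-Sauvignon", "Riesling")
  if (convention == "BBCH07_50") {
    return(if (vinifera) 10 else 5)
  }
  if (!vinifera) {
    stop("no adjusted threshold is defined for Concord under ", convention)
  }
  switch(convention, BBCH05_50 = 5, BBCH05_first = 0)
}

#' Extract predicted budbreak from a projected trajectory
#'
#' Budbreak is the first day whose projected 50th-percentile hardiness is
#' at or above the threshold (daily resolution, no sub-day interpolation).
#' If no crossing occurs by the season end (30 June), the prediction is
#' `FAILED` — a first-class outcome, not an error.
#'
#' @param trajectory A projected-mode `hardiness_trajectory`, or any
#'   data.frame with `date` and `ch50_c`.
#' @param threshold_c Threshold in degC (see [threshold_for()]).
#' @param season_year Spring calendar year; defaults to the trajectory
#'   attribute.
#' @return A `budbreak_prediction`: list with `site_id`, `cultivar`,
#'   `season_year`, `threshold_c`, `doy` (day of year of the spring
#'   calendar year, `NA` if failed), `date`, `status` (`"OK"`/`"FAILED"`),
#'   `corrected` (FALSE here).
#' @export
extract_budbreak <- function(trajectory, threshold_c,
                             season_year = attr(trajectory, "season_year")) {
  mode <- attr(trajectory, "mode")
  if (!is.null(mode) && mode != "projected") {
    stop("budbreak extraction needs a projected-mode trajectory ",
         "(the spring floor would prevent threshold crossing)")
  }
  hit <- which(trajectory$ch50_c >= threshold_c)
  if (length(hit) == 0) {
    pred <- list(date = as.Date(NA), doy = NA_integer_, status = "FAILED")
  } else {
    date <- trajectory$date[hit[1]]
    if (is.null(season_year)) season_year <- as.integer(format(date, "%Y"))
    doy <- as.integer(date - as.Date(sprintf("%d-01-01", season_year))) + 1L
    pred <- list(date = date, doy = doy, status = "OK")
  }
  structure(list(site_id = attr(trajectory, "site_id"),
                 cultivar = attr(trajectory, "cultivar"),
                 season_year = season_year,
                 threshold_c = threshold_c,
                 doy = pred$doy, date = pred$date, status = pred$status,
                 corrected = FALSE),
            class = "budbreak_prediction")
}

#' @export
print.budbreak_prediction <- function(x, ...) {
  cat(sprintf("<budbreak> %s %s %s: %s (threshold %+g degC%s)\n",
              x$site_id %||% "?", x$cultivar %||% "?",
              x$season_year %||% "?",
              if (x$status == "OK") sprintf("DOY %d", x$doy) else "FAILED",
              x$threshold_c,
              if (isTRUE(x$corrected)) ", damage-corrected" else ""))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
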