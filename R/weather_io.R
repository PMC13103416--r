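#' Read and validate a daily weather CSV for one site
#'
#' Reads a CSV with columns `date` (ISO-8601, `YYYY-MM-DD`), `tmin_c` and
#' `tmax_c` (degrees Celsius) and returns a validated, date-sorted
#' `site_series` object. Validation rejects malformed dates, non-finite or
#' out-of-range temperatures (outside \[-60, 60\] degC), `tmin_c > tmax_c`,
#' and duplicated dates, naming the offending row/date in the error.
#'
#' @param path Path to the CSV file.
#' @param site_id Character site identifier.
#' @param latitude_deg Site latitude in decimal degrees (-90..90).
#' @return A `site_series`: list with `site_id`, `latitude_deg` and `data`
#'   (data.frame with `date`, `tmin_c`, `tmax_c`, sorted by date).
#' @export
read_daily_weather <- function(path, site_id, latitude_deg) {
  stopifnot(is.character(site_id), length(site_id) == 1)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("date", "tmin_c", "tmax_c")
  miss <- setdiff(need, names(df))
  if (length(miss) > 0) {
    stop("weather CSV is missing column(s): ", paste(miss, collapse = ", "))
  }
  site_series(df[need], site_id = site_id, latitude_deg = latitude_deg)
}

#' Construct a site_series from an in-memory daily weather table
#'
#' @param data data.frame with columns `date`, `tmin_c`, `tmax_c`. `date`
#'   may be `Date` or ISO-8601 character.
#' @param site_id Character site identifier.
#' @param latitude_deg Latitude in decimal degrees.
#' @return A validated `site_series` object.
#' @export
site_series <- function(data, site_id, latitude_deg) {
  if (!is.numeric(latitude_deg) || length(latitude_deg) != 1 ||
      !is.finite(latitude_deg) || abs(latitude_deg) > 90) {
    stop("latitude_deg must be a single finite value in [-90, 90]")
  }
  data <- as.data.frame(data)
  if (is.character(data$date) || is.factor(data$date)) {
    raw <- as.character(data$date)
    parsed <- as.Date(raw, format = "%Y-%m-%d")
    bad <- which(is.na(parsed))
    if (length(bad) > 0) {
      stop(sprintf("malformed date in row %d: '%s'", bad[1], raw[bad[1]]))
    }
    data$date <- parsed
  }
  if (!inherits(data$date, "Date")) stop("date column must be Date or ISO-8601 character")
  for (col in c("tmin_c", "tmax_c")) {
    v <- data[[col]]
    if (!is.numeric(v)) stop(col, " must be numeric")
    bad <- which(!is.finite(v) | v < -60 | v > 60)
    if (length(bad) > 0) {
      stop(sprintf("%s out of range or non-finite on %s", col,
                   format(data$date[bad[1]])))
    }
  }
  bad <- which(data$tmin_c > data$tmax_c)
  if (length(bad) > 0) {
    stop(sprintf("tmin_c > tmax_c on %s", format(data$date[bad[1]])))
  }
  dup <- which(duplicated(data$date))
  if (length(dup) > 0) {
    stop(sprintf("duplicated date: %s", format(data$date[dup[1]])))
  }
  data <- data[order(data$date), , drop = FALSE]
  rownames(data) <- NULL
  structure(list(site_id = site_id, latitude_deg = latitude_deg, data = data),
            class = "site_series")
}

#' @export
print.site_series <- function(x, ...) {
  cat(sprintf("<site_series> %s (lat %.2f): %d days, %s .. %s\n",
              x$site_id, x$latitude_deg, nrow(x$data),
              format(min(x$data$date)), format(max(x$data$date))))
  invisible(x)
}

#' Split a site series into complete dormant seasons
#'
#' A dormant season runs from 1 July of `season_year - 1` through 30 June of
#' `season_year` (Northern Hemisphere). Only windows with every calendar day
#' present are returned; partial windows are dropped (with a message when
#' `quiet = FALSE`).
#'
#' @param series A `site_series`.
#' @param mdst_method How the mean dormant-season temperature is computed;
#'   see [mean_dormant_season_temperature()].
#' @param quiet Suppress messages about skipped partial windows.
#' @return List of `dormant_season` objects (possibly empty).
#' @export
split_seasons <- function(series, mdst_method = c("midpoint", "hourly"),
                          quiet = TRUE) {
  stopifnot(inherits(series, "site_series"))
  mdst_method <- match.arg(mdst_method)
  if (series$latitude_deg < 0) {
    stop("Southern-Hemisphere sites are not supported: season windows are ",
         "fixed to the Northern-Hemisphere 1 Jul - 30 Jun convention")
  }
  d <- series$data
  if (nrow(d) == 0) stop("empty series")
  years <- seq(as.integer(format(min(d$date), "%Y")),
               as.integer(format(max(d$date), "%Y")) + 1)
  have <- d$date  # sorted, unique
  out <- list()
  for (y in years) {
    start <- as.Date(sprintf("%d-07-01", y - 1))
    end <- as.Date(sprintf("%d-06-30", y))
    window <- seq(start, end, by = "day")
    idx <- match(window, have)
    if (anyNA(idx)) {
      if (!quiet && any(!is.na(idx))) {
        message(sprintf("season %d skipped: incomplete window", y))
      }
      next
    }
    slice <- d[idx, , drop = FALSE]
    rownames(slice) <- NULL
    season <- structure(
      list(season_year = y, start = start, end = end, records = slice,
           site_id = series$site_id, latitude_deg = series$latitude_deg,
           mdst_c = NA_real_),
      class = "dormant_season")
    season$mdst_c <- mean_dormant_season_temperature(season, method = mdst_method)
    out[[length(out) + 1]] <- season
  }
  out
}

#' @export
print.dormant_season <- function(x, ...) {
  cat(sprintf("<dormant_season> %s %d: %d days, MDST %.2f degC\n",
              x$site_id, x$season_year, nrow(x$records), x$mdst_c))
  invisible(x)
}

#' Mean dormant-season temperature (1 Nov - 30 Apr)
#'
#' Averages daily temperature over 1 November of `season_year - 1` through
#' 30 April of `season_year`, inclusive. With `method = "midpoint"` (the
#' default) the daily value is `(tmin_c + tmax_c) / 2`; with
#' `method = "hourly"` it is the mean of the 24 interpolated hourly
#' temperatures (see [interpolate_hourly()]).
#'
#' @param season A `dormant_season`.
#' @param method `"midpoint"` or `"hourly"`.
#' @return Mean temperature in degrees Celsius.
#' @export
mean_dormant_season_temperature <- function(season,
                                            method = c("midpoint", "hourly")) {
  stopifnot(inherits(season, "dormant_season"))
  method <- match.arg(method)
  w_start <- as.Date(sprintf("%d-11-01", season$season_year - 1))
  w_end <- as.Date(sprintf("%d-04-30", season$season_year))
  d <- season$records
  idx <- match(seq(w_start, w_end, by = "day"), d$date)
  if (anyNA(idx)) stop("missing day inside the 1 Nov - 30 Apr window")
  if (method == "midpoint") {
    return(mean((d$tmin_c[idx] + d$tmax_c[idx]) / 2))
  }
  hr <- hourly_temperatures(d[idx, , drop = FALSE], season$latitude_deg)
  mean(hr$temp_c)
}

# Solar geometry: declination (Cooper's formula) and sunrise/sunset in local
# solar hours. Used by the daytime-sine / night-log hourly interpolation.
solar_times <- function(latitude_deg, date) {
  if (abs(latitude_deg) > 66.6) {
    stop("unsupported latitude: |lat| > 66.6 (polar day/night)")
  }
  doy <- as.POSIXlt(date)$yday + 1
  decl <- 23.45 * sin(2 * pi * (284 + doy) / 365) * pi / 180
  phi <- latitude_deg * pi / 180
  cosw <- -tan(phi) * tan(decl)
  cosw <- min(1, max(-1, cosw))
  halfday <- acos(cosw) * 12 / pi      # hours from solar noon to sunset
  list(sunrise = 12 - halfday, sunset = 12 + halfday, daylength = 2 * halfday)
}

#' Interpolate 24 hourly temperatures from daily minima/maxima
#'
#' Implements the daytime-sine / nocturnal-logarithmic scheme with day length
#' from standard solar geometry: daytime follows
#' `tmin + (tmax - tmin) * sin(pi * (h - sunrise) / (daylength + 4))` and the
#' night declines logarithmically from the sunset temperature toward the next
#' morning's minimum at sunrise. Hours are local solar hours 0..23.
#'
#' @param prev_day,day,next_day Lists or one-row data.frames with fields
#'   `date`, `tmin_c`, `tmax_c`. At season edges pass the edge day itself.
#' @param latitude_deg Latitude in decimal degrees, |lat| <= 66.6.
#' @param date Date of `day`; defaults to `day$date`.
#' @return Numeric vector of 24 temperatures (degC).
#' @export
interpolate_hourly <- function(prev_day, day, next_day, latitude_deg,
                               date = day$date) {
  day <- as.list(day); prev_day <- as.list(prev_day); next_day <- as.list(next_day)
  st <- solar_times(latitude_deg, date)
  sunrise <- st$sunrise; sunset <- st$sunset; dl <- st$daylength
  nightlen <- 24 - dl
  sine_at <- function(tmin, tmax, h) {
    tmin + (tmax - tmin) * sin(pi * (h - sunrise) / (dl + 4))
  }
  t_sunset_prev <- sine_at(prev_day$tmin_c, prev_day$tmax_c, sunset)
  t_sunset <- sine_at(day$tmin_c, day$tmax_c, sunset)
  h <- 0:23
  out <- numeric(24)
  pre <- h < sunrise
  # pre-dawn: continuation of last night's decline, hitting tmin at sunrise
  hrs_pre <- h[pre] + (24 - sunset)
  out[pre] <- t_sunset_prev -
    (t_sunset_prev - day$tmin_c) * log(hrs_pre + 1) / log(nightlen + 1)
  dayt <- h >= sunrise & h <= sunset
  out[dayt] <- sine_at(day$tmin_c, day$tmax_c, h[dayt])
  post <- h > sunset
  hrs_post <- h[post] - sunset
  out[post] <- t_sunset -
    (t_sunset - next_day$tmin_c) * log(hrs_post + 1) / log(nightlen + 1)
  out
}

#' Hourly temperatures for a block of consecutive days
#'
#' Applies [interpolate_hourly()] to each row of a daily weather data.frame,
#' reusing the edge day as its own neighbor at the block boundaries.
#'
#' @param records data.frame with `date`, `tmin_c`, `tmax_c` on consecutive
#'   days.
#' @param latitude_deg Latitude in decimal degrees.
#' @return data.frame with `date`, `hour` (0..23) and `temp_c`;
#'   `24 * nrow(records)` rows.
#' @export
hourly_temperatures <- function(records, latitude_deg) {
  n <- nrow(records)
  if (n == 0) stop("no records")
  if (n > 1 && any(diff(records$date) != 1)) {
    stop("records must be consecutive days")
  }
  temps <- vector("list", n)
  for (i in seq_len(n)) {
    prev <- records[max(1, i - 1), ]
    nxt <- records[min(n, i + 1), ]
    temps[[i]] <- interpolate_hourly(prev, records[i, ], nxt, latitude_deg)
  }
  data.frame(date = rep(records$date, each = 24L),
             hour = rep(0:23, times = n),
             temp_c = unlist(temps))
}
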