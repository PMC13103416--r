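# Shared fixtures and independent oracles for the test suite.

params_tbl <- load_cultivar_params()
ALL_CULTIVARS <- c("Cabernet-Sauvignon", "Riesling", "Concord")

# Small daily weather data.frame of consecutive days.
make_weather <- function(start = "2000-07-01", n = 10, tmin = 0, tmax = 10) {
  dates <- seq(as.Date(start), by = "day", length.out = n)
  data.frame(date = dates,
             tmin_c = rep_len(tmin, n), tmax_c = rep_len(tmax, n))
}

# One calibrated synthetic season at a target MDST (cached per call site).
synth_season <- function(mdst, seed = 42, n_years = 2, which = 1) {
  spec <- calibrate_spec_for_mdst(mdst, climate_spec(8, n_years = n_years,
                                                     seed = seed))
  split_seasons(generate_weather(spec, sprintf("mdst%g", mdst)))[[which]]
}

# --- Monte-Carlo population oracle for the freeze-damage interpolation ---
# Buds live on the piecewise-linear quantile curve through (10, ch10),
# (50, ch50), (90, ch90); the hardiest decile (u > 90) is treated as a
# censored survivor tail (this is the population reading under which the
# damage interpolation's 90% cap is exact). A bud at quantile u dies when
# its lethal temperature exceeds tmin.
quantile_curve <- function(u, ch10, ch50, ch90) {
  ifelse(u <= 50,
         ch10 + (ch50 - ch10) / 40 * (u - 10),
         ch50 + (ch90 - ch50) / 40 * (u - 50))
}

mc_percent_damage <- function(tmin, ch10, ch50, ch90, n = 1e5, seed = 99) {
  set.seed(seed)
  u <- stats::runif(n, 0, 100)
  lethal <- ifelse(u > 90, -Inf, quantile_curve(u, ch10, ch50, ch90))
  100 * mean(lethal > tmin)
}

# Survivor-population 50th percentile after d% of the existing population
# is killed: survivors are u > d, and their median sits at quantile
# position d + 0.5 * (100 - d) of the old curve.
mc_survivor_ch50 <- function(d, ch10, ch50, ch90, n = 1e5, seed = 99) {
  set.seed(seed)
  u <- stats::runif(n, 0, 100)
  surv <- u[u > d]
  stats::median(quantile_curve(surv, ch10, ch50, ch90))
}

# A synthetic season with extreme cold nights inserted on given dates, to
# force freeze events deterministically.
season_with_cold_snap <- function(mdst = 2, snap_dates, snap_tmin = -35,
                                  seed = 7) {
  spec <- calibrate_spec_for_mdst(mdst, climate_spec(8, n_years = 2,
                                                     seed = seed))
  w <- generate_weather(spec, "snap")
  idx <- w$data$date %in% as.Date(snap_dates)
  stopifnot(any(idx))
  w$data$tmin_c[idx] <- snap_tmin
  w$data$tmax_c[idx] <- pmax(w$data$tmax_c[idx], snap_tmin + 5)
  split_seasons(w)[[1]]
}
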