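test_that("freeze-event detection is strictly below the 10th percentile", {
  expect_true(detect_freeze_event(-21, -20))
  expect_false(detect_freeze_event(-20, -20))
  expect_false(detect_freeze_event(-5, -20))
})

test_that("percent damage hits the quantile anchors and the cap", {
  expect_equal(percent_damage(-20, -20, -23, -26), 10)
  expect_equal(percent_damage(-23, -20, -23, -26), 50)
  expect_equal(percent_damage(-40, -20, -23, -26), 90)
})

test_that("the two interpolation bands agree exactly at the seam", {
  ch <- c(-18.3, -22.1, -24.9)
  seam_band1 <- 10 + (50 - 10) / (ch[2] - ch[1]) * (ch[2] - ch[1])
  seam_band2 <- 50 + (90 - 50) / (ch[3] - ch[2]) * (ch[2] - ch[2])
  expect_equal(seam_band1, seam_band2)
  expect_equal(percent_damage(ch[2], ch[1], ch[2], ch[3]), 50)
})

test_that("percent damage is non-increasing in tmin and errors on bad input", {
  tmins <- seq(-20, -35, by = -0.25)
  d <- vapply(tmins, percent_damage, numeric(1),
              ch10_c = -20, ch50_c = -23, ch90_c = -26)
  expect_true(all(diff(d) >= 0))       # colder -> at least as much damage
  expect_true(all(diff(d[d < 90]) > 0))  # strictly until the cap
  expect_error(percent_damage(-25, -20, -20, -26), "degenerate")
  expect_error(percent_damage(-15, -20, -23, -26), "tmin")
  expect_error(percent_damage(-25, -26, -23, -20), "ordering")
})

test_that("percent damage matches the Monte-Carlo population oracle", {
  ch <- c(-20, -23, -26)
  for (tmin in seq(ch[3] - 4.75, ch[1] - 0.25, by = 0.5)) {
    mc <- mc_percent_damage(tmin, ch[1], ch[2], ch[3])
    expect_equal(percent_damage(tmin, ch[1], ch[2], ch[3]), mc,
                 tolerance = 1 / max(mc, 1))  # within 1 percentage point
  }
  # the spec's example point
  expect_equal(percent_damage(-21.5, -20, -23, -26),
               mc_percent_damage(-21.5, -20, -23, -26), tolerance = 1 / 30)
})

test_that("survivor adjustment: identity at d = 0, golden values, branches", {
  ch <- c(-20, -23, -26)
  id <- adjust_percentiles(ch[1], ch[2], ch[3], 0)
  expect_equal(unlist(id, use.names = FALSE), ch)

  a20 <- adjust_percentiles(ch[1], ch[2], ch[3], 20)
  expect_equal(a20$ch10_adj_c, -21.35)
  expect_equal(a20$ch50_adj_c, -23.75)
  expect_equal(a20$ch90_adj_c, -26.15)

  # d = 60 uses the 10-90 chord for CH10*: hand evaluation
  a60 <- adjust_percentiles(ch[1], ch[2], ch[3], 60)
  expect_equal(a60$ch10_adj_c, -20 + (-6 / 80) * (40 * 0.1 + 60 - 10))
  expect_equal(a60$ch10_adj_c, -24.05)

  expect_error(adjust_percentiles(ch[1], ch[2], ch[3], 95), "pct_damage")
  expect_error(adjust_percentiles(ch[1], ch[2], ch[3], -1), "pct_damage")
})

test_that("CH50* matches the survivor-quantile Monte-Carlo oracle", {
  ch <- c(-20, -23, -26)
  for (d in seq(10, 80, by = 10)) {
    adj <- adjust_percentiles(ch[1], ch[2], ch[3], d)
    mc <- mc_survivor_ch50(d, ch[1], ch[2], ch[3])
    expect_equal(adj$ch50_adj_c, mc, tolerance = 0.05 / abs(mc))
  }
})

test_that("adjusted percentiles harden and stay ordered (property sweep)", {
  set.seed(11)
  for (i in 1:2000) {
    ch10 <- runif(1, -25, -5)
    g1 <- runif(1, 1, 4); g2 <- runif(1, 1, 4)  # realistic spread asymmetry
    ch50 <- ch10 - g1; ch90 <- ch50 - g2
    d <- runif(1, 0, 90)
    a <- adjust_percentiles(ch10, ch50, ch90, d)
    expect_true(a$ch10_adj_c <= ch10 + 1e-12)
    expect_true(a$ch50_adj_c <= ch50 + 1e-12)
    expect_true(a$ch90_adj_c <= ch90 + 1e-12)
    expect_true(a$ch10_adj_c >= a$ch50_adj_c - 1e-12)
    expect_true(a$ch50_adj_c >= a$ch90_adj_c - 1e-12)
  }
})

test_that("no-damage seasons: FDC equals the initial prediction, no events", {
  s <- synth_season(8, seed = 41)  # warm: no freeze events expected
  res <- simulate_with_damage("Cabernet-Sauvignon", s, chill_for_season(s))
  if (nrow(res$events) == 0) {
    expect_equal(res$budbreak_fdc$doy, res$budbreak_initial$doy)
  }
  expect_equal(res$budbreak_fdc$corrected, TRUE)
})

test_that("an engineered cold snap creates a consistent freeze event", {
  s <- season_with_cold_snap(2, snap_dates = "2001-01-15")
  chill <- chill_for_season(s)
  res <- simulate_with_damage("Cabernet-Sauvignon", s, chill)
  ev <- res$events[res$events$date == as.Date("2001-01-15"), ]
  expect_equal(nrow(ev), 1)
  # compositional consistency: stored event reproduces the primitives
  expect_equal(ev$pct_damage,
               percent_damage(ev$tmin_c, ev$ch10_c, ev$ch50_c, ev$ch90_c))
  adj <- adjust_percentiles(ev$ch10_c, ev$ch50_c, ev$ch90_c, ev$pct_damage)
  expect_equal(ev$ch50_adj_c, adj$ch50_adj_c)
  # the trajectory on the event day carries the adjusted bounded values
  day <- res$trajectory[res$trajectory$date == ev$date, ]
  expect_equal(day$ch50_bnd_c, adj$ch50_adj_c)
  expect_gt(ev$pct_damage, 10)
  expect_lte(ev$pct_damage, 90)
  # a pre-budbreak event delays (or at least never advances) budbreak
  expect_gte(res$budbreak_fdc$doy, res$budbreak_initial$doy)
})

test_that("multi-event survivor bookkeeping is multiplicative", {
  s <- season_with_cold_snap(2, snap_dates = c("2001-01-15", "2001-02-10"),
                             snap_tmin = -34)
  res <- simulate_with_damage("Cabernet-Sauvignon", s, chill_for_season(s))
  ev <- res$events
  snap <- ev[ev$date %in% as.Date(c("2001-01-15", "2001-02-10")), ]
  expect_equal(nrow(snap), 2)
  expect_equal(ev$surviving_fraction_cum,
               cumprod(1 - ev$pct_damage / 100))
  expect_true(all(ev$surviving_fraction_cum > 0 &
                    ev$surviving_fraction_cum <= 1))
})

test_that("disabling damage correction records events without adjusting", {
  s <- season_with_cold_snap(2, snap_dates = "2001-01-15")
  chill <- chill_for_season(s)
  on <- simulate_with_damage("Riesling", s, chill, damage_correction = TRUE)
  off <- simulate_with_damage("Riesling", s, chill, damage_correction = FALSE)
  expect_gte(nrow(off$events), 1)
  expect_equal(off$budbreak_fdc$doy, off$budbreak_initial$doy)
  expect_equal(off$budbreak_initial$doy, on$budbreak_initial$doy)
  expect_gte(on$budbreak_fdc$doy, off$budbreak_fdc$doy)
})
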