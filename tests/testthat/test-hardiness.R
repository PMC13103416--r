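all_param_sets <- do.call(rbind, lapply(ALL_CULTIVARS, function(cv) {
  data.frame(cultivar = cv, percentile = c(10, 50, 90))
}))
param_set <- function(i) {
  cultivar_params(params_tbl, all_param_sets$cultivar[i],
                  all_param_sets$percentile[i])
}

test_that("parameter table is complete and bounds are negative", {
  expect_equal(nrow(all_param_sets), 9)
  for (i in seq_len(9)) {
    p <- param_set(i)
    expect_lt(p$ch_max, 0)
    expect_true(all(c("ch_init", "acc_rate", "deacc_rate", "dp_mid") %in%
                      names(p)))
  }
  expect_error(cultivar_params(params_tbl, "Merlot", 50), "unknown cultivar")
})

test_that("deacclimation potential is a saturating logistic in chill", {
  for (i in seq_len(9)) {
    p <- param_set(i)
    expect_lt(deacclimation_potential(p, 0), 0.05)
    expect_gte(deacclimation_potential(p, 150), 0.95)
    expect_lt(deacclimation_potential(p, 50), deacclimation_potential(p, 100))
    cp <- seq(0, 150, by = 5)
    expect_true(all(diff(deacclimation_potential(p, cp)) > 0))
  }
  expect_error(deacclimation_potential(param_set(1), -1), "chill_portions")
})

test_that("acclimation gain honors saturation, temperature and chill", {
  for (i in seq_len(9)) {
    p <- param_set(i)
    expect_equal(acclimation_gain(p, 40, -10, p$ch_max), 0)
    expect_gte(acclimation_gain(p, 40, -10, -15),
               acclimation_gain(p, 40, -2, -15))
    expect_gte(acclimation_gain(p, 20, -5, -15),
               acclimation_gain(p, 80, -5, -15))
    expect_true(all(acclimation_gain(p, c(0, 50, 120),
                                     c(-20, 0, 15), c(-5, -20, -1)) >= 0))
  }
  # hand-evaluated golden (Riesling p50, chill 20, tmin -5, ch_prev -15):
  # threshold = 12 - 10 * 20/50 = 8; drive = 13; capacity = 12/27
  p <- cultivar_params(params_tbl, "Riesling", 50)
  expect_equal(acclimation_gain(p, 20, -5, -15), 0.462222222222222,
               tolerance = 1e-12)
})

test_that("deacclimation loss is chill-gated and monotone in temperature", {
  for (i in seq_len(9)) {
    p <- param_set(i)
    expect_lt(deacclimation_loss(p, 0, 10, 25), 0.05)
    expect_gte(deacclimation_loss(p, 150, 10, 25),
               deacclimation_loss(p, 150, 5, 10))
  }
  # hand-evaluated golden of the documented formulas (Riesling p50,
  # chill 80, tmin 5, tmax 15)
  p <- cultivar_params(params_tbl, "Riesling", 50)
  expect_equal(deacclimation_loss(p, 80, 5, 15), 0.910470605801977,
               tolerance = 1e-12)
  expect_error(deacclimation_loss(p, 80, 15, 5), "tmin")
})

test_that("daily update conserves gain/loss before clamping", {
  s <- synth_season(4, seed = 21)
  chill <- chill_for_season(s)
  p <- cultivar_params(params_tbl, "Riesling", 50)
  tr <- simulate_hardiness(p, s, chill, mode = "projected")
  prev <- c(p$ch_init, tr$ch_c[-nrow(tr)])
  raw <- prev - tr$gain_c + tr$loss_c
  unclamped <- raw >= p$ch_max  # projected mode: only the lower bound clamps
  expect_gt(sum(unclamped), 300)
  expect_equal(tr$ch_c[unclamped], raw[unclamped], tolerance = 1e-12)
  expect_true(all(tr$ch_c >= p$ch_max - 1e-12))
})

test_that("projected trajectories cross +10 in spring; bounded stay floored", {
  s <- synth_season(6, seed = 22)
  chill <- chill_for_season(s)
  p <- cultivar_params(params_tbl, "Riesling", 50)
  proj <- simulate_hardiness(p, s, chill, mode = "projected")
  expect_gt(max(proj$ch_c), 10)
  fl <- spring_floor()
  bnd <- simulate_hardiness(p, s, chill, mode = "bounded", floor = fl)
  expect_lte(max(bnd$ch_c), fl$p50)
  # identical until the floor first binds
  first <- which(bnd$ch_c >= fl$p50 - 1e-12)[1]
  expect_equal(proj$ch_c[seq_len(first - 1)], bnd$ch_c[seq_len(first - 1)])
})

test_that("percentile ordering and cultivar contrasts hold on a cold season", {
  s <- synth_season(2, seed = 23)
  chill <- chill_for_season(s)
  trs <- lapply(ALL_CULTIVARS, simulate_all_percentiles,
                season = s, chill = chill, mode = "projected",
                params_tbl = params_tbl)
  for (tr in trs) {
    expect_true(all(tr$ch10_c >= tr$ch50_c & tr$ch50_c >= tr$ch90_c))
  }
  # parameter sensitivity: cultivars differ on the same weather
  expect_false(isTRUE(all.equal(trs[[1]]$ch50_c, trs[[2]]$ch50_c)))
  # the Northern hybrid reaches deeper midwinter hardiness than the
  # warm-climate vinifera
  expect_lt(min(trs[[3]]$ch50_c), min(trs[[1]]$ch50_c))
})

test_that("cold-season ch50 is U-shaped: minimum strictly inside the season", {
  s <- synth_season(3, seed = 24)
  chill <- chill_for_season(s)
  tr <- simulate_all_percentiles("Concord", s, chill, mode = "projected",
                                 params_tbl = params_tbl)
  bb <- extract_budbreak(tr, threshold_for("Concord", "BBCH07_50"))
  expect_equal(bb$status, "OK")
  imin <- which.min(tr$ch50_c)
  expect_gt(imin, 1)
  expect_lt(tr$date[imin], bb$date)
})

test_that("seeded full-season trajectory is reproducible (regression)", {
  s <- synth_season(5, seed = 77)
  chill <- chill_for_season(s)
  tr1 <- simulate_all_percentiles("Riesling", s, chill, mode = "projected",
                                  params_tbl = params_tbl)
  tr2 <- simulate_all_percentiles("Riesling", s, chill, mode = "projected",
                                  params_tbl = params_tbl)
  expect_identical(tr1$ch50_c, tr2$ch50_c)
})

test_that("misaligned chill and weather is an error", {
  s <- synth_season(5, seed = 25)
  chill <- chill_for_season(s)
  p <- cultivar_params(params_tbl, "Concord", 50)
  expect_error(simulate_hardiness(p, s, chill[-1, ]), "aligned")
})
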