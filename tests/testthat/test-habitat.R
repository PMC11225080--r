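# Habitat thermal-regime metrics and thermal safety margins.

make_constant_series <- function(temp = 10, start = "2020-08-01",
                                 end = "2020-08-31") {
  generate_habitat_series(regime_params(temp), start, end, seed = 1)
}

test_that("daily summaries collapse hourly readings per calendar date", {
  s <- make_constant_series(10)
  d <- daily_summaries(s)
  expect_equal(nrow(d), 31)
  expect_true(all(d$mean == 10 & d$min == 10 & d$max == 10))
  expect_true(all(d$n == 24))

  sin5 <- generate_habitat_series(regime_params(15, 0, 5), "2020-08-01",
                                  "2020-08-31", seed = 1)
  d2 <- daily_summaries(sin5)
  expect_equal(d2$min, rep(10, 31), tolerance = 1e-12)
  expect_equal(d2$max, rep(20, 31), tolerance = 1e-12)

  spike <- make_constant_series(10)
  spike$temp_c[spike$timestamp == as.POSIXct("2020-08-15 14:00:00",
                                             tz = "UTC")] <- 25
  d3 <- daily_summaries(spike)
  expect_equal(d3$max[d3$date == as.Date("2020-08-15")], 25)
})

test_that("7-day sliding averages use fully contained windows", {
  d <- daily_summaries(make_constant_series(18))
  sw <- sliding_7day(d, "max")
  expect_equal(nrow(sw$windows), 25)  # 31 - 7 + 1
  expect_true(all(sw$windows$value == 18))
  expect_equal(sw$period_mean, 18)

  d$max <- 1:31
  sw2 <- sliding_7day(d, "max")
  expect_equal(sw2$windows$value[1], mean(1:7))
  expect_error(sliding_7day(d[1:6, ], "max"), "7 days")
})

test_that("diel range and degree accumulations behave on simple series", {
  s <- make_constant_series(10)
  d <- daily_summaries(s)
  expect_equal(diel_range(d), 0)
  expect_equal(cumulative_degree_days(d), 310)
  expect_equal(cumulative_degree_hours(s), 7440)
  # constant-series identity
  expect_equal(cumulative_degree_hours(s),
               24 * cumulative_degree_days(d))

  z <- make_constant_series(0, "2020-01-01", "2020-01-10")
  expect_equal(cumulative_degree_days(daily_summaries(z)), 0)

  d_missing <- d[-15, ]
  expect_error(cumulative_degree_days(d_missing, range(d$date)),
               "2020-08-15")
})

test_that("degree hours check the cadence", {
  s <- make_constant_series(10)
  gappy <- s[-(5:10), ]
  expect_error(cumulative_degree_hours(gappy), "cadence")
  expect_warning(cumulative_degree_hours(gappy, strict = FALSE), "cadence")
})

test_that("threshold exposure counts partition the period", {
  s <- make_constant_series(15)
  d <- daily_summaries(s)
  ex <- threshold_exposure(d, s, c(11.4, 19.4))
  expect_true(all(ex$days$within == 31))
  expect_true(all(ex$days$below == 0 & ex$days$above == 0))
  expect_equal(ex$hours_above, 0)
  expect_equal(ex$hours_within, 31 * 24)

  spike <- s
  spike$temp_c[350] <- 20
  ex2 <- threshold_exposure(daily_summaries(spike), spike, c(11.4, 19.4))
  expect_equal(ex2$days$above[ex2$days$statistic == "max"], 1)
  expect_equal(ex2$hours_above, 1)

  # partition property on a noisy series
  noisy <- generate_habitat_series(regime_params(16, 0, 5, noise_sd = 2),
                                   "2020-08-01", "2020-08-31", seed = 4)
  exn <- threshold_exposure(daily_summaries(noisy), noisy, c(14, 18))
  expect_true(all(exn$days$below + exn$days$within + exn$days$above == 31))
  expect_error(threshold_exposure(d, s, c(20, 10)), "lo <= hi")
})

test_that("winter metrics find the freezing season or fall back", {
  # dam-stabilized site: never freezes -> fixed-window fallback, zero counts
  heb <- generate_habitat_series(hebgen_regime(), "2019-10-01", "2020-05-31",
                                 seed = 2)
  wm <- winter_metrics(daily_summaries(heb))
  expect_true(wm$fallback)
  expect_equal(wm$days_min_le0, 0)
  expect_equal(wm$days_max_le0, 0)
  expect_equal(wm$season_start, as.Date("2019-11-11"))
  expect_equal(wm$season_end, as.Date("2020-04-16"))
  expect_gt(wm$february_min, 0)

  # freezing site: season bounds from the data, counts match a direct count
  var <- generate_habitat_series(varney_regime(), "2019-10-01", "2020-05-31",
                                 seed = 2)
  dv <- daily_summaries(var)
  wv <- winter_metrics(dv)
  expect_false(wv$fallback)
  in_season <- dv[dv$date >= wv$season_start & dv$date <= wv$season_end, ]
  expect_equal(wv$days_min_le0, sum(in_season$min <= 0))
  expect_equal(wv$days_max_le0, sum(in_season$max <= 0))
  expect_gt(wv$days_min_le0, 0)
  expect_lte(wv$february_min, 0)

  # a synthetic cold snap of exactly 10 all-day-frozen days
  snap <- make_constant_series(3, "2019-10-01", "2020-05-31")
  frozen <- as.Date("2020-01-10") + 0:9
  snap$temp_c[as.Date(snap$timestamp, tz = "UTC") %in% frozen] <- -0.5
  ws <- winter_metrics(daily_summaries(snap))
  expect_equal(ws$days_max_le0, 10)
  expect_equal(ws$days_min_le0, 10)

  expect_error(winter_metrics(daily_summaries(make_constant_series(5))),
               "November")
})

test_that("thermal safety margins are exact differences", {
  v <- thermal_safety_margin(19.4, 21.9, 19.4)
  expect_equal(v$tsm_max, -2.5)
  expect_equal(v$tsm_7dadmax, 0)
  h <- thermal_safety_margin(24.6, 19.9, 17.9)
  expect_equal(h$tsm_max, 4.7)
  expect_equal(h$tsm_7dadmax, 6.7)
  eq <- thermal_safety_margin(20, 20, 20)
  expect_equal(eq$tsm_max, 0)
  expect_equal(eq$tsm_7dadmax, 0)
  # antitone in the habitat maximum at fixed optimum upper limit
  maxima <- seq(15, 25, 0.5)
  tsms <- vapply(maxima, function(m)
    thermal_safety_margin(19.4, m, m)$tsm_max, 0)
  expect_true(all(diff(tsms) < 0))
})

test_that("regime summaries compose the August metric set", {
  p <- regime_params(17.06, seasonal_amplitude = 0, diel_amplitude = 5,
                     noise_sd = 0.3)
  s <- generate_habitat_series(p, "2020-08-01", "2020-08-31", seed = 13,
                               site = "varney_like")
  rs <- regime_summary(s, period = c("2020-08-01", "2020-08-31"),
                       interval = c(11.4, 19.4))
  expect_equal(rs$cdd, 17.06 * 31, tolerance = 0.01)
  expect_equal(rs$cdh, 17.06 * 744, tolerance = 0.01)
  expect_equal(rs$mean_diel_range, 10, tolerance = 0.5)
  expect_gte(rs$mean_7dadmax, rs$mean_7dadmean)
  expect_gte(rs$mean_7dadmean, rs$mean_7dadmin)
  expect_true(all(rs$exposure$days$below + rs$exposure$days$within +
                    rs$exposure$days$above == 31))
  expect_equal(rs$site, "varney_like")
})
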