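# Synthetic respirometry traces, habitat series, and cohorts.

test_that("trace generation is deterministic per seed", {
  truth <- trial_truth(1e-3, 3e-3, 15)
  p <- resp_protocol(sample_interval = 10)
  a <- generate_respirometry_trace(truth, p, seed = 7)
  b <- generate_respirometry_trace(truth, p, seed = 7)
  c <- generate_respirometry_trace(truth, p, seed = 8)
  expect_identical(a, b)
  expect_false(identical(a$do_saturation_pct, c$do_saturation_pct))
})

test_that("noiseless trace recovers the generating rate in every seal", {
  truth <- trial_truth(1e-3, 3e-3, 15, noise_sd = 0, activity_burst_rate = 0)
  tr <- generate_respirometry_trace(truth, resp_protocol(sample_interval = 5),
                                    seed = 1)
  sl <- estimate_slopes(segment_trace(tr), volume_l = truth$chamber_volume)
  ov <- sl$rate_mg_min[sl$phase == "overnight"]
  expect_equal(ov, rep(1e-3, length(ov)), tolerance = 1e-9)
  ch <- sl$rate_mg_min[sl$phase == "chase"]
  expect_equal(ch, rep(3e-3, length(ch)), tolerance = 1e-9)
})

test_that("saturation stays within [0, 100 + 3 * noise_sd]", {
  truth <- trial_truth(2e-3, 6e-3, 25, noise_sd = 0.4,
                       activity_burst_rate = 2)
  tr <- generate_respirometry_trace(truth, resp_protocol(sample_interval = 10),
                                    seed = 3)
  expect_gte(min(tr$do_saturation_pct), 0)
  expect_lte(max(tr$do_saturation_pct), 100 + 3 * 0.4)
})

test_that("trace generator rejects invalid designs", {
  expect_error(trial_truth(1e-3, 5e-4, 15), "mmr_true")
  expect_error(trial_truth(-1e-3, 5e-4, 15), "rmr_true")
  expect_error(resp_protocol(sample_interval = 0), "sample_interval")
  # a seal long enough to empty the chamber at mmr is rejected
  big <- trial_truth(0.05, 0.12, 20)
  expect_error(generate_respirometry_trace(big, resp_protocol(), seed = 1),
               "below 0")
})

test_that("noisy cold-trial recovery stays within 5% of generating truth", {
  # the coldest, lowest-signal study condition: resting rate 8.95e-4 at 8 C
  truth <- trial_truth(8.95e-4, 2.03e-3, 8, noise_sd = 0.05)
  tr <- generate_respirometry_trace(truth, resp_protocol(), seed = 7)
  sl <- estimate_slopes(segment_trace(tr), volume_l = truth$chamber_volume)
  rmr <- estimate_rmr(sl)
  expect_lt(abs(rmr$rate - 8.95e-4) / 8.95e-4, 0.05)
  mmr <- estimate_mmr(sl)
  expect_lt(abs(mmr$rate - 2.03e-3) / 2.03e-3, 0.10)
})

test_that("habitat generator produces the configured structure", {
  const <- generate_habitat_series(regime_params(10), "2020-08-01",
                                   "2020-08-31", seed = 1)
  expect_true(all(const$temp_c == 10))

  diel <- generate_habitat_series(regime_params(15, 0, 5), "2020-08-01",
                                  "2020-08-31", seed = 1)
  d <- daily_summaries(diel)
  expect_equal(d$max - d$min, rep(10, nrow(d)), tolerance = 1e-12)

  expect_error(regime_params(10, seasonal_amplitude = -1), "non-negative")
  expect_error(generate_habitat_series(regime_params(10), "2020-08-31",
                                       "2020-08-01"), "end_date")
})

test_that("habitat generator is deterministic and honours the floor", {
  a <- generate_habitat_series(varney_regime(), "2019-11-01", "2020-04-30",
                               seed = 5)
  b <- generate_habitat_series(varney_regime(), "2019-11-01", "2020-04-30",
                               seed = 5)
  expect_identical(a, b)
  expect_gte(min(a$temp_c), varney_regime()$floor)
  z <- varney_regime(); z$floor <- 0
  s <- generate_habitat_series(z, "2020-01-01", "2020-02-28", seed = 2)
  expect_gte(min(s$temp_c), 0)
})

test_that("August diel-range metric matches the configured peak-to-trough", {
  p <- regime_params(17.06, seasonal_amplitude = 0, diel_amplitude = 5,
                     noise_sd = 0.3)
  s <- generate_habitat_series(p, "2020-08-01", "2020-08-31", seed = 11)
  expect_equal(diel_range(daily_summaries(s)), 10, tolerance = 0.5)
})

test_that("scatter-free cohort lies exactly on the truth curves", {
  models <- salmonfly_models()["varney"]
  models$varney$rmr$rse <- 0
  models$varney$mmr$rse <- 0
  temps <- seq(8, 30, by = 2)
  coh <- generate_cohort(temp_grid = temps, populations = models, seed = 3,
                         noise_sd = 0)
  expect_equal(nrow(coh$metadata), length(temps))
  expect_equal(coh$metadata$test_temp_c, temps)
  mu_r <- evaluate_model(models$varney$rmr$model,
                         models$varney$rmr$coefficients, temps)
  got_r <- vapply(coh$truths, `[[`, 0, "rmr_true")
  expect_equal(unname(got_r), mu_r, tolerance = 1e-12)
})

test_that("cohorts are deterministic, valid, and reject empty grids", {
  a <- generate_cohort(seed = 9)
  b <- generate_cohort(seed = 9)
  expect_identical(a, b)
  for (tt in a$truths) {
    expect_gt(tt$rmr_true, 0)
    expect_gt(tt$mmr_true, tt$rmr_true)
  }
  expect_true(all(a$metadata$chamber_volume_ml >= 129 &
                    a$metadata$chamber_volume_ml <= 137))
  expect_true(all(a$metadata$dry_mass_g >= 0.034 &
                    a$metadata$dry_mass_g <= 0.311))
  expect_error(generate_cohort(temp_grid = numeric(0)), "empty")
})

test_that("trace and logger CSVs round-trip", {
  truth <- trial_truth(1e-3, 3e-3, 15, noise_sd = 0.05)
  p <- resp_protocol(seal_minutes = 5, flush_minutes = 2,
                     overnight_start = "19:00", overnight_end = "19:30",
                     chase_minutes = 14, sample_interval = 10)
  tr <- generate_respirometry_trace(truth, p, seed = 2, trial_id = "t1")
  f <- tempfile(fileext = ".csv")
  write_oxygen_trace(tr, f)
  back <- read_oxygen_trace(f, trial_id = "t1")
  expect_equal(back$do_saturation_pct, tr$do_saturation_pct, tolerance = 1e-6)
  expect_identical(back$phase, tr$phase)

  s <- generate_habitat_series(hebgen_regime(), "2020-08-01", "2020-08-05",
                               seed = 1)
  g <- tempfile(fileext = ".csv")
  write_logger_series(s, g)
  back2 <- read_logger_series(g)
  expect_equal(back2$temp_c, s$temp_c, tolerance = 1e-6)
})
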