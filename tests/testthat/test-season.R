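# Season windows, temperature summaries, pooling and phase rates.

test_that("detect_season_start: immediate, never, synthetic recovery", {
  t10 <- gen_temperature(100, 160, summer_mean = 10, diurnal_amp = 2.5,
                         noise_sd = 0, pre_days = 0, seed = 1)
  expect_equal(detect_season_start(t10), 100)
  flat <- gen_temperature(100, 160, summer_mean = 0.2, diurnal_amp = 0,
                          noise_sd = 0.05, seed = 1)
  expect_error(detect_season_start(flat), class = "no_season")
  hits <- 0
  for (i in 1:20) {
    tt <- gen_temperature(150 + i, 260 + i, seed = 100 + i)
    hits <- hits + (abs(detect_season_start(tt) - (150 + i)) <= 1)
  }
  expect_gte(hits / 20, 0.95)
})

test_that("season_end: configured dates and missing year", {
  expect_equal(season_end(2020), 269)  # 25 Sep in a leap year
  expect_equal(season_end(2021), 288)  # 15 Oct
  expect_error(season_end(1999), class = "missing_config")
})

test_that("mean_temp: constant series, generator truth, bad window", {
  t <- gen_temperature(100, 200, summer_mean = 10, diurnal_amp = 0,
                       noise_sd = 0, seed = 1)
  expect_equal(mean_temp(t, 100, 50), 10)
  tn <- gen_temperature(100, 200, summer_mean = 11, seed = 2)
  se <- 0.3 / sqrt(50 * 12)
  expect_lt(abs(mean_temp(tn, 100, 50) - 11), max(2 * se, 0.05))
  expect_error(mean_temp(t, 100, 0), class = "invalid_input")
  expect_error(mean_temp(t, 195, 50), class = "coverage")
})

test_that("gdh: base threshold, below-base zero, 2-h logging, additivity", {
  mk <- function(temp, step, days = 1) {
    hours <- seq(0, days * 24 - step, by = step)
    out <- data.frame(unit_id = "u", doy = 1 + hours / 24,
                      temp_C = rep(temp, length(hours)))
    class(out) <- c("temperature_series", "data.frame")
    attr(out, "step_hours") <- step
    out
  }
  expect_equal(gdh(mk(6, 1), 1, 2), 24)     # (6-5) x 24 h
  expect_equal(gdh(mk(4, 1), 1, 2), 0)
  expect_equal(gdh(mk(7, 2), 1, 2), 48)     # (7-5) x 2 h x 12 samples
  t2 <- mk(8, 2, days = 4)
  expect_equal(gdh(t2, 1, 3) + gdh(t2, 3, 5), gdh(t2, 1, 5))
})

test_that("pool_visits: means, unchanged when sparse, strict boundary", {
  p <- pool_visits(c(150, 153), c(4, 6))
  expect_equal(p$doy, 151.5)
  expect_equal(p$value, 5)
  sparse <- pool_visits(c(100, 110, 125), c(1, 2, 3))
  expect_equal(sparse$doy, c(100, 110, 125))
  exact7 <- pool_visits(c(100, 107), c(1, 3))
  expect_equal(nrow(exact7), 2)
  # pooling preserves the mean within the within-pool spread
  set.seed(3)
  d <- sort(sample(100:180, 12)); v <- rnorm(12, 5)
  pooled <- pool_visits(d, v)
  expect_lte(abs(mean(pooled$value) - mean(v)), diff(range(v)))
})

test_that("phase_rates: windows, exclusion near peak, browning sign, gdh", {
  s <- measurement_series("u", "g", "leaf_length_cm",
                          c(150, 160, 170, 186, 200, 214, 228),
                          c(0.5, 4.5, 8, 9.4, 8.5, 4.7, 2.5))
  peak <- 186; half <- 215
  r <- phase_rates(s, season_start = 150, peak_doy = peak,
                   half_decline_doy = half)
  elong <- r[r$phase == "elongation", ]
  brown <- r[r$phase == "browning", ]
  # first pair 150->160 inside [150, 172]: rate 4/10
  expect_equal(elong$rate[1], 0.4)
  # pair 160->170 ends before peak-14 = 172: included; 170->186 straddles
  expect_equal(nrow(elong), 2)
  # browning pairs within [200, 222]: only 200->214
  expect_equal(nrow(brown), 1)
  expect_equal(brown$rate, (4.7 - 8.5) / 14)
  expect_lt(brown$rate, 0)
  # temperature attachment
  t <- gen_temperature(140, 240, summer_mean = 8, diurnal_amp = 0,
                       noise_sd = 0, seed = 1)
  r2 <- phase_rates(s, 150, peak, half, temperature = t)
  expect_equal(r2$gdh[1], 3 * 24 * 10, tolerance = 1e-9)  # (8-5) x 10 d
  # no qualifying interval -> empty frame
  empty <- phase_rates(s[1:2, ], 150, 151, NA)
  expect_equal(nrow(empty), 0)
})
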