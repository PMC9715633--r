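# Scaling, smoothing and phenological timepoint extraction.

test_that("scale_series: proportional map, zeroing, idempotence", {
  s <- measurement_series("u", "g", "greenness", c(1, 2, 3), c(2, 4, 8))
  expect_equal(scale_series(s)$value, c(25, 50, 100))
  r <- measurement_series("u", "g", "root_area", c(1, 2, 3, 4),
                          c(5, 5, 15, 25))
  expect_equal(scale_series(r, zero_at_start = TRUE)$value, c(0, 0, 50, 100))
  once <- scale_series(s)
  expect_equal(scale_series(once)$value, once$value)
  const <- measurement_series("u", "g", "greenness", 1:3, rep(4, 3))
  expect_error(scale_series(const), class = "degenerate_scaling")
})

test_that("fit_smoother: exact line, MSE bound, insufficient data", {
  s <- measurement_series("u", "g", "greenness", seq(100, 160, 5),
                          seq(0, 60, 5))
  fit <- fit_smoother(s)
  expect_gte(fit$r2, 0.999)
  expect_lt(max(abs(diff(fit$fitted) - 1)), 0.05)   # near-unit daily slope
  set.seed(2)
  s2 <- measurement_series("u", "g", "greenness", seq(100, 190, 6),
                           50 + 30 * sin(seq(0, 3, length.out = 16)) +
                             rnorm(16, 0, 3))
  f2 <- fit_smoother(s2)
  pred <- f2$fitted[match(s2$doy, f2$grid)]
  expect_lte(mean((s2$value - pred)^2), var(s2$value))
  short <- measurement_series("u", "g", "greenness", 1:3, c(1, 2, 3))
  expect_error(fit_smoother(short), class = "insufficient_data")
})

test_that("fit_smoother recovers a noisy synthetic hump within 2 days", {
  for (seed in c(1, 2, 3)) {
    tr <- gen_trajectory("greenness", season_start = 150, seed = seed,
                         noise_sd = 0.42 * 0.03)  # 3% of peak
    s <- scale_series(tr$series)
    fit <- fit_smoother(s)
    expect_lte(abs(peak_date(fit) - tr$truth$true_peak_doy), 2)
  }
})

test_that("peak_date: argmax, plateau tie rule, boundary warning", {
  tri <- fake_fit(190:210, c(0:10, 9:0))
  expect_equal(peak_date(tri), 200)
  plat <- fake_fit(148:158, c(0, 1, 5, 5, 5, 5, 5, 5, 2, 1, 0))
  expect_equal(peak_date(plat), 150)
  rising <- fake_fit(1:10, 1:10)
  expect_warning(p <- peak_date(rising), class = "boundary_peak")
  expect_equal(p, 10)
})

test_that("half_decline_date: interpolation, exact hit, sentinel", {
  s <- measurement_series("u", "g", "greenness", c(90, 100, 110),
                          c(100, 80, 40))
  expect_equal(half_decline_date(s, 90, peak_value = 100), 107.5)
  s2 <- measurement_series("u", "g", "greenness", c(90, 120),
                           c(100, 50))
  expect_equal(half_decline_date(s2, 90, peak_value = 100), 120)
  s3 <- measurement_series("u", "g", "greenness", c(90, 100, 110),
                           c(100, 90, 60))
  expect_true(is.na(half_decline_date(s3, 90, peak_value = 100)))
})

test_that("quantile_date: ramp inversion, q = 1, validation", {
  ramp <- fake_fit(100:200, seq(0, 100, 1))
  expect_equal(quantile_date(ramp, 0.8), 180)
  expect_equal(quantile_date(ramp, 1), 200)
  expect_equal(quantile_date(ramp, 1), ramp$grid[which.max(ramp$fitted)])
  expect_error(quantile_date(ramp, 0), class = "invalid_input")
  expect_error(quantile_date(ramp, 1.1), class = "invalid_input")
  # synthetic root curve: q80 within 1.5 d at low noise
  tr <- gen_trajectory("root", season_start = 150, noise_sd = 0.1, seed = 4)
  sr <- scale_series(tr$series, zero_at_start = TRUE)
  fr <- fit_smoother(sr, cumulative_smoother_config())
  expect_lte(abs(quantile_date(fr, 0.8) - tr$truth$true_q80_doy), 1.5)
})

test_that("max_rate_date: logistic inflection, ramp tie, decline flag", {
  t <- 100:220
  logi <- fake_fit(t, 100 * plogis((t - 160) / 12))
  expect_lte(abs(max_rate_date(logi) - 160), 1)
  ramp <- fake_fit(100:120, seq(0, 20, 1))
  expect_equal(max_rate_date(ramp), 100)
  dec <- fake_fit(100:120, seq(20, 0, -1))
  expect_warning(max_rate_date(dec), class = "no_growth")
})

test_that("auc_fit: constant, triangle vs trapezoid oracle, additivity", {
  const <- fake_fit(1:10, rep(100, 10))
  expect_equal(auc_fit(const, 1, 10), 1000)
  tri <- fake_fit(100:120, c(seq(0, 100, 10), seq(90, 0, -10)))
  expect_lt(abs(auc_fit(tri, 100, 120) -
                oracle_trapz(100:120, tri$fitted)), 0.051 * 1000)
  split <- auc_fit(tri, 100, 110) + auc_fit(tri, 111, 120)
  expect_equal(split, auc_fit(tri, 100, 120))
  expect_error(auc_fit(tri, 300, 310), class = "invalid_window")
  neg <- fake_fit(1:5, c(-5, -1, 2, 4, 6))
  expect_equal(auc_fit(neg, 1, 5), 12)  # negatives clipped to zero
})

test_that("root_onset: window OLS rule, boundary, sentinel", {
  s <- measurement_series("u", "g", "root_area",
                          c(100, 105, 110, 115, 120, 125),
                          c(0, 0, 0, 1, 6, 11))
  expect_equal(root_onset(s), 110)
  zero <- measurement_series("u", "g", "root_area", c(1, 5, 9), c(0, 0, 0))
  expect_true(is.na(root_onset(zero)))
  # exact 0.5 %/d ramp: strict inequality, never starts
  ramp <- measurement_series("u", "g", "root_area", seq(0, 40, 10),
                             seq(0, 20, 5))
  expect_true(is.na(root_onset(ramp)))
})

test_that("root_onset agrees with the brute-force oracle on random series", {
  set.seed(7)
  for (i in 1:40) {
    n <- sample(4:10, 1)
    doy <- sort(sample(100:200, n))
    val <- cumsum(pmax(rnorm(n, 0.5), 0)) * sample(c(0.5, 2, 6), 1)
    s <- measurement_series("u", "g", "root_area", doy, val)
    expect_equal(root_onset(s), as.numeric(oracle_root_onset(doy, val)))
  }
})

test_that("edge stability: duplicating a measurement moves the peak <= 1 d", {
  tr <- gen_trajectory("greenness", season_start = 150, seed = 11)
  s <- scale_series(tr$series)
  p1 <- peak_date(fit_smoother(s))
  # duplicate an interior measurement at an adjacent (distinct) day
  i <- 8
  s2 <- measurement_series("u", "g", "greenness",
                           sort(c(s$doy, s$doy[i] + 1)),
                           append(s$value, s$value[i], after = i))
  p2 <- peak_date(fit_smoother(s2))
  expect_lte(abs(p2 - p1), 1)
})

test_that("pheno_metrics composes all extractors coherently", {
  tr <- gen_trajectory("root", season_start = 150, seed = 13)
  s <- scale_series(tr$series, zero_at_start = TRUE)
  m <- pheno_metrics(s, 150, 270)
  expect_true(m$onset_doy <= m$q50_doy && m$q50_doy <= m$q80_doy)
  expect_gte(m$auc, 0)
  expect_equal(m$days_to_peak, m$peak_doy - 150)
})
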