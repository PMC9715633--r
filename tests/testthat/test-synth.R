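# Synthetic-data generators: temperature, trajectories, canopy images,
# rhizotron stacks.

test_that("gen_temperature: degenerate noise-free case is exactly constant", {
  t <- gen_temperature(100, 150, summer_mean = 10, diurnal_amp = 0,
                       noise_sd = 0, seed = 1)
  post <- t$temp_C[t$doy >= 100]
  expect_true(all(post == 10))
})

test_that("gen_temperature: summer mean and detectability", {
  t <- gen_temperature(170, 280, summer_mean = 10.5, seed = 7)
  # mean of first 50 post-start days within 2 SE of generated noise
  keep <- t$doy >= 170 & t$doy < 220
  se <- 0.3 / sqrt(sum(keep))  # sinusoid contributes ~0 over whole days
  expect_lt(abs(mean(t$temp_C[keep]) - 10.5), max(2 * se, 0.05))
  # season-start detector recovers the programmed melt day within 1 d
  expect_lte(abs(detect_season_start(t) - 170), 1)
})

test_that("gen_temperature: reproducibility and input validation", {
  a <- gen_temperature(100, 200, seed = 42)
  b <- gen_temperature(100, 200, seed = 42)
  expect_identical(a, b)
  expect_error(gen_temperature(200, 100), class = "invalid_input")
  expect_error(gen_temperature(100, 200, step = 3), class = "invalid_input")
})

test_that("gen_trajectory: symmetric shape peaks exactly at the midpoint", {
  p <- list(rise_mid = 190, rise_scale = 8, decline_mid = 210,
            decline_scale = 8, peak_value = 100, baseline = 0,
            second_greening_amp = 0)
  tr <- gen_trajectory("greenness", season_start = 100, season_end = 300,
                       sampling_dates = 100:300, params = p, noise_sd = 0)
  expect_equal(tr$truth$true_peak_doy, 200, tolerance = 1e-6)
})

test_that("gen_trajectory: truth records are consistent with the curve", {
  for (seed in 1:6) {
    kind <- c("leaf", "greenness", "root")[(seed %% 3) + 1]
    tr <- gen_trajectory(kind, season_start = 150, seed = seed)
    f <- tr$truth$curve
    tg <- seq(150, 270, by = 0.01)
    # peak reproduces the maximum
    expect_lt(max(f(tg)) - f(tr$truth$true_peak_doy), 1e-7)
    # half-decline sits at 50% of peak
    if (!is.na(tr$truth$true_half_decline_doy))
      expect_lt(abs(f(tr$truth$true_half_decline_doy) -
                    0.5 * tr$truth$peak_value), 1e-9)
    if (kind == "root") {
      # 80% quantile of final gain
      expect_lt(abs(f(tr$truth$true_q80_doy) - 0.8 * f(270)), 1e-9)
      expect_gte(tr$truth$true_root_onset_doy, 150)
    }
  }
})

test_that("gen_trajectory: root q80 matches the logistic closed form", {
  p <- list(total_gain = 15, root_mid = 200, root_scale = 10, late_loss = 0)
  tr <- gen_trajectory("root", season_start = 160, season_end = 290,
                       params = p, noise_sd = 0)
  # closed form: sigma(t) = s0 + 0.8 * (s_end - s0)
  s0 <- plogis((160 - 200) / 10); s_end <- plogis((290 - 200) / 10)
  d_star <- 200 + 10 * qlogis(s0 + 0.8 * (s_end - s0))
  expect_equal(tr$truth$true_q80_doy, d_star, tolerance = 1e-6)
})

test_that("gen_trajectory: second greening creates a late local maximum", {
  p <- list(second_greening_amp = 0.36)
  tr <- gen_trajectory("greenness", season_start = 100, season_end = 260,
                       params = p, noise_sd = 0,
                       sampling_dates = 100:260)
  v <- tr$series$value
  half <- tr$truth$true_half_decline_doy
  late <- which(tr$series$doy > half)
  dv <- diff(v[late])
  expect_true(any(dv > 0))           # rises again after the half decline
  expect_lt(max(v[late]), max(v))    # but stays below the main peak
})

test_that("gen_trajectory: leaf baseline, determinism, degenerate input", {
  tr <- gen_trajectory("leaf", season_start = 150, noise_sd = 0)
  expect_equal(tr$series$value[1], 0.5, tolerance = 1e-6)
  a <- gen_trajectory("leaf", season_start = 150, seed = 3)
  b <- gen_trajectory("leaf", season_start = 150, seed = 3)
  expect_identical(a$series$value, b$series$value)
  expect_error(
    gen_trajectory("leaf", season_start = 150,
                   sampling_dates = c(120, 125, 130, 135)),
    class = "degenerate_series")
})

test_that("gen_canopy_image: closed-form greenness of pure fields", {
  g <- gen_canopy_image(32, 32, 1, green_rgb = c(0, 255, 0))
  expect_equal(canopy_greenness(g$image), 1)
  a <- gen_canopy_image(32, 32, 0, brown_rgb = c(100, 100, 100))
  expect_equal(canopy_greenness(a$image), 1 / 3)
  m <- gen_canopy_image(64, 64, 0.5, green_rgb = c(0, 255, 0),
                        brown_rgb = c(255, 0, 0), seed = 1)
  expect_equal(canopy_greenness(m$image), 0.5)
  expect_equal(m$truth$expected_greenness, 0.5)
})

test_that("gen_canopy_image: realised fraction exact to one pixel", {
  for (f in c(0.1, 0.37, 0.9)) {
    g <- gen_canopy_image(50, 40, f, seed = 2)
    expect_lt(abs(g$truth$true_green_fraction - f), 1 / (50 * 40))
  }
  expect_error(gen_canopy_image(10, 10, 1.2), class = "invalid_input")
})

test_that("gen_rhizotron_stack: truth masks match scheduled areas within 2%", {
  sched <- c(0.4, 0.8, 1.2)
  st <- gen_rhizotron_stack(3, 256, 256, root_schedule = sched, seed = 5)
  px_mm <- 25.4 / st$dpi
  img_area_cm2 <- 256 * 256 * px_mm^2 / 100
  for (d in 1:3) {
    # mask/area consistency: truth area = pixel count x pixel area
    expect_equal(st$true_area_mm2_cm2[d],
                 sum(st$masks[[d]]) * px_mm^2 / img_area_cm2,
                 tolerance = 1e-12)
    # scheduled area hit within 2%
    expect_lt(abs(st$true_area_mm2_cm2[d] - sched[d]) / sched[d], 0.02)
  }
  expect_true(all(diff(st$true_area_px) >= 0))
})

test_that("gen_rhizotron_stack: determinism and input validation", {
  a <- gen_rhizotron_stack(2, 64, 64, seed = 8)
  b <- gen_rhizotron_stack(2, 64, 64, seed = 8)
  expect_identical(a$images, b$images)
  expect_error(gen_rhizotron_stack(2, 64, 64, root_schedule = c(1, 2, 3)),
               class = "invalid_input")
  expect_error(gen_rhizotron_stack(2, 64, 64, root_schedule = c(2, 1)),
               class = "invalid_input")
  expect_error(gen_rhizotron_stack(2, 64, 64,
                                   shifts = rbind(c(0, 0), c(40, 0))),
               class = "invalid_input")
})
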