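# Benchmark computations used by the acceptance tests and the acceptance
# report script. Every quantity is measured at run time by executing the
# package's own operators on freshly generated synthetic data with known
# ground truth.

# Unit-level shape jitter matching synth_study().
jitter_params <- function(p, kind, seed) {
  jit <- with_seed(seed, list(shift = rnorm(1, 0, 2),
                              stretch = exp(rnorm(1, 0, 0.06)),
                              amp = exp(rnorm(1, 0, 0.08))))
  if (kind == "root") {
    p$root_mid <- p$root_mid + jit$shift
    p$root_scale <- p$root_scale * jit$stretch
    p$total_gain <- p$total_gain * jit$amp
  } else {
    p$rise_mid <- p$rise_mid + jit$shift
    p$decline_mid <- p$decline_mid + jit$shift
    p$decline_scale <- p$decline_scale * jit$stretch
    p$peak_value <- p$peak_value * jit$amp
  }
  p
}

#' Phenodate-recovery benchmark
#'
#' Generates `n_units` synthetic experimental units (alternating leaf and
#' greenness hump trajectories plus one cumulative root trajectory each) at
#' default noise and paper-like sampling, runs the package's scaling,
#' smoothing and timepoint extractors, and compares against the known
#' ground truth.
#'
#' @param n_units number of synthetic units.
#' @param seed master seed.
#' @param season_start day of year the synthetic season starts.
#' @return List with `peak_mae`, `half_mae`, `q80_mae` (median absolute
#'   errors in days), `mean_r2` (across all fits) and the per-unit error
#'   vectors.
#' @export
recovery_benchmark <- function(n_units = 200, seed = 1, season_start = 166) {
  ep <- eh <- eq <- r2 <- numeric(0)
  for (i in seq_len(n_units)) {
    kind <- if (i %% 2 == 0) "leaf" else "greenness"
    p <- jitter_params(default_trajectory_params(kind, season_start), kind,
                       child_seed(seed, 3 * i))
    tr <- gen_trajectory(kind, season_start = season_start, params = p,
                         unit_id = sprintf("u%03d", i),
                         seed = child_seed(seed, 3 * i + 1))
    s <- scale_series(tr$series)
    m <- pheno_metrics(s, season_start, max(s$doy))
    ep <- c(ep, m$peak_doy - tr$truth$true_peak_doy)
    eh <- c(eh, m$half_decline_doy - tr$truth$true_half_decline_doy)
    r2 <- c(r2, m$r2)

    pr <- jitter_params(default_trajectory_params("root", season_start),
                        "root", child_seed(seed, 3 * i + 2))
    rt <- gen_trajectory("root", season_start = season_start, params = pr,
                         unit_id = sprintf("u%03d", i),
                         seed = child_seed(seed, 90000 + i))
    sr <- scale_series(rt$series, zero_at_start = TRUE)
    mr <- pheno_metrics(sr, season_start, max(sr$doy))
    eq <- c(eq, mr$q80_doy - rt$truth$true_q80_doy)
    r2 <- c(r2, mr$r2)
  }
  list(peak_mae = stats::median(abs(ep)),
       half_mae = stats::median(abs(eh), na.rm = TRUE),
       q80_mae = stats::median(abs(eq)),
       mean_r2 = mean(r2),
       peak_err = ep, half_err = eh, q80_err = eq, r2 = r2)
}

#' Root-onset rule vs brute-force oracle
#'
#' Draws random small scaled root series and checks [root_onset()] against
#' an independent brute-force implementation that fits `lm()` on every
#' window of three adjacent dates.
#'
#' @param n number of random series.
#' @param seed master seed.
#' @return List with `agreement` (fraction identical, NA-safe) and `n`.
#' @export
onset_benchmark <- function(n = 1000, seed = 1) {
  oracle <- function(doy, value, threshold = 0.5) {
    for (i in seq_len(length(doy) - 2)) {
      b <- stats::coef(stats::lm(value[i:(i + 2)] ~ doy[i:(i + 2)]))[2]
      if (b > threshold) return(doy[i])
    }
    NA_real_
  }
  ok <- logical(n)
  with_seed(seed, {
    for (i in seq_len(n)) {
      len <- sample(3:12, 1)
      doy <- sort(sample(100:230, len))
      value <- cumsum(pmax(rnorm(len, 0.4), 0)) * sample(c(0.3, 1, 3, 8), 1)
      s <- measurement_series("u", "g", "root_area", doy, value)
      a <- root_onset(s)
      b <- oracle(doy, value)
      ok[i] <- (is.na(a) && is.na(b)) || (!is.na(a) && !is.na(b) && a == b)
    }
  })
  list(agreement = mean(ok), n = n)
}

#' Daily-interval AUC vs trapezoid oracle
#'
#' Generates random noise-free seasonal curves, integrates them with
#' [auc_fit()] (daily rectangle rule, as used for greenness) and compares
#' with trapezoidal integration of the same daily curve.
#'
#' @param n number of random curves.
#' @param seed master seed.
#' @return List with `max_rel_err` and `n`.
#' @export
auc_benchmark <- function(n = 100, seed = 1) {
  rel <- numeric(n)
  for (i in seq_len(n)) {
    p <- jitter_params(default_trajectory_params("greenness", 150),
                       "greenness", child_seed(seed, 7000 + i))
    tr <- gen_trajectory("greenness", season_start = 150, params = p,
                         noise_sd = 0)
    grid <- 150:270
    scaled <- 100 * tr$truth$curve(grid) / tr$truth$peak_value
    fit <- structure(list(grid = grid, fitted = scaled), class = "smooth_fit")
    a <- auc_fit(fit, 150, 270)
    v <- pmax(scaled, 0)
    trap <- sum((v[-1] + v[-length(v)]) / 2)
    rel[i] <- abs(a - trap) / trap
  }
  list(max_rel_err = max(rel), n = n)
}

#' Imaging-chain benchmark
#'
#' On 512 x 512 synthetic rhizotron fixtures: exact shift recovery on a
#' clean stack, shift recovery at default noise, destriping attenuation,
#' segmentation pixel F1 against the truth masks, and the root-area
#' arithmetic against its closed form.
#'
#' @param seed master seed.
#' @param size fixture edge length in px.
#' @return List with `align_err_clean`, `align_err_noisy` (max abs shift
#'   error, px), `destripe_factor`, `seg_f1` (minimum over dates),
#'   `area_arith_err`, `area_rel_err` (max over dates), `area_r`.
#' @export
imaging_benchmark <- function(seed = 1, size = 512) {
  shifts <- rbind(c(0, 0), c(5, -3), c(-9, 7), c(12, 10))
  clean <- gen_rhizotron_stack(4, size, size, stripe_amp = 0, noise_sd = 0,
                               root_schedule = rep(1, 4), shifts = shifts,
                               seed = child_seed(seed, 1))
  ac <- align_stack(clean)
  err_clean <- max(abs(ac$shifts - shifts))

  noisy <- gen_rhizotron_stack(4, size, size,
                               root_schedule = c(0.5, 1, 1.4, 1.6),
                               shifts = shifts, seed = child_seed(seed, 2))
  pr <- process_stack(noisy)
  err_noisy <- max(abs(pr$shifts - shifts))
  f1 <- vapply(seq_along(noisy$masks), function(d) {
    tp <- sum(pr$seg_masks[[d]] & noisy$masks[[d]])
    2 * tp / (sum(pr$seg_masks[[d]]) + sum(noisy$masks[[d]]))
  }, numeric(1))
  rel <- abs(pr$root_area - noisy$true_area_mm2_cm2) / noisy$true_area_mm2_cm2

  bg <- with_seed(child_seed(seed, 3), noise_texture(size, size))
  stripes <- with_seed(child_seed(seed, 4),
                       matrix(rnorm(size, 0, 20 / 255), size, size,
                              byrow = TRUE))
  ds <- destripe(bg + stripes)
  factor <- sqrt(mean(stripes^2)) / sqrt(mean((ds - bg)^2))

  mask <- matrix(FALSE, 2196, 2550)
  mask[seq_len(10000)] <- TRUE
  ra <- root_area(mask, 1200)
  arith_err <- abs(ra$area_mm2 - (25.4 / 1200)^2 * 10000)

  list(align_err_clean = err_clean, align_err_noisy = err_noisy,
       destripe_factor = factor, seg_f1 = min(f1),
       area_arith_err = arith_err, area_rel_err = max(rel),
       area_r = stats::cor(pr$root_area, noisy$true_area_mm2_cm2))
}

#' Statistics oracles benchmark
#'
#' Compares [group_contrasts()] with the closed-form pooled two-sample t
#' statistic and [simple_regression()] with the closed-form OLS expressions
#' on random inputs.
#'
#' @param n random replicates.
#' @param seed master seed.
#' @return List with `contrast_max_err` and `ols_max_err`.
#' @export
stats_benchmark <- function(n = 50, seed = 1) {
  ce <- oe <- 0
  with_seed(seed, {
    for (i in seq_len(n)) {
      a <- rnorm(sample(3:10, 1)); b <- rnorm(sample(3:10, 1), 0.5)
      ct <- group_contrasts(c(a, b), rep(c("A", "B"), c(length(a), length(b))))
      na <- length(a); nb <- length(b)
      sp2 <- ((na - 1) * stats::var(a) + (nb - 1) * stats::var(b)) /
        (na + nb - 2)
      t_ref <- (mean(b) - mean(a)) / sqrt(sp2 * (1 / na + 1 / nb))
      ce <- max(ce, abs(ct$t - t_ref))

      x <- rnorm(sample(5:30, 1)); y <- rnorm(length(x), x)
      r <- simple_regression(y, x)
      sxx <- sum((x - mean(x))^2)
      slope <- sum((x - mean(x)) * (y - mean(y))) / sxx
      res <- y - (mean(y) - slope * mean(x)) - slope * x
      se <- sqrt(sum(res^2) / (length(x) - 2) / sxx)
      oe <- max(oe, abs(r$slope - slope), abs(r$se_slope - se))
    }
  })
  list(contrast_max_err = ce, ols_max_err = oe)
}

#' End-to-end anchoring benchmark
#'
#' Runs the full pipeline on two synthetic studies: one in which trajectory
#' shapes are anchored to each group's season start (growth follows the
#' local season; between-group days-to-peak contrasts should vanish) and one
#' anchored to the calendar (growth happens on fixed dates; days-to-peak
#' contrasts should equal the programmed season-start offsets).
#'
#' @param seed master seed.
#' @return List with `season_max_abs_contrast`, `season_min_p`,
#'   `calendar_max_dev` (max deviation of contrast estimates from the
#'   programmed offsets, days) and the contrast tables.
#' @export
anchoring_benchmark <- function(seed = 1) {
  run_one <- function(anchor) {
    cfg <- run_config(seed = seed, anchor = anchor)
    res <- run_pipeline(cfg)
    ct <- res$contrasts
    ct[ct$variable == "greenness", ]
  }
  cs <- run_one("season")
  cc <- run_one("calendar")
  starts <- c(plus4m = 49, plus2m = 113, field = 183)
  expected <- vapply(seq_len(nrow(cc)), function(i) {
    parts <- strsplit(cc$label[i], " - ")[[1]]
    # days_to_peak = peak_cal - start; contrast = start[first] - start[second]
    starts[parts[2]] - starts[parts[1]]
  }, numeric(1))
  list(season_max_abs_contrast = max(abs(cs$estimate)),
       season_min_p = min(cs$p),
       calendar_max_dev = max(abs(cc$estimate - expected)),
       season_contrasts = cs, calendar_contrasts = cc)
}
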