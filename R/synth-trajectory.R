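# Synthetic seasonal growth trajectories with analytic ground truth.
#
# Aboveground variables (leaf length, canopy greenness, vigour) follow a
# product of a rising and a declining logistic, re-anchored so the curve
# starts at its baseline at season start and tops out at the prescribed peak
# value; community greenness may carry an additive Gaussian "second
# greening" bump late in the season. Root area is a cumulative logistic
# gain, optionally multiplied by a late-loss factor.

#' Construct a measurement series
#'
#' The basic per-unit time series container: one variable for one
#' experimental unit over day-of-year.
#'
#' @param unit_id,group identifiers.
#' @param variable one of `"leaf_length_cm"`, `"greenness"`, `"root_area"`,
#'   `"vigour"`.
#' @param doy strictly increasing day-of-year vector.
#' @param value measurements, same length as `doy`.
#' @param scaled logical: values are percent-of-maximum (0--100).
#' @return A `measurement_series` data.frame.
#' @export
measurement_series <- function(unit_id, group, variable, doy, value,
                               scaled = FALSE) {
  stopifnot(length(doy) == length(value))
  if (is.unsorted(doy, strictly = TRUE))
    stop_ap("invalid_input", "doy must be strictly increasing")
  out <- data.frame(unit_id = unit_id, group = group, variable = variable,
                    doy = as.numeric(doy), value = as.numeric(value),
                    stringsAsFactors = FALSE)
  class(out) <- c("measurement_series", "data.frame")
  attr(out, "scaled") <- scaled
  out
}

#' Default trajectory parameters for a variable kind
#'
#' Shapes are anchored to the start of the growing season: leaf length peaks
#' around 43 days and greenness around 39 days after season start, root gain
#' follows a cumulative logistic with midpoint 38 days after start (onset of
#' detectable growth around day 10, 80 percent of gain near day 52). Peak
#' leaf length defaults to 9.4 cm and total root gain to 15 mm2 cm-2.
#'
#' @param kind `"leaf"`, `"greenness"`, `"root"` or `"vigour"`.
#' @param season_start day of year growth conditions begin.
#' @return Named list of shape parameters (absolute day-of-year positions).
#' @export
default_trajectory_params <- function(kind = c("leaf", "greenness", "root",
                                               "vigour"),
                                      season_start) {
  kind <- match.arg(kind)
  s <- season_start
  switch(kind,
    leaf = list(baseline = 0.5, peak_value = 9.4,
                rise_mid = s + 18, rise_scale = 6,
                decline_mid = s + 80, decline_scale = 11,
                second_greening_amp = 0, second_greening_doy = s + 120,
                second_greening_sd = 15),
    greenness = ,
    vigour = list(baseline = 0, peak_value = if (kind == "greenness") 0.42 else 100,
                  rise_mid = s + 16, rise_scale = 6,
                  decline_mid = s + 76, decline_scale = 11,
                  second_greening_amp = 0, second_greening_doy = s + 120,
                  second_greening_sd = 15),
    root = list(total_gain = 15, root_mid = s + 38, root_scale = 10,
                late_loss = 0, late_loss_mid = s + 130, late_loss_scale = 12)
  )
}

# Noise-free curve factory. Returns function f(t) on raw measurement scale.
trajectory_fun <- function(kind, p, season_start, season_end) {
  if (kind == "root") {
    g <- function(t) {
      gain <- p$total_gain *
        (stats::plogis((t - p$root_mid) / p$root_scale) -
         stats::plogis((season_start - p$root_mid) / p$root_scale))
      if (p$late_loss > 0)
        gain <- gain * (1 - p$late_loss *
                          stats::plogis((t - p$late_loss_mid) / p$late_loss_scale))
      pmax(gain, 0)
    }
    return(g)
  }
  f0 <- function(t)
    stats::plogis((t - p$rise_mid) / p$rise_scale) *
    stats::plogis(-(t - p$decline_mid) / p$decline_scale)
  tg <- seq(season_start, season_end, by = 0.05)
  v0 <- f0(season_start)
  m <- max(f0(tg))
  if (m - v0 <= 0) stop_ap("invalid_input", "degenerate trajectory shape")
  function(t) {
    base <- p$baseline + (p$peak_value - p$baseline) *
      pmax(f0(t) - v0, 0) / (m - v0)
    if (p$second_greening_amp > 0)
      base <- base + p$second_greening_amp * p$peak_value *
        exp(-(t - p$second_greening_doy)^2 / (2 * p$second_greening_sd^2))
    base
  }
}

#' Paper-like sampling schedule
#'
#' Twice-weekly visits during the first month after season start, then
#' regular visits every `later_interval` days until season end (field
#' campaigns revisited at 7--21 day intervals after the initial month).
#'
#' @param season_start,season_end day-of-year window.
#' @param later_interval revisit interval after the first month (days).
#' @return Integer day-of-year vector.
#' @export
sampling_schedule <- function(season_start, season_end, later_interval = 12) {
  dense <- season_start + c(0, 4, 7, 11, 14, 18, 21, 25, 28)
  sparse <- seq(season_start + 28 + later_interval, season_end,
                by = later_interval)
  d <- unique(round(c(dense, sparse)))
  d[d <= season_end]
}

# Locate truth dates on the noise-free curve to ~1e-10 day precision.
refine_max <- function(f, lo, hi) {
  tg <- seq(lo, hi, by = 0.02)
  i <- which.max(f(tg))
  o <- stats::optimize(f, lower = tg[max(1, i - 2)], upper = tg[min(length(tg), i + 2)],
                       maximum = TRUE, tol = 1e-10)
  o$maximum
}

first_crossing <- function(f, level, lo, hi, decreasing = TRUE) {
  tg <- seq(lo, hi, by = 0.02)
  v <- f(tg) - level
  idx <- if (decreasing) which(v[-1] <= 0 & v[-length(v)] > 0)
         else which(v[-1] >= 0 & v[-length(v)] < 0)
  if (!length(idx)) return(NA_real_)
  i <- idx[1]
  stats::uniroot(function(t) f(t) - level, lower = tg[i], upper = tg[i + 1],
                 tol = 1e-10)$root
}

#' Generate a synthetic growth trajectory with ground truth
#'
#' Draws noisy measurements of one seasonal variable at the given sampling
#' dates and returns them together with a `truth_record` holding the exact
#' phenological dates of the underlying noise-free curve (peak, half-decline,
#' root-growth onset and 80 percent quantile, area under the scaled curve).
#'
#' @param kind `"leaf"`, `"greenness"`, `"root"` or `"vigour"`.
#' @param season_start,season_end day-of-year season window.
#' @param sampling_dates day-of-year measurement dates; default
#'   [sampling_schedule()].
#' @param params shape parameters; missing entries filled from
#'   [default_trajectory_params()].
#' @param noise_sd sd of additive Gaussian measurement noise, in raw units
#'   (defaults: 0.4 cm leaf length, 0.012 greenness, 0.5 mm2 cm-2 root area,
#'   4 vigour-percent).
#' @param unit_id,group identifiers.
#' @param seed integer seed; identical seeds give bit-identical output.
#' @return List of class `trajectory` with elements `series`
#'   (a [measurement_series()]) and `truth` (a `truth_record` list with
#'   `true_peak_doy`, `true_half_decline_doy`, `true_root_onset_doy`,
#'   `true_q80_doy`, `true_auc`, `curve` = the noise-free function).
#' @export
gen_trajectory <- function(kind = c("leaf", "greenness", "root", "vigour"),
                           season_start = 166, season_end = season_start + 120,
                           sampling_dates = NULL, params = list(),
                           noise_sd = NULL, unit_id = "u1", group = "field",
                           seed = NULL) {
  kind <- match.arg(kind)
  p <- utils::modifyList(default_trajectory_params(kind, season_start), params)
  if (kind != "root" && (p$rise_scale <= 0 || p$decline_scale <= 0))
    stop_ap("invalid_input", "rate scales must be > 0")
  if (kind == "root" && p$root_scale <= 0)
    stop_ap("invalid_input", "rate scales must be > 0")
  sampling_dates <- sampling_dates %||% sampling_schedule(season_start, season_end)
  if (is.unsorted(sampling_dates, strictly = TRUE))
    stop_ap("invalid_input", "sampling dates must be strictly increasing")
  noise_sd <- noise_sd %||%
    switch(kind, leaf = 0.4, greenness = 0.012, root = 0.5, vigour = 4)
  f <- trajectory_fun(kind, p, season_start, season_end)

  clean <- f(sampling_dates)
  base <- if (kind == "root") 0 else if (kind == "leaf") p$baseline else 0
  amp <- max(f(seq(season_start, season_end, by = 0.25))) - base
  if (max(clean) - base < 0.01 * amp)
    stop_ap("degenerate_series",
            "sampling dates fall entirely before trajectory onset")

  # --- ground truth from the noise-free curve ------------------------------
  true_peak <- refine_max(f, season_start, season_end)
  fmax <- f(true_peak)
  true_half <- first_crossing(f, 0.5 * fmax, true_peak, season_end)
  grid <- season_start:season_end
  if (kind == "root") {
    gain_end <- f(season_end)
    scaled_grid <- 100 * f(grid) / fmax
    true_q80 <- first_crossing(f, 0.8 * gain_end, season_start, season_end,
                               decreasing = FALSE)
    # onset: first day the scaled (percent of max) curve grows > 0.5 %/d
    sf <- function(t) 100 * f(t) / fmax
    dsf <- function(t) (sf(t + 0.005) - sf(t - 0.005)) / 0.01
    true_onset <- first_crossing(dsf, 0.5, season_start, true_peak,
                                 decreasing = FALSE)
  } else {
    scaled_grid <- 100 * f(grid) / fmax
    true_q80 <- NA_real_
    true_onset <- NA_real_
  }
  truth <- structure(list(
    unit_id = unit_id,
    kind = kind,
    true_peak_doy = true_peak,
    true_half_decline_doy = true_half,
    true_root_onset_doy = true_onset,
    true_q80_doy = true_q80,
    true_auc = sum(pmax(scaled_grid, 0)),
    peak_value = fmax,
    curve = f
  ), class = "truth_record")

  value <- with_seed(seed, clean + rnorm(length(clean), 0, noise_sd))
  if (kind %in% c("leaf", "root")) value <- pmax(value, 0)
  variable <- switch(kind, leaf = "leaf_length_cm", greenness = "greenness",
                     root = "root_area", vigour = "vigour")
  structure(list(
    series = measurement_series(unit_id, group, variable, sampling_dates, value),
    truth = truth
  ), class = "trajectory")
}
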