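# Season windows and temperature summaries: snowmelt detection from soil
# temperature, configured season ends, interval means, growing degree hours,
# visit pooling, and phase-restricted elongation/browning rates.

#' Detect the start of the growing season from soil temperature
#'
#' Snow disappearance shows up in shallow soil-temperature logs as the first
#' day with mean temperature above `temp_floor` (3 degC) together with the
#' return of diurnal temperature fluctuations. The day qualifies when both
#' conditions hold for `persist_days` consecutive days; the first such day
#' is returned.
#'
#' @param t a `temperature_series` (columns `doy`, `temp_C`).
#' @param temp_floor daily mean threshold (degC).
#' @param min_diurnal_range minimum daily temperature range (K) counting as
#'   "fluctuating" (snow-free) soil.
#' @param persist_days consecutive days both criteria must hold.
#' @return Day of year of season start.
#' @export
detect_season_start <- function(t, temp_floor = 3, min_diurnal_range = 0.5,
                                persist_days = 3) {
  day <- floor(t$doy)
  agg_mean <- tapply(t$temp_C, day, mean)
  agg_rng <- tapply(t$temp_C, day, function(x) diff(range(x)))
  days <- as.numeric(names(agg_mean))
  ok <- agg_mean > temp_floor & agg_rng >= min_diurnal_range
  run <- 0
  for (i in seq_along(ok)) {
    run <- if (isTRUE(ok[i])) run + 1 else 0
    if (run >= persist_days) return(days[i - persist_days + 1])
  }
  stop_ap("no_season", "criteria never satisfied: no season start detected")
}

#' Configured end of the growing season
#'
#' Season ends are set from meteorological events (significant snowfall, a
#' cold spell), not detected: 25 September for 2020 and 15 October for 2021
#' by default.
#'
#' @param year calendar year.
#' @param ends named character vector mapping year to end date.
#' @return Day of year of the season end.
#' @export
season_end <- function(year,
                       ends = c("2020" = "2020-09-25", "2021" = "2021-10-15")) {
  key <- as.character(year)
  if (!key %in% names(ends))
    stop_ap("missing_config", "no season end configured for year %s", key)
  doy_of(ends[[key]])
}

#' Mean soil temperature over the first days of a season
#'
#' @param t a `temperature_series`.
#' @param start_doy season start.
#' @param first_n_days length of the averaging window (days); samples in
#'   `[start_doy, start_doy + first_n_days)` are used.
#' @param min_coverage minimum fraction of the expected samples required.
#' @return Mean temperature (degC).
#' @export
mean_temp <- function(t, start_doy, first_n_days = 50, min_coverage = 0.9) {
  if (first_n_days <= 0) stop_ap("invalid_input", "window of 0 days")
  keep <- t$doy >= start_doy & t$doy < start_doy + first_n_days
  step <- attr(t, "step_hours") %||% 1
  expected <- first_n_days * 24 / step
  if (sum(keep) < min_coverage * expected)
    stop_ap("coverage", "only %d of ~%d samples in window", sum(keep),
            round(expected))
  mean(t$temp_C[keep])
}

#' Growing degree hours above a base temperature
#'
#' Sum of max(T - base, 0) x step_hours over all samples in the half-open
#' interval `[doy_a, doy_b)`, making GDH additive over adjacent intervals.
#'
#' @param t a `temperature_series`.
#' @param doy_a,doy_b interval bounds (day of year).
#' @param base base temperature (degC), default 5.
#' @return Degree-hours.
#' @export
gdh <- function(t, doy_a, doy_b, base = 5) {
  step <- attr(t, "step_hours") %||% 1
  keep <- t$doy >= doy_a & t$doy < doy_b
  sum(pmax(t$temp_C[keep] - base, 0)) * step
}

#' Pool visits closer than a week
#'
#' Merges consecutive visits separated by less than `max_gap_days` (strictly)
#' into one observation at the mean date with the mean value, greedily from
#' left to right; a visit joins the current pool when its gap to the
#' previous visit is below the threshold.
#'
#' @param doys sorted visit days.
#' @param values measurements at those days.
#' @param max_gap_days pooling threshold (days); gaps of exactly this size
#'   are not pooled.
#' @return data.frame with pooled `doy`, `value`, `n`.
#' @export
pool_visits <- function(doys, values, max_gap_days = 7) {
  stopifnot(length(doys) == length(values))
  if (is.unsorted(doys)) stop_ap("invalid_input", "doys must be sorted")
  if (!length(doys)) return(data.frame(doy = numeric(0), value = numeric(0),
                                       n = integer(0)))
  grp <- cumsum(c(1, diff(doys) >= max_gap_days))
  data.frame(doy = as.numeric(tapply(doys, grp, mean)),
             value = as.numeric(tapply(values, grp, mean)),
             n = as.integer(tapply(values, grp, length)))
}

#' Elongation and browning rates between consecutive measurements
#'
#' Computes rates (delta value / delta day) for consecutive measurement
#' pairs, restricted to the paper-style phase windows that exclude the flat
#' peak: elongation pairs must lie entirely within `[season_start,
#' peak_doy - pre_peak_margin]`, browning pairs within `[peak_doy +
#' post_peak_margin, half_decline_doy + post_half_margin]`. When a
#' temperature series is supplied each record also carries the interval mean
#' temperature and growing degree hours.
#'
#' @param s a [measurement_series()] (typically pooled leaf lengths).
#' @param season_start,peak_doy,half_decline_doy phenodates for the unit.
#' @param pre_peak_margin,post_peak_margin,post_half_margin window margins in
#'   days (defaults two weeks, two weeks, one week).
#' @param temperature optional `temperature_series` for the same unit.
#' @param gdh_base base temperature for [gdh()].
#' @return data.frame with `unit_id`, `phase`, `doy_a`, `doy_b`, `rate`,
#'   `mean_temp`, `gdh` (possibly zero rows).
#' @export
phase_rates <- function(s, season_start, peak_doy, half_decline_doy,
                        pre_peak_margin = 14, post_peak_margin = 14,
                        post_half_margin = 7, temperature = NULL,
                        gdh_base = 5) {
  n <- nrow(s)
  out <- list()
  elong_hi <- peak_doy - pre_peak_margin
  brown_lo <- peak_doy + post_peak_margin
  brown_hi <- if (is.na(half_decline_doy)) -Inf
              else half_decline_doy + post_half_margin
  for (i in seq_len(max(0, n - 1))) {
    a <- s$doy[i]; b <- s$doy[i + 1]
    phase <- if (a >= season_start && b <= elong_hi) "elongation"
             else if (a >= brown_lo && b <= brown_hi) "browning"
             else next
    rec <- data.frame(unit_id = s$unit_id[1], phase = phase,
                      doy_a = a, doy_b = b,
                      rate = (s$value[i + 1] - s$value[i]) / (b - a),
                      mean_temp = NA_real_, gdh = NA_real_,
                      stringsAsFactors = FALSE)
    if (!is.null(temperature)) {
      keep <- temperature$doy >= a & temperature$doy < b
      if (any(keep)) {
        rec$mean_temp <- mean(temperature$temp_C[keep])
        rec$gdh <- gdh(temperature, a, b, base = gdh_base)
      }
    }
    out[[length(out) + 1]] <- rec
  }
  if (!length(out))
    return(data.frame(unit_id = character(0), phase = character(0),
                      doy_a = numeric(0), doy_b = numeric(0),
                      rate = numeric(0), mean_temp = numeric(0),
                      gdh = numeric(0), stringsAsFactors = FALSE))
  do.call(rbind, out)
}
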