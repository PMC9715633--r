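# Synthetic soil-temperature series: a snow-covered near-0 degC winter phase
# followed, from season start, by a summer phase with a sinusoidal diurnal
# cycle. Mirrors soil loggers at 3-4 cm depth recording every 1-2 h.

#' Generate a synthetic soil-temperature series
#'
#' Emulates a soil-temperature log across snowmelt: before `season_start` the
#' soil sits under snow at around 0.2 degC with negligible diurnal range;
#' from `season_start` on it follows `summer_mean` plus a sinusoidal diurnal
#' cycle of amplitude `diurnal_amp` (daily range = 2 * amplitude) plus noise.
#' The transition is sharp, as observed when the snowpack disappears.
#'
#' @param season_start day of year of snowmelt (start of summer conditions).
#' @param season_end day of year of the end of the series.
#' @param summer_mean mean soil temperature after melt-out (degC). Default
#'   10.5 degC, typical of the first 50 days of an alpine growing season.
#' @param diurnal_amp amplitude of the diurnal cycle (K); the day/night
#'   settings of 5--14 degC correspond to an amplitude of 4.5 K.
#' @param step logging step in hours (1 or 2).
#' @param noise_sd sd of additive sensor/weather noise (K) in summer.
#' @param winter_mean,winter_sd snow-covered phase mean and sd (degC);
#'   values are clipped at -0.5 degC.
#' @param pre_days days of winter record before `season_start`.
#' @param year calendar year used to build timestamps.
#' @param unit_id identifier stored with the series.
#' @param seed integer seed for reproducibility; identical seeds give
#'   bit-identical series.
#' @return A `temperature_series`: data.frame with columns `unit_id`,
#'   `timestamp` (POSIXct, UTC), `doy` (fractional), `temp_C`.
#' @export
gen_temperature <- function(season_start, season_end, summer_mean = 10.5,
                            diurnal_amp = 4.5, step = 2, noise_sd = 0.3,
                            winter_mean = 0.2, winter_sd = 0.1,
                            pre_days = 30, year = 2021, unit_id = "u1",
                            seed = NULL) {
  if (!step %in% c(1, 2)) stop_ap("invalid_input", "step must be 1 or 2 hours")
  if (diurnal_amp < 0) stop_ap("invalid_input", "diurnal_amp must be >= 0")
  if (season_end <= season_start)
    stop_ap("invalid_input", "non-positive season duration")
  with_seed(seed, {
    t0 <- (season_start - pre_days - 1) * 24 # hours since Jan 1 00:00
    t1 <- (season_end - 1) * 24
    hours <- seq(t0, t1, by = step)
    doy <- hours / 24 + 1
    hod <- hours %% 24
    n <- length(hours)
    summer <- doy >= season_start
    temp <- numeric(n)
    nw <- sum(!summer)
    temp[!summer] <- pmax(rnorm(nw, winter_mean, winter_sd), -0.5)
    ns <- sum(summer)
    # diurnal peak mid-afternoon (14:00)
    temp[summer] <- summer_mean +
      diurnal_amp * sin(2 * pi * (hod[summer] - 8) / 24) +
      rnorm(ns, 0, noise_sd)
    out <- data.frame(
      unit_id = unit_id,
      timestamp = as.POSIXct(sprintf("%d-01-01 00:00:00", year), tz = "UTC") +
        hours * 3600,
      doy = doy,
      temp_C = temp,
      stringsAsFactors = FALSE
    )
    class(out) <- c("temperature_series", "data.frame")
    attr(out, "step_hours") <- step
    out
  })
}
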