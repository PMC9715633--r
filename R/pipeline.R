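# End-to-end orchestration: synthetic study generation, per-unit metric
# extraction, group summaries and contrasts.

#' Default study design
#'
#' Three experimental groups in one year: summer conditions started about
#' four months early (18 Feb, day 49), two months early (23 Apr, day 113),
#' and at natural snowmelt (2 Jul, day 183), with 8, 8 and 5 units and a
#' common meteorological season end on 15 Oct (day 288).
#'
#' @param year calendar year of the design.
#' @return A `study_design` list with a `groups` data.frame.
#' @export
default_design <- function(year = 2021) {
  groups <- data.frame(
    name = c("plus4m", "plus2m", "field"),
    season_start_doy = c(49, 113, 183),
    season_end_doy = c(288, 288, 288),
    n_units = c(8L, 8L, 5L),
    stringsAsFactors = FALSE
  )
  structure(list(groups = groups, year = year), class = "study_design")
}

#' Generate a full synthetic study
#'
#' Draws soil-temperature series and leaf-length, greenness and root-area
#' trajectories for every unit of a design, with moderate unit-to-unit
#' variation in shape parameters and known ground truth. With
#' `anchor = "season"` trajectory shapes are anchored to each group's season
#' start (the autonomous-phenology scenario); with `anchor = "calendar"`
#' all groups share the shape of the latest-starting group, i.e. growth
#' happens on the same calendar dates regardless of season start.
#'
#' @param design a [default_design()]-style object.
#' @param seed integer master seed; every unit derives its own child seed.
#' @param anchor `"season"` or `"calendar"`.
#' @param kinds trajectory kinds to generate per unit.
#' @param unit_jitter logical; disable to make all units of a group share
#'   the same noise-free curve.
#' @return List of class `synthetic_study`: `measurements` (stacked
#'   measurement series), `temperature` (stacked temperature series),
#'   `truth` (per unit x kind data.frame), `design`, `seed`.
#' @export
synth_study <- function(design = default_design(), seed = 1,
                        anchor = c("season", "calendar"),
                        kinds = c("leaf", "greenness", "root"),
                        unit_jitter = TRUE) {
  anchor <- match.arg(anchor)
  groups <- design$groups
  meas <- list(); temps <- list(); truths <- list()
  uidx <- 0
  for (gi in seq_len(nrow(groups))) {
    g <- groups[gi, ]
    anchor_start <- if (anchor == "season") g$season_start_doy
                    else max(groups$season_start_doy)
    for (ui in seq_len(g$n_units)) {
      uidx <- uidx + 1
      unit_id <- sprintf("%s_%02d", g$name, ui)
      tseed <- child_seed(seed, uidx * 10)
      temps[[uidx]] <- gen_temperature(g$season_start_doy, g$season_end_doy,
                                       year = design$year, unit_id = unit_id,
                                       seed = tseed)
      dates <- sampling_schedule(g$season_start_doy, g$season_end_doy)
      for (ki in seq_along(kinds)) {
        kind <- kinds[ki]
        kseed <- child_seed(seed, uidx * 10 + ki)
        p <- default_trajectory_params(kind, anchor_start)
        if (unit_jitter) {
          jit <- with_seed(child_seed(seed, uidx * 10 + ki + 5000), {
            list(shift = rnorm(1, 0, 2), stretch = exp(rnorm(1, 0, 0.06)),
                 amp = exp(rnorm(1, 0, 0.08)))
          })
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
        }
        tr <- gen_trajectory(kind, season_start = g$season_start_doy,
                             season_end = g$season_end_doy,
                             sampling_dates = dates, params = p,
                             unit_id = unit_id, group = g$name, seed = kseed)
        meas[[length(meas) + 1]] <- tr$series
        tru <- tr$truth
        truths[[length(truths) + 1]] <- data.frame(
          unit_id = unit_id, group = g$name, kind = kind,
          true_peak_doy = tru$true_peak_doy,
          true_half_decline_doy = tru$true_half_decline_doy,
          true_root_onset_doy = tru$true_root_onset_doy,
          true_q80_doy = tru$true_q80_doy,
          true_auc = tru$true_auc,
          season_start = g$season_start_doy,
          stringsAsFactors = FALSE)
      }
    }
  }
  structure(list(
    measurements = do.call(rbind, meas),
    temperature = do.call(rbind, temps),
    truth = do.call(rbind, truths),
    design = design, seed = seed, anchor = anchor
  ), class = "synthetic_study")
}

#' Group summary table
#'
#' Per-group mean, standard error (sd / sqrt(n)) and n for each numeric
#' metric column; SE is `NA` for single-unit groups.
#'
#' @param metrics per-unit metrics data.frame with a `group` column.
#' @param cols metric columns to summarize (default: all numeric columns).
#' @return Long data.frame with `group`, `metric`, `mean`, `se`, `n`.
#' @export
summarize_groups <- function(metrics, cols = NULL) {
  num <- vapply(metrics, is.numeric, logical(1))
  cols <- cols %||% names(metrics)[num]
  out <- list()
  for (cl in cols) {
    for (g in unique(metrics$group)) {
      v <- metrics[[cl]][metrics$group == g]
      v <- v[!is.na(v)]
      n <- length(v)
      out[[length(out) + 1]] <- data.frame(
        group = g, metric = cl,
        mean = if (n) mean(v) else NA_real_,
        se = if (n > 1) stats::sd(v) / sqrt(n) else NA_real_,
        n = n, stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}

#' Run configuration
#'
#' Single source for all thresholds and settings of a pipeline run.
#'
#' @param design study design for synthetic runs (ignored when
#'   `measurements_csv` is given).
#' @param measurements_csv,temperature_csv optional input CSV paths; when
#'   `NULL` a synthetic study is generated.
#' @param seed master seed.
#' @param anchor trajectory anchoring for synthetic runs.
#' @param smoother a [smoother_config()] for hump-shaped variables.
#' @param smoother_cumulative a [smoother_config()] for cumulative
#'   variables (root area).
#' @param onset_slope root-onset slope threshold (percent per day).
#' @param quantiles growth quantiles extracted for cumulative variables.
#' @param season_temp_floor,season_min_diurnal_range,season_persist_days
#'   snowmelt-detection settings (see [detect_season_start()]).
#' @param contrast_metric metric used for group contrasts.
#' @param out_dir optional output directory for CSVs.
#' @return A `run_config` list.
#' @export
run_config <- function(design = default_design(), measurements_csv = NULL,
                       temperature_csv = NULL, seed = 1,
                       anchor = "season", smoother = smoother_config(),
                       smoother_cumulative = cumulative_smoother_config(),
                       onset_slope = 0.5, quantiles = c(0.5, 0.8),
                       season_temp_floor = 3,
                       season_min_diurnal_range = 0.5,
                       season_persist_days = 3,
                       contrast_metric = "days_to_peak", out_dir = NULL) {
  structure(list(design = design, measurements_csv = measurements_csv,
                 temperature_csv = temperature_csv, seed = seed,
                 anchor = anchor, smoother = smoother,
                 smoother_cumulative = smoother_cumulative,
                 onset_slope = onset_slope, quantiles = quantiles,
                 season_temp_floor = season_temp_floor,
                 season_min_diurnal_range = season_min_diurnal_range,
                 season_persist_days = season_persist_days,
                 contrast_metric = contrast_metric, out_dir = out_dir),
            class = "run_config")
}

#' Run the full pipeline
#'
#' Generates (or loads) measurements and temperature logs, detects season
#' starts from temperature, scales each unit's series, fits smoothers,
#' extracts phenometrics, and produces group summaries and pairwise
#' contrasts. Deterministic given `cfg$seed`; every threshold actually
#' applied is recorded in the returned `log`.
#'
#' @param cfg a [run_config()].
#' @return List with `metrics`, `summaries`, `contrasts`, `seasons`,
#'   `measurements`, `log` (and `truth` for synthetic runs).
#' @export
run_pipeline <- function(cfg = run_config()) {
  log <- list(seed = cfg$seed, onset_slope = cfg$onset_slope,
              quantiles = cfg$quantiles,
              season_temp_floor = cfg$season_temp_floor,
              season_min_diurnal_range = cfg$season_min_diurnal_range,
              season_persist_days = cfg$season_persist_days,
              max_knots = cfg$smoother$max_knots,
              smoother_basis = cfg$smoother$basis,
              smoother_basis_cumulative = cfg$smoother_cumulative$basis,
              anchor = cfg$anchor)
  if (is.null(cfg$measurements_csv)) {
    study <- synth_study(cfg$design, seed = cfg$seed, anchor = cfg$anchor)
    measurements <- study$measurements
    temperature <- study$temperature
    truth <- study$truth
  } else {
    measurements <- read_measurements_csv(cfg$measurements_csv)
    temperature <- if (!is.null(cfg$temperature_csv))
      read_temperature_csv(cfg$temperature_csv) else NULL
    truth <- NULL
  }
  # season windows per unit
  units <- unique(measurements$unit_id)
  seasons <- list()
  for (u in units) {
    start <- NA_real_
    if (!is.null(temperature)) {
      tu <- temperature[temperature$unit_id == u, ]
      attr(tu, "step_hours") <- attr(temperature, "step_hours") %||% 2
      class(tu) <- c("temperature_series", "data.frame")
      start <- tryCatch(
        detect_season_start(tu, cfg$season_temp_floor,
                            cfg$season_min_diurnal_range,
                            cfg$season_persist_days),
        alpinepheno_error = function(e) NA_real_)
    }
    if (is.na(start)) start <- min(measurements$doy[measurements$unit_id == u])
    seasons[[u]] <- data.frame(unit_id = u, start_doy = start,
                               end_doy = max(measurements$doy[measurements$unit_id == u]),
                               source = if (!is.null(temperature)) "detected"
                                        else "configured",
                               stringsAsFactors = FALSE)
  }
  seasons <- do.call(rbind, seasons)
  rownames(seasons) <- NULL

  metrics <- list()
  for (u in units) {
    win <- seasons[seasons$unit_id == u, ]
    mu <- measurements[measurements$unit_id == u, ]
    for (v in unique(mu$variable)) {
      sv <- mu[mu$variable == v, ]
      s <- measurement_series(u, sv$group[1], v, sv$doy, sv$value)
      s <- tryCatch(scale_series(s, zero_at_start = v == "root_area"),
                    alpinepheno_error = function(e) NULL)
      if (is.null(s)) next
      m <- tryCatch(
        pheno_metrics(s, win$start_doy, win$end_doy,
                      if (v == "root_area") cfg$smoother_cumulative
                      else cfg$smoother,
                      cfg$quantiles),
        error = function(e) {
          stop_ap("stage_error", "phenometrics failed for unit %s, %s: %s",
                  u, v, conditionMessage(e))
        })
      metrics[[length(metrics) + 1]] <- m
    }
  }
  metrics <- do.call(rbind, metrics)
  rownames(metrics) <- NULL
  metric_cols <- c("onset_doy", "peak_doy", "half_decline_doy", "q50_doy",
                   "q80_doy", "max_rate_doy", "auc", "days_to_peak")
  summaries <- do.call(rbind, lapply(unique(metrics$variable), function(v) {
    sm <- summarize_groups(metrics[metrics$variable == v, ], metric_cols)
    sm$variable <- v
    sm
  }))
  summaries <- summaries[!is.na(summaries$mean), ]
  rownames(summaries) <- NULL
  contrasts <- list()
  for (v in unique(metrics$variable)) {
    mv <- metrics[metrics$variable == v, ]
    val <- mv[[cfg$contrast_metric]]
    ok <- !is.na(val)
    if (length(unique(mv$group[ok])) >= 2) {
      ct <- group_contrasts(val[ok], mv$group[ok])
      ct$variable <- v
      contrasts[[length(contrasts) + 1]] <- ct
    }
  }
  contrasts <- if (length(contrasts)) do.call(rbind, contrasts) else NULL
  res <- list(metrics = metrics, summaries = summaries,
              contrasts = contrasts, seasons = seasons,
              measurements = measurements, truth = truth, log = log)
  if (!is.null(cfg$out_dir)) {
    dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
    write.csv(metrics, file.path(cfg$out_dir, "metrics.csv"),
              row.names = FALSE)
    write.csv(summaries, file.path(cfg$out_dir, "group_summaries.csv"),
              row.names = FALSE)
    if (!is.null(contrasts))
      write.csv(contrasts, file.path(cfg$out_dir, "contrasts.csv"),
                row.names = FALSE)
    write.csv(seasons, file.path(cfg$out_dir, "seasons.csv"),
              row.names = FALSE)
    writeLines(jsonlite::toJSON(log, auto_unbox = TRUE, pretty = TRUE),
               file.path(cfg$out_dir, "run_log.json"))
  }
  res
}
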