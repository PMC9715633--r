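# Plain-format I/O: measurement and temperature CSVs, PNG/JPEG images and
# text PGM/PPM rasters. TIFF is not supported in this build; convert cylinder
# scans to PNG or PGM first.

#' Write / read a measurement CSV
#'
#' Long format: `unit_id, group, doy, variable, value`.
#'
#' @param measurements stacked [measurement_series()] rows.
#' @param path file path.
#' @return `read_measurements_csv` returns the data.frame.
#' @export
write_measurements_csv <- function(measurements, path) {
  write.csv(measurements[, c("unit_id", "group", "doy", "variable", "value")],
            path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_measurements_csv
#' @export
read_measurements_csv <- function(path) {
  if (!file.exists(path)) stop_ap("missing_file", "no such file: %s", path)
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("unit_id", "group", "doy", "variable", "value")
  if (!all(need %in% names(df)))
    stop_ap("invalid_input", "measurement CSV must have columns %s",
            paste(need, collapse = ", "))
  df
}

#' Write / read a temperature CSV
#'
#' Columns: `unit_id, timestamp` (ISO-8601), `temp_C`.
#'
#' @param temperature stacked `temperature_series` rows.
#' @param path file path.
#' @param step_hours logging step recorded on read (hours).
#' @return `read_temperature_csv` returns a `temperature_series`.
#' @export
write_temperature_csv <- function(temperature, path) {
  df <- data.frame(unit_id = temperature$unit_id,
                   timestamp = strftime(temperature$timestamp,
                                        "%Y-%m-%dT%H:%M:%SZ", tz = "UTC"),
                   temp_C = temperature$temp_C)
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_temperature_csv
#' @export
read_temperature_csv <- function(path, step_hours = NULL) {
  if (!file.exists(path)) stop_ap("missing_file", "no such file: %s", path)
  df <- read.csv(path, stringsAsFactors = FALSE)
  ts <- as.POSIXct(df$timestamp, format = "%Y-%m-%dT%H:%M:%S", tz = "UTC")
  out <- data.frame(unit_id = df$unit_id, timestamp = ts,
                    doy = as.numeric(strftime(ts, "%j")) +
                      (as.numeric(strftime(ts, "%H")) +
                       as.numeric(strftime(ts, "%M")) / 60) / 24,
                    temp_C = df$temp_C, stringsAsFactors = FALSE)
  if (is.null(step_hours) && nrow(out) > 1)
    step_hours <- round(as.numeric(difftime(out$timestamp[2],
                                            out$timestamp[1], units = "hours")))
  class(out) <- c("temperature_series", "data.frame")
  attr(out, "step_hours") <- step_hours %||% 1
  out
}

#' Read an image file
#'
#' Reads PNG or JPEG (via the png/jpeg packages) or plain-text PGM (P2) /
#' PPM (P3). Greyscale images return a matrix in \[0, 1\]; colour images an
#' H x W x 3 array scaled 0--255.
#'
#' @param path image path.
#' @return Matrix or array.
#' @export
read_image <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext == "png") {
    if (!requireNamespace("png", quietly = TRUE))
      stop_ap("missing_dep", "package 'png' required to read PNG")
    x <- png::readPNG(path)
    return(if (length(dim(x)) == 3) x[, , 1:3] * 255 else x)
  }
  if (ext %in% c("jpg", "jpeg")) {
    if (!requireNamespace("jpeg", quietly = TRUE))
      stop_ap("missing_dep", "package 'jpeg' required to read JPEG")
    x <- jpeg::readJPEG(path)
    return(if (length(dim(x)) == 3) x[, , 1:3] * 255 else x)
  }
  if (ext %in% c("pgm", "ppm")) return(read_pnm(path))
  stop_ap("invalid_input", "unsupported image format: %s", ext)
}

# Plain (ASCII) PGM/PPM reader; P2 -> matrix in [0,1], P3 -> HxWx3 in 0..255.
read_pnm <- function(path) {
  txt <- readLines(path)
  txt <- txt[!grepl("^#", txt)]
  tok <- scan(text = paste(txt[-1], collapse = " "), what = numeric(),
              quiet = TRUE)
  magic <- trimws(txt[1])
  w <- tok[1]; h <- tok[2]; mx <- tok[3]
  px <- tok[-(1:3)]
  if (magic == "P2") {
    matrix(px / mx, nrow = h, ncol = w, byrow = TRUE)
  } else if (magic == "P3") {
    arr <- array(0, c(h, w, 3))
    m <- matrix(px, ncol = 3, byrow = TRUE)
    for (ch in 1:3) arr[, , ch] <- matrix(m[, ch], h, w, byrow = TRUE) / mx * 255
    arr
  } else stop_ap("invalid_input", "only plain P2/P3 PNM supported")
}

#' Write a greyscale matrix as plain PGM (P2)
#'
#' @param img matrix in \[0, 1\].
#' @param path output path.
#' @param maxval grey levels.
#' @export
write_pgm <- function(img, path, maxval = 255) {
  vals <- round(pmin(pmax(img, 0), 1) * maxval)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("P2", sprintf("%d %d", ncol(img), nrow(img)),
               as.character(maxval)), con)
  apply(vals, 1, function(r) writeLines(paste(r, collapse = " "), con))
  invisible(path)
}

#' Write a boolean mask as a 0/255 PNG
#'
#' @param mask logical matrix.
#' @param path output path.
#' @export
write_mask_png <- function(mask, path) {
  if (!requireNamespace("png", quietly = TRUE))
    stop_ap("missing_dep", "package 'png' required to write PNG")
  png::writePNG(mask * 1, path)
  invisible(path)
}
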