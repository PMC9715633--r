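# Canopy greenness (green chromatic coordinate) from RGB photographs.

#' Canopy greenness from an RGB image
#'
#' Computes the green chromatic coordinate G / (R + G + B) over a region of
#' interest. The default follows the phenocam convention of taking the ratio
#' of the channel means over the ROI, which is robust to per-pixel exposure
#' noise; `per_pixel = TRUE` instead averages the per-pixel ratios.
#'
#' @param img height x width x 3 numeric array (any linear intensity scale).
#' @param roi optional logical matrix (same height/width) restricting the
#'   region of interest; `NA`/`FALSE` pixels are excluded. Vegetation masks
#'   and tape/blackout masks are supplied this way.
#' @param per_pixel logical; average per-pixel ratios instead of taking the
#'   ratio of channel means.
#' @return Greenness in \[0, 1\].
#' @examples
#' img <- array(0, c(2, 2, 3)); img[, , 2] <- 255
#' canopy_greenness(img)  # 1
#' @export
canopy_greenness <- function(img, roi = NULL, per_pixel = FALSE) {
  if (length(dim(img)) != 3 || dim(img)[3] != 3)
    stop_ap("invalid_input", "img must be an H x W x 3 array")
  r <- img[, , 1]; g <- img[, , 2]; b <- img[, , 3]
  if (!is.null(roi)) {
    if (!all(dim(roi) == dim(r)))
      stop_ap("invalid_input", "roi dimensions must match image")
    keep <- which(roi %in% TRUE)
    if (!length(keep)) stop_ap("undefined_index", "empty ROI")
    r <- r[keep]; g <- g[keep]; b <- b[keep]
  }
  tot <- r + g + b
  if (per_pixel) {
    ok <- tot > 0
    if (!any(ok)) stop_ap("undefined_index", "all-black ROI")
    return(mean(g[ok] / tot[ok]))
  }
  if (sum(tot) <= 0) stop_ap("undefined_index", "all-black ROI")
  mean(g) / (mean(r) + mean(g) + mean(b))
}
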