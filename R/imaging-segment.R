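# Classical root segmentation: multi-scale ridge enhancement + hysteresis.
#
# This is a deterministic stand-in for a trained segmentation network, kept
# behind a small parameter object so a learned segmenter can be plugged in
# later. Roots appear as bright curvilinear ridges on the soil background of
# a normalized scan; the detector responds to the scale-normalized negative
# principal curvature of the Gaussian-smoothed image.

#' Segmentation parameters
#'
#' @param ridge_scales Gaussian scales (px) of the multi-scale ridge filter;
#'   a root of width w responds strongest near w / 2.
#' @param threshold_low,threshold_high hysteresis thresholds on the ridge
#'   response (absolute, for images normalized with [normalize_image()]).
#' @param min_object_px connected components smaller than this are removed.
#' @return A `segmenter_params` list.
#' @export
segmenter_params <- function(ridge_scales = c(2, 3.5, 5),
                             threshold_low = 0.12, threshold_high = 0.2,
                             min_object_px = 40) {
  if (threshold_low >= threshold_high)
    stop_ap("invalid_input", "threshold_low must be < threshold_high")
  if (min_object_px < 1) stop_ap("invalid_input", "min_object_px must be >= 1")
  structure(list(ridge_scales = ridge_scales, threshold_low = threshold_low,
                 threshold_high = threshold_high,
                 min_object_px = min_object_px),
            class = "segmenter_params")
}

# Scale-normalized bright-ridge response: sigma^2 * max(0, -lambda_min) of
# the Hessian of the sigma-smoothed image, maximized over scales.
ridge_response <- function(img, scales) {
  H <- nrow(img); W <- ncol(img)
  resp <- matrix(0, H, W)
  for (s in scales) {
    sm <- gaussian_blur(img, s)
    up <- rbind(sm[H, ], sm[-H, ]); dn <- rbind(sm[-1, ], sm[1, ])
    lf <- cbind(sm[, W], sm[, -W]); rt <- cbind(sm[, -1], sm[, 1])
    fyy <- up + dn - 2 * sm
    fxx <- lf + rt - 2 * sm
    ul <- roll_matrix(sm, 1, 1); dr <- roll_matrix(sm, -1, -1)
    ur <- roll_matrix(sm, -1, 1); dl <- roll_matrix(sm, 1, -1)
    fxy <- (dr + ul - ur - dl) / 4
    disc <- sqrt(((fxx - fyy) / 2)^2 + fxy^2)
    lmin <- (fxx + fyy) / 2 - disc
    resp <- pmax(resp, s^2 * pmax(-lmin, 0))
  }
  resp
}

#' Segment roots in a normalized greyscale scan
#'
#' Multi-scale ridge enhancement at `params$ridge_scales`, hysteresis
#' thresholding (pixels above `threshold_high` seed regions that extend over
#' connected pixels above `threshold_low`), an intensity refinement that
#' trims the anti-aliased stroke halo (mask pixels must be brighter than the
#' midpoint between the background and root median intensities, i.e. at
#' least half-covered by root), and removal of components smaller than
#' `min_object_px`. Fully deterministic.
#'
#' @param img normalized greyscale matrix (see [normalize_image()]).
#' @param params a [segmenter_params()] object.
#' @return Logical root mask (possibly empty).
#' @export
segment_roots <- function(img, params = segmenter_params()) {
  resp <- ridge_response(img, params$ridge_scales)
  weak <- resp >= params$threshold_low
  strong <- resp >= params$threshold_high
  if (!any(strong)) return(matrix(FALSE, nrow(img), ncol(img)))
  lab <- .cc_label(weak)
  keep_ids <- unique(lab[strong])
  mask <- matrix(lab %in% setdiff(keep_ids, 0L), nrow(img), ncol(img))
  # halo refinement: keep pixels at least half-way between soil and root
  # intensity (a half-coverage area convention for anti-aliased edges)
  bg_med <- stats::median(img[!mask])
  root_med <- stats::median(img[mask])
  if (is.finite(root_med) && root_med > bg_med)
    mask <- mask & img >= (bg_med + root_med) / 2
  # size filter
  lab2 <- .cc_label(mask)
  if (max(lab2) > 0) {
    sizes <- tabulate(lab2[lab2 > 0], nbins = max(lab2))
    small <- which(sizes < params$min_object_px)
    if (length(small)) mask[lab2 %in% small] <- FALSE
  }
  mask
}
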