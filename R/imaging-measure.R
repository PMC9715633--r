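# Root quantification: area per image area and diameter summaries.

#' Root area from a segmentation mask
#'
#' Converts the positive-pixel count of a root mask into absolute area and
#' area per unit image area. Pixel side length is 25.4 / dpi mm.
#'
#' @param mask logical matrix.
#' @param dpi scan resolution in dots per inch (> 0).
#' @return List with `area_mm2` (absolute root area),
#'   `area_mm2_cm2` (root area per image area), `n_px`, `image_area_cm2`.
#' @examples
#' m <- matrix(FALSE, 100, 100); m[1:10, 1:10] <- TRUE
#' root_area(m, dpi = 1200)
#' @export
root_area <- function(mask, dpi = 1200) {
  if (dpi <= 0) stop_ap("invalid_input", "dpi must be > 0")
  px_mm <- 25.4 / dpi
  n <- sum(mask)
  area_mm2 <- n * px_mm^2
  image_area_cm2 <- length(mask) * px_mm^2 / 100
  list(area_mm2 = area_mm2,
       area_mm2_cm2 = area_mm2 / image_area_cm2,
       n_px = n, image_area_cm2 = image_area_cm2)
}

#' Root diameter summary from a segmentation mask
#'
#' Diameters follow the inscribed-disk (medial axis) convention: the mask is
#' thinned to a 1-px skeleton and the diameter at each skeleton pixel is
#' twice the Euclidean distance to the nearest background pixel, converted
#' to mm. The minimum resolvable diameter under this convention is two pixel
#' widths.
#'
#' @param mask logical matrix.
#' @param dpi scan resolution.
#' @return List with `mean_mm`, `max_mm`, `n` (skeleton pixels) and
#'   `diameters_mm` (per skeleton pixel); all-`NA`/empty summary for an
#'   empty mask.
#' @export
root_diameters <- function(mask, dpi = 1200) {
  if (dpi <= 0) stop_ap("invalid_input", "dpi must be > 0")
  if (!any(mask))
    return(list(mean_mm = NA_real_, max_mm = NA_real_, n = 0L,
                diameters_mm = numeric(0)))
  px_mm <- 25.4 / dpi
  d <- .edt(mask)
  skel <- .thin_mask(mask)
  dia <- 2 * d[skel] * px_mm
  list(mean_mm = mean(dia), max_mm = max(dia), n = sum(skel),
       diameters_mm = dia)
}

#' Run the full root-quantification chain on a stack
#'
#' Destripes, normalizes, aligns, segments and measures every scan of a
#' rhizotron stack.
#'
#' @param stack a `rhizotron_stack`.
#' @param params a [segmenter_params()] object.
#' @param destripe_strength passed to [destripe()]; 0 disables destriping.
#' @param align align the stack by phase correlation first.
#' @return The stack with added `seg_masks`, `root_area` (mm2 cm-2 per
#'   date), `mean_diam_mm`, `max_diam_mm`, and `shifts`.
#' @export
process_stack <- function(stack, params = segmenter_params(),
                          destripe_strength = 0.7, align = TRUE) {
  stack$images <- lapply(stack$images, function(im) {
    if (destripe_strength > 0) im <- destripe(im, destripe_strength)
    normalize_image(im)
  })
  if (align && length(stack$images) >= 2) stack <- align_stack(stack)
  n <- length(stack$images)
  stack$seg_masks <- vector("list", n)
  stack$root_area <- stack$mean_diam_mm <- stack$max_diam_mm <- numeric(n)
  for (i in seq_len(n)) {
    m <- segment_roots(stack$images[[i]], params)
    stack$seg_masks[[i]] <- m
    stack$root_area[i] <- root_area(m, stack$dpi)$area_mm2_cm2
    dia <- root_diameters(m, stack$dpi)
    stack$mean_diam_mm[i] <- dia$mean_mm
    stack$max_diam_mm[i] <- dia$max_mm
  }
  stack
}
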