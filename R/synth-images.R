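# Synthetic canopy photographs and mini-rhizotron scan stacks with known
# ground truth (green pixel fraction, root masks, per-date root areas).

#' Generate a synthetic canopy photograph
#'
#' Builds an RGB raster in which a prescribed fraction of pixels is drawn
#' from a green colour and the rest from a brown soil/litter colour,
#' optionally with per-pixel channel jitter. The expected greenness index of
#' the image is computable in closed form from the two colours.
#'
#' @param width,height image size in pixels.
#' @param green_fraction fraction of pixels that are vegetation, in \[0, 1\];
#'   realised exactly to within one pixel.
#' @param green_rgb,brown_rgb length-3 RGB triples (0--255).
#' @param jitter_sd sd of Gaussian channel jitter (0 disables it).
#' @param seed integer seed.
#' @return List with `image` (height x width x 3 array, 0--255),
#'   `truth` (list with `true_green_fraction`, `expected_greenness`).
#' @export
gen_canopy_image <- function(width = 256, height = 256, green_fraction = 0.5,
                             green_rgb = c(60, 140, 50),
                             brown_rgb = c(120, 100, 70),
                             jitter_sd = 0, seed = NULL) {
  if (green_fraction < 0 || green_fraction > 1)
    stop_ap("invalid_input", "green_fraction must be in [0, 1]")
  with_seed(seed, {
    n <- width * height
    n_green <- round(green_fraction * n)
    idx <- sample.int(n, n_green)
    img <- array(0, dim = c(height, width, 3))
    for (ch in 1:3) {
      plane <- matrix(brown_rgb[ch], height, width)
      plane[idx] <- green_rgb[ch]
      if (jitter_sd > 0)
        plane <- plane + matrix(rnorm(n, 0, jitter_sd), height, width)
      img[, , ch] <- pmin(pmax(plane, 0), 255)
    }
    f <- n_green / n
    mean_rgb <- f * green_rgb + (1 - f) * brown_rgb
    truth <- list(true_green_fraction = f,
                  expected_greenness = mean_rgb[2] / sum(mean_rgb))
    list(image = img, truth = truth)
  })
}

# Draw one anti-aliased quadratic Bezier stroke onto a coverage canvas.
draw_stroke <- function(canvas, p0, p1, p2, width) {
  len <- sqrt(sum((p2 - p0)^2)) + sqrt(sum((p1 - p0)^2))
  ts <- seq(0, 1, length.out = max(8, ceiling(len / 0.4)))
  xs <- (1 - ts)^2 * p0[1] + 2 * (1 - ts) * ts * p1[1] + ts^2 * p2[1]
  ys <- (1 - ts)^2 * p0[2] + 2 * (1 - ts) * ts * p1[2] + ts^2 * p2[2]
  .stamp_disks(canvas, xs, ys, width / 2)
}

# Add random strokes until the coverage mask reaches target_px positive
# pixels (within tol_frac).
grow_roots <- function(canvas, target_px, mean_width = 10, tol_frac = 0.01,
                       max_iter = 600) {
  H <- nrow(canvas); W <- ncol(canvas)
  count <- sum(canvas > 0.5)
  iter <- 0
  while (count < target_px * (1 - tol_frac) && iter < max_iter) {
    iter <- iter + 1
    remaining <- target_px - count
    w <- max(3, rnorm(1, mean_width, mean_width / 5))
    # shrink the final strokes so the scheduled area is hit within tol_frac
    if (remaining < 25 * w) w <- max(2, remaining / 25)
    # stroke pixel count ~ len * w + pi * (w/2)^2 (rounded end caps);
    # undershoot deliberately and let later strokes close the gap
    len <- min(max(0.9 * remaining / w - pi * w / 4, 8), 0.8 * min(H, W))
    p0 <- c(runif(1, 1, W), runif(1, 1, H))
    ang <- runif(1, 0, 2 * pi)
    p2 <- p0 + len * c(cos(ang), sin(ang))
    mid <- (p0 + p2) / 2
    p1 <- mid + rnorm(2, 0, len / 6)
    canvas <- draw_stroke(canvas, p0, p1, p2, w)
    count <- sum(canvas > 0.5)
  }
  canvas
}

#' Generate a synthetic mini-rhizotron scan stack
#'
#' Produces a time-ordered stack of greyscale scans: a smooth soil texture,
#' plus persistent bright root strokes whose cumulative area follows
#' `root_schedule` (within 2 percent), plus an additive column-wise stripe
#' pattern (scanner artifact) and a per-date planar shift. Ground-truth
#' masks (in the unshifted frame) and true per-date areas are returned.
#'
#' @param n_dates number of scan dates.
#' @param width,height image size (px).
#' @param root_schedule non-decreasing cumulative root area per date, in
#'   mm2 cm-2; default a logistic ramp to 1.5 mm2 cm-2.
#' @param doy day-of-year per date.
#' @param dpi scanner resolution (default 1200).
#' @param stripe_amp sd of per-column additive stripe offsets, on the \[0, 1\]
#'   grey scale (0 disables stripes).
#' @param shifts n_dates x 2 matrix of integer (dx, dy) pixel shifts applied
#'   to each date (first row usually 0, 0). Applied circularly.
#' @param noise_sd per-pixel sensor noise sd.
#' @param mean_width mean stroke width in px (10 px is a 0.21 mm diameter
#'   root at 1200 DPI).
#' @param seed integer seed.
#' @return A `rhizotron_stack`: list with `images` (list of matrices in
#'   \[0, 1\]), `doy`, `dpi`, `masks` (truth, unshifted), `true_shifts`,
#'   `true_area_px`, `true_area_mm2_cm2`, `shifts` (NULL until aligned).
#' @export
gen_rhizotron_stack <- function(n_dates = 5, width = 512, height = 512,
                                root_schedule = NULL, doy = NULL, dpi = 1200,
                                stripe_amp = 0.03, shifts = NULL,
                                noise_sd = 0.02, mean_width = 10,
                                seed = NULL) {
  if (is.null(root_schedule)) {
    x <- seq_len(n_dates)
    root_schedule <- 1.5 * stats::plogis((x - n_dates / 2) / (n_dates / 6))
  }
  if (length(root_schedule) > n_dates)
    stop_ap("invalid_input", "root_schedule longer than n_dates")
  root_schedule <- rep_len(root_schedule, n_dates)
  if (is.unsorted(root_schedule))
    stop_ap("invalid_input", "root_schedule must be non-decreasing")
  if (is.null(shifts)) shifts <- matrix(0L, n_dates, 2)
  shifts <- matrix(as.integer(shifts), ncol = 2)
  if (any(abs(shifts) >= min(width, height) / 4))
    stop_ap("invalid_input", "|shifts| must be < image_size / 4")
  doy <- doy %||% seq(160, by = 7, length.out = n_dates)

  px_mm <- 25.4 / dpi
  img_area_cm2 <- height * width * px_mm^2 / 100
  target_px <- root_schedule * img_area_cm2 / px_mm^2  # mm2cm-2 -> pixels

  with_seed(seed, {
    bg <- noise_texture(height, width)
    canvas <- matrix(0, height, width)
    images <- masks <- vector("list", n_dates)
    area_px <- numeric(n_dates)
    for (d in seq_len(n_dates)) {
      canvas <- grow_roots(canvas, target_px[d], mean_width = mean_width)
      mask <- canvas > 0.5
      masks[[d]] <- mask
      area_px[d] <- sum(mask)
      img <- bg + 0.45 * canvas
      if (stripe_amp > 0) {
        offsets <- rnorm(width, 0, stripe_amp)
        img <- img + matrix(offsets, height, width, byrow = TRUE)
      }
      if (noise_sd > 0)
        img <- img + matrix(rnorm(height * width, 0, noise_sd), height, width)
      img <- pmin(pmax(img, 0), 1)
      images[[d]] <- roll_matrix(img, shifts[d, 1], shifts[d, 2])
    }
    structure(list(
      images = images, doy = doy, dpi = dpi, masks = masks,
      true_shifts = shifts, true_area_px = area_px,
      true_area_mm2_cm2 = area_px * px_mm^2 / img_area_cm2,
      shifts = NULL, root_area = NULL
    ), class = "rhizotron_stack")
  })
}

#' @export
print.rhizotron_stack <- function(x, ...) {
  cat(sprintf("rhizotron_stack: %d scans of %d x %d px at %g DPI\n",
              length(x$images), nrow(x$images[[1]]), ncol(x$images[[1]]),
              x$dpi))
  invisible(x)
}
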