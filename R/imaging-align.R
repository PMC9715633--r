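# Phase-correlation alignment of scan stacks and grid tiling.

#' Phase correlation between two images
#'
#' Estimates the integer planar shift (dx, dy) such that `img` is `ref`
#' translated by that amount, by locating the peak of the normalized
#' cross-power spectrum. Circular convention: shifts are reported in
#' (-size/2, size/2].
#'
#' @param ref,img greyscale matrices of identical size.
#' @return List with `dx`, `dy` (integer px) and `peak` (correlation peak
#'   height between 0 and 1; 1 for an exact circular translation).
#' @export
phase_correlate <- function(ref, img) {
  if (!all(dim(ref) == dim(img)))
    stop_ap("invalid_input", "images must have identical dimensions")
  H <- nrow(ref); W <- ncol(ref)
  Fr <- fft2(ref - mean(ref))
  Fi <- fft2(img - mean(img))
  cross <- Fr * Conj(Fi)
  mag <- Mod(cross)
  mag[mag < .Machine$double.eps] <- 1
  surf <- ifft2(cross / mag)
  i <- which.max(surf)
  peak <- surf[i]
  iy <- (i - 1) %% H
  ix <- (i - 1) %/% H
  # surface peaks at the displacement ref -> img
  dx <- -ix; dy <- -iy
  if (dx <= -W / 2) dx <- dx + W
  if (dy <= -H / 2) dy <- dy + H
  list(dx = as.integer(dx), dy = as.integer(dy), peak = as.numeric(peak))
}

#' Align a rhizotron stack by phase correlation
#'
#' Registers every scan against the first of the stack with integer-pixel
#' translations and undoes the shifts (circular resampling). When a scan's
#' correlation peak falls below `peak_floor` the match is considered
#' unreliable: a warning is raised and the shift is set to (0, 0).
#'
#' @param stack a `rhizotron_stack` (see [gen_rhizotron_stack()]) or any list
#'   with an `images` field.
#' @param peak_floor minimum acceptable correlation peak; unrelated images
#'   of this size produce peaks well below 0.02, matching pairs above 0.05.
#' @return The stack with `images` re-aligned and `shifts` (n x 2 matrix of
#'   the detected (dx, dy)) and `peaks` recorded.
#' @export
align_stack <- function(stack, peak_floor = 0.03) {
  n <- length(stack$images)
  if (n < 2) stop_ap("invalid_input", "need at least 2 images to align")
  shifts <- matrix(0L, n, 2)
  peaks <- numeric(n)
  peaks[1] <- 1
  ref <- stack$images[[1]]
  for (i in 2:n) {
    pc <- phase_correlate(ref, stack$images[[i]])
    peaks[i] <- pc$peak
    if (pc$peak < peak_floor) {
      warn_ap("low_confidence",
              "image %d: correlation peak %.3f below floor %.3f; shift set to 0",
              i, pc$peak, peak_floor)
      next
    }
    shifts[i, ] <- c(pc$dx, pc$dy)
    stack$images[[i]] <- roll_matrix(stack$images[[i]], -pc$dx, -pc$dy)
  }
  stack$shifts <- shifts
  stack$peaks <- peaks
  stack
}

# Tile geometry: cropped size and tile size for a grid (remainder cropped).
tile_geometry <- function(width, height, n_cols, n_rows) {
  tw <- width %/% n_cols
  th <- height %/% n_rows
  if (tw < 1 || th < 1) stop_ap("invalid_input", "grid larger than image")
  list(tile_width = tw, tile_height = th,
       crop_width = tw * n_cols, crop_height = th * n_rows)
}

#' Split an image into a grid of sub-images
#'
#' Full-resolution cylinder scans are conventionally split into sub-images
#' (e.g. a 10200 x 8784 px scan into 16 tiles of 2550 x 2196 px) before
#' segmentation. Trailing rows/columns that do not divide evenly are
#' cropped; tiles are returned in row-major order and their concatenation
#' reproduces the cropped original.
#'
#' @param img greyscale matrix.
#' @param n_cols,n_rows grid size.
#' @return List of `n_cols * n_rows` matrices, row-major.
#' @export
tile <- function(img, n_cols, n_rows) {
  g <- tile_geometry(ncol(img), nrow(img), n_cols, n_rows)
  out <- vector("list", n_cols * n_rows)
  k <- 0
  for (r in seq_len(n_rows)) {
    for (cc in seq_len(n_cols)) {
      k <- k + 1
      rows <- ((r - 1) * g$tile_height + 1):(r * g$tile_height)
      cols <- ((cc - 1) * g$tile_width + 1):(cc * g$tile_width)
      out[[k]] <- img[rows, cols, drop = FALSE]
    }
  }
  out
}
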