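# Scanner-artifact removal and intensity normalization for rhizotron scans.

#' Remove vertical striping artifacts
#'
#' Flatbed/cylinder scanners frequently leave column-wise offset stripes.
#' Strictly vertical structure lives on the zero-vertical-frequency row of
#' the 2-D Fourier spectrum; this filter applies a Gaussian notch of width
#' `strength` (in frequency bins) around that row, while protecting the
#' lowest horizontal frequencies (|kx| <= `protect`) so the image mean and
#' large-scale lighting gradients are untouched.
#'
#' @param img greyscale matrix (values on any scale).
#' @param strength Gaussian damping width in vertical-frequency bins.
#' @param protect number of lowest horizontal-frequency columns to leave
#'   unfiltered (the DC column is always kept).
#' @return Filtered matrix, same size; input range is preserved by clipping.
#' @export
destripe <- function(img, strength = 0.7, protect = 2) {
  if (ncol(img) < 16) stop_ap("invalid_input", "image must be >= 16 px wide")
  H <- nrow(img); W <- ncol(img)
  ky <- freq_index(H)
  kx <- freq_index(W)
  damp_y <- 1 - exp(-ky^2 / (2 * strength^2))      # 0 at ky = 0
  keep_x <- abs(kx) <= protect
  damp <- outer(damp_y, rep(1, W))
  damp[, keep_x] <- 1
  lo <- min(img); hi <- max(img)
  out <- ifft2(fft2(img) * damp)
  pmin(pmax(out, lo), hi)
}

#' Normalize brightness and contrast of a greyscale image
#'
#' Linearly rescales intensities to a fixed target mean and standard
#' deviation, optionally after clipping extreme quantiles. The map is
#' monotone and invariant to affine changes of the input (`a * x + b`,
#' `a > 0` gives an identical result), so scans from different sessions
#' become directly comparable.
#'
#' @param img greyscale matrix.
#' @param target_mean,target_sd moments of the output.
#' @param clip_quantiles length-2 vector of quantiles clipped before
#'   rescaling; `c(0, 1)` (default) disables clipping.
#' @return Normalized matrix.
#' @export
normalize_image <- function(img, target_mean = 0.5, target_sd = 0.15,
                            clip_quantiles = c(0, 1)) {
  if (!identical(as.numeric(clip_quantiles), c(0, 1))) {
    q <- quantile(img, clip_quantiles, names = FALSE)
    img <- pmin(pmax(img, q[1]), q[2])
  }
  s <- stats::sd(img)
  if (s == 0) stop_ap("degenerate_normalization", "constant image")
  (img - mean(img)) / s * target_sd + target_mean
}
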