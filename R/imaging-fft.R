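# FFT utilities shared by the imaging operators and the synthetic image
# generator. All 2-D operations use circular (periodic) boundary conditions,
# which keeps translation, rotation-by-180 and pixel-count bookkeeping exact.

# Frequency index vector for length n: 0, 1, ..., floor(n/2), -(...), -1.
freq_index <- function(n) {
  k <- c(0:floor(n / 2), if (n > 1) -(ceiling(n / 2) - 1):-1)
  k[seq_len(n)]
}

fft2 <- function(x) mvfft(t(mvfft(t(x))))
ifft2 <- function(x) {
  n <- length(x)
  Re(Conj(mvfft(t(mvfft(t(Conj(x)))))) / n)
}

# Gaussian low-pass with spatial sd sigma (px), circular boundary.
gaussian_blur <- function(img, sigma) {
  if (sigma <= 0) return(img)
  H <- nrow(img); W <- ncol(img)
  ky <- freq_index(H) / H
  kx <- freq_index(W) / W
  gy <- exp(-2 * pi^2 * sigma^2 * ky^2)
  gx <- exp(-2 * pi^2 * sigma^2 * kx^2)
  ifft2(fft2(img) * outer(gy, gx))
}

# Circular shift: contents move by dx columns (+right) and dy rows (+down).
roll_matrix <- function(img, dx, dy) {
  H <- nrow(img); W <- ncol(img)
  dy <- ((dy %% H) + H) %% H
  dx <- ((dx %% W) + W) %% W
  if (dy > 0) img <- rbind(img[(H - dy + 1):H, , drop = FALSE],
                           img[1:(H - dy), , drop = FALSE])
  if (dx > 0) img <- cbind(img[, (W - dx + 1):W, drop = FALSE],
                           img[, 1:(W - dx), drop = FALSE])
  img
}

# Smooth random texture in [mean +- ~3 sd], used as soil background.
noise_texture <- function(height, width, smooth_sigma = 8, mean = 0.35,
                          sd = 0.04) {
  z <- matrix(rnorm(height * width), height, width)
  z <- gaussian_blur(z, smooth_sigma)
  z <- (z - base::mean(z)) / stats::sd(z)
  mean + sd * z
}
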