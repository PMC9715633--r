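# Imaging operators: greenness, destriping, normalization, alignment,
# tiling, segmentation, quantification.

test_that("canopy_greenness: pure colours, achromatic grey, mixtures", {
  mk <- function(rgb, h = 4, w = 4) {
    img <- array(0, c(h, w, 3))
    for (ch in 1:3) img[, , ch] <- rgb[ch]
    img
  }
  expect_equal(canopy_greenness(mk(c(0, 255, 0))), 1)
  for (k in c(1, 77, 255))
    expect_equal(canopy_greenness(mk(c(k, k, k))), 1 / 3)
  half <- mk(c(0, 255, 0), 4, 8)
  half[, 5:8, 1] <- 255; half[, 5:8, 2] <- 0
  expect_equal(canopy_greenness(half), 0.5)
  expect_equal(canopy_greenness(half, per_pixel = TRUE), 0.5)
})

test_that("canopy_greenness: channel-scaling invariance and ROI handling", {
  set.seed(1)
  img <- array(runif(12 * 12 * 3, 10, 250), c(12, 12, 3))
  for (a in c(0.25, 2, 7.5))
    expect_equal(canopy_greenness(img * a), canopy_greenness(img),
                 tolerance = 1e-12)
  roi <- matrix(FALSE, 12, 12); roi[1:3, 1:3] <- TRUE
  sub <- img[1:3, 1:3, , drop = FALSE]
  expect_equal(canopy_greenness(img, roi), canopy_greenness(sub))
  img0 <- array(0, c(4, 4, 3))
  expect_error(canopy_greenness(img0), class = "undefined_index")
  expect_error(canopy_greenness(img, matrix(FALSE, 12, 12)),
               class = "undefined_index")
})

test_that("destripe: constant image unchanged, stripes removed >= 5x", {
  const <- matrix(0.5, 64, 64)
  expect_equal(destripe(const), const, tolerance = 1e-12)
  set.seed(3)
  clean <- alpinepheno:::noise_texture(256, 256)
  stripes <- matrix(rnorm(256, 0, 20 / 255), 256, 256, byrow = TRUE)
  ds <- destripe(clean + stripes)
  rms_before <- sqrt(mean((stripes)^2))
  rms_after <- sqrt(mean((ds - clean)^2))
  expect_gte(rms_before / rms_after, 5)
  # stripe-free input changed by < 1% RMS
  expect_lt(sqrt(mean((destripe(clean) - clean)^2)), 0.01)
  # near-idempotence
  expect_lt(sqrt(mean((destripe(ds) - ds)^2)), 0.01)
  expect_error(destripe(matrix(0, 8, 8)), class = "invalid_input")
})

test_that("normalize_image: fixed point, affine invariance, monotonicity", {
  set.seed(4)
  x <- matrix(rnorm(900), 30, 30)
  n1 <- normalize_image(x)
  expect_equal(mean(n1), 0.5, tolerance = 1e-12)
  expect_equal(sd(n1), 0.15, tolerance = 1e-12)
  expect_equal(normalize_image(n1), n1, tolerance = 1e-9)      # fixed point
  expect_equal(normalize_image(3.2 * x + 0.7), n1, tolerance = 1e-9)
  ord <- order(x)
  expect_true(!is.unsorted(n1[ord]))                            # monotone
  expect_error(normalize_image(matrix(1, 5, 5)),
               class = "degenerate_normalization")
})

test_that("phase correlation: identity, programmed shifts, noise flag", {
  st <- gen_rhizotron_stack(2, 128, 128, stripe_amp = 0, noise_sd = 0,
                            seed = 2)
  pc <- phase_correlate(st$images[[1]], st$images[[2]])
  expect_identical(c(pc$dx, pc$dy), c(0L, 0L))
  st2 <- gen_rhizotron_stack(3, 128, 128, stripe_amp = 0, noise_sd = 0,
                             root_schedule = c(0.8, 0.8, 0.8),
                             shifts = rbind(c(0, 0), c(5, -3), c(-9, 7)),
                             seed = 2)
  al <- align_stack(st2)
  expect_equal(al$shifts, rbind(c(0L, 0L), c(5L, -3L), c(-9L, 7L)))
  # realigned images reproduce the reference exactly (circular shifts)
  expect_equal(al$images[[2]], al$images[[1]], tolerance = 1e-12)
  # unrelated noise pair: low-confidence flag, shift reset to zero
  set.seed(9)
  noisy <- list(images = list(matrix(runif(256 * 256), 256),
                              matrix(runif(256 * 256), 256)))
  expect_warning(aln <- align_stack(noisy), class = "low_confidence")
  expect_equal(aln$shifts[2, ], c(0L, 0L))
})

test_that("alignment conserves pixel counts under circular shifts", {
  set.seed(5)
  m <- matrix(runif(64 * 64) > 0.8, 64, 64)
  rolled <- alpinepheno:::roll_matrix(m * 1, 7, -11) > 0.5
  expect_identical(sum(rolled), sum(m))
})

test_that("tile: geometry, identity, conservation, reassembly", {
  g <- alpinepheno:::tile_geometry(10200, 8784, 4, 4)
  expect_equal(g$tile_width, 2550)
  expect_equal(g$tile_height, 2196)
  set.seed(6)
  img <- matrix(runif(60 * 80), 60, 80)
  expect_identical(tile(img, 1, 1)[[1]], img)
  tiles <- tile(img, 4, 3)
  expect_length(tiles, 12)
  expect_equal(sum(sapply(tiles, sum)), sum(img), tolerance = 1e-9)
  # row-major reassembly reproduces the original
  rows <- lapply(1:3, function(r) do.call(cbind, tiles[(r - 1) * 4 + 1:4]))
  expect_equal(do.call(rbind, rows), img, tolerance = 1e-12)
  # uneven dimensions are cropped
  tiles2 <- tile(img[1:59, 1:79], 4, 3)
  expect_equal(dim(tiles2[[1]]), c(19, 19))
  expect_error(tile(matrix(0, 2, 2), 4, 4), class = "invalid_input")
})

test_that("segment_roots: blank soil, stroke recovery, 180-degree symmetry", {
  blank <- gen_rhizotron_stack(1, 256, 256, root_schedule = 0, seed = 9)
  img0 <- normalize_image(destripe(blank$images[[1]]))
  expect_lt(mean(segment_roots(img0)), 0.005)
  st <- gen_rhizotron_stack(1, 256, 256, root_schedule = 0.6, seed = 10)
  img <- normalize_image(destripe(st$images[[1]]))
  mask <- segment_roots(img)
  expect_gte(pixel_f1(mask, st$masks[[1]]), 0.8)
  expect_identical(segment_roots(rot180(img)), rot180(segment_roots(img)))
})

test_that("root_area: arithmetic oracle, empty mask, linearity", {
  empty <- matrix(FALSE, 10, 10)
  expect_equal(root_area(empty, 1200)$area_mm2, 0)
  # 10,000 positive px in a 2550 x 2196 frame at 1200 DPI
  mask <- matrix(FALSE, 2196, 2550)
  mask[seq_len(10000)] <- TRUE
  ra <- root_area(mask, 1200)
  expect_equal(ra$area_mm2, (25.4 / 1200)^2 * 10000, tolerance = 1e-9)
  expect_equal(ra$image_area_cm2, 2550 * 2196 * (25.4 / 1200)^2 / 100,
               tolerance = 1e-9)
  expect_equal(ra$area_mm2_cm2, ra$area_mm2 / ra$image_area_cm2,
               tolerance = 1e-12)
  mask2 <- mask; mask2[10001:20000] <- TRUE
  expect_equal(root_area(mask2, 1200)$area_mm2, 2 * ra$area_mm2,
               tolerance = 1e-12)
})

test_that("root_diameters: bar geometry, minimal width, bounds", {
  mask <- matrix(FALSE, 60, 200); mask[26:35, 20:180] <- TRUE
  d <- root_diameters(mask, 1200)
  expect_equal(d$mean_mm, 10 * 25.4 / 1200, tolerance = 0.01)
  # single-pixel line: inscribed-disk convention gives 2 px equivalent
  line <- matrix(FALSE, 20, 50); line[10, 5:45] <- TRUE
  dl <- root_diameters(line, 1200)
  expect_equal(dl$mean_mm, 2 * 25.4 / 1200, tolerance = 1e-9)
  diag_mm <- sqrt(60^2 + 200^2) * 25.4 / 1200
  expect_lte(d$max_mm, diag_mm)
  de <- root_diameters(matrix(FALSE, 5, 5), 1200)
  expect_identical(de$n, 0L)
  expect_true(is.na(de$mean_mm))
})

test_that("process_stack recovers the true area series end to end", {
  st <- gen_rhizotron_stack(4, 512, 512,
                            root_schedule = c(0.3, 0.8, 1.2, 1.4),
                            shifts = rbind(c(0, 0), c(3, -2), c(-4, 5),
                                           c(6, 6)),
                            seed = 12)
  pr <- process_stack(st)
  expect_equal(pr$shifts, st$true_shifts)
  expect_gte(cor(pr$root_area, st$true_area_mm2_cm2), 0.98)
  rel <- abs(pr$root_area - st$true_area_mm2_cm2) / st$true_area_mm2_cm2
  expect_lt(max(rel), 0.10)
})
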