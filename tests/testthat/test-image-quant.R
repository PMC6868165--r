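disk_frame <- function(size, cx, cy, r, inside = 0.2, outside = 0.6,
                       texture = 0.25, seed = 1) {
  set.seed(seed)
  xg <- matrix(rep(seq_len(size), each = size), size)
  yg <- matrix(rep(seq_len(size), times = size), size)
  img <- matrix(outside, size, size)
  sel <- (xg - cx)^2 + (yg - cy)^2 <= r^2
  img[sel] <- inside + texture * runif(sum(sel), -1, 1)
  img + matrix(rnorm(size^2, 0, 0.01), size)
}

test_that("disk-energy centre detection recovers centred and corner disks", {
  fr <- disk_frame(128, 64, 64, 40)
  ctr <- find_center(fr)
  expect_lt(abs(ctr[["cx"]] - 64), 2.01)
  expect_lt(abs(ctr[["cy"]] - 64), 2.01)

  corner <- disk_frame(128, 12, 120, 30)
  ctr2 <- find_center(corner)
  expect_lt(abs(ctr2[["cx"]] - 12), 2.01)
  expect_lt(abs(ctr2[["cy"]] - 120), 2.01)

  expect_error(find_center(matrix(1, 32, 32)),
               class = "collacomp_degenerate_input")
})

test_that("radial graininess separates texture from smooth background", {
  fr <- disk_frame(128, 64, 64, 40, texture = 0.3, seed = 2)
  prof <- radial_graininess(fr, c(64, 64))
  inside <- prof$graininess[prof$radius_px < 30]
  outside <- prof$graininess[prof$radius_px > 50 & prof$radius_px < 60]
  expect_gt(min(inside), 5 * max(outside))

  blank <- matrix(0, 64, 64)
  expect_true(all(radial_graininess(blank, c(32, 32))$graininess == 0))
  expect_error(radial_graininess(fr, c(500, 64)),
               class = "collacomp_domain_error")
})

test_that("white-noise graininess is flat across bins (Monte-Carlo)", {
  set.seed(99)
  fr <- matrix(rnorm(512^2), 512, 512)
  prof <- radial_graininess(fr, c(256, 256))
  big <- prof[prof$n >= 1000, ]
  expect_lt(sd(big$graininess) / mean(big$graininess), 0.2)
})

test_that("spheroid radius is recovered, calibration-invariant, and flags no-contrast", {
  track <- tibble::tibble(time_s = 0, radius_um = 50 * 1.126)
  tl <- gen_spheroid_timelapse(track, frame_size = 128, pixel_size = 1.126,
                               seed = 3)
  r <- spheroid_radius(tl$frames[[1]], pixel_size = 1.126)
  expect_equal(r$radius_um, 56.3, tolerance = 2 * 1.126 / 56.3)

  # the same physical spheroid imaged at twice the sampling gives the same
  # radius in micrometres
  tl2 <- gen_spheroid_timelapse(track, frame_size = 256, pixel_size = 0.563,
                                seed = 3)
  r2 <- spheroid_radius(tl2$frames[[1]], pixel_size = 0.563)
  expect_equal(r2$radius_um, r$radius_um, tolerance = 2 * 1.126 / 56.3)

  tl0 <- gen_spheroid_timelapse(track, frame_size = 128,
                                texture_contrast = 0, seed = 3)
  expect_error(spheroid_radius(tl0$frames[[1]], pixel_size = 1.126),
               class = "collacomp_unreliable_detection")
})

test_that("a growth curve is recovered monotonically within tolerance", {
  gt <- tibble::tibble(time_s = (0:5) * 3600,
                       radius_um = 30 + 25 / (1 + exp(-(0:5 - 2))))
  tl <- gen_spheroid_timelapse(gt, frame_size = 128, pixel_size = 1, seed = 4)
  tr <- track_spheroid(tl)
  expect_true(all(abs(tr$radius_um - gt$radius_um) <= 2.5))
  expect_true(all(diff(tr$radius_um) > -1))

  const <- tibble::tibble(time_s = 0:3, radius_um = rep(50, 4))
  tlc <- gen_spheroid_timelapse(const, frame_size = 128, pixel_size = 1,
                                seed = 5)
  trc <- track_spheroid(tlc)
  expect_true(all(abs(trc$radius_um - 50) <= 2))
})

test_that("global threshold applies the mean + 2 SD and max-over-groups rules", {
  # single constant ROI: SD 0, threshold = the value
  one <- global_threshold(list(g1 = list(matrix(10, 4, 4))))
  expect_equal(one$global, 10)

  # per-image maxima {8, 10, 12}: sample SD 2, threshold 14
  rois <- lapply(c(8, 10, 12), function(m) matrix(c(m, m - 1, 0, 1), 2))
  tr <- global_threshold(list(g1 = rois))
  expect_equal(tr$by_group$threshold, 14)

  # global is the largest group threshold
  two <- global_threshold(list(
    a = list(matrix(12, 2, 2)), b = list(matrix(15, 2, 2))
  ))
  expect_equal(two$global, 15)
  expect_error(global_threshold(list(a = list())),
               class = "collacomp_invalid_argument")
})

test_that("porosity complements the fiber fraction and tracks density", {
  zero <- image_stack(array(0, c(3, 16, 16)), 1, 1, "SHG")
  expect_equal(binarize_and_porosity(zero, 1)$porosity, 1)
  sat <- image_stack(array(100, c(3, 16, 16)), 1, 1, "SHG")
  expect_equal(binarize_and_porosity(sat, 1)$porosity, 0)

  s1 <- gen_shg_stack(fiber_density = 0.02, dim_zyx = c(7, 96, 96), seed = 6)
  s2 <- gen_shg_stack(fiber_density = 0.04, dim_zyx = c(7, 96, 96), seed = 7)
  thr <- 0.3
  p1 <- binarize_and_porosity(s1, thr)
  p2 <- binarize_and_porosity(s2, thr)
  expect_gt(p1$porosity, p2$porosity)
  expect_equal(p1$porosity + p1$fiber_area_fraction, 1)
  expect_equal(p2$porosity + p2$fiber_area_fraction, 1)
})

test_that("masked TPF intensity is a mean over fiber pixels only", {
  mask <- array(FALSE, c(2, 8, 8))
  mask[, , 1:4] <- TRUE
  vals <- array(9, c(2, 8, 8))
  vals[mask] <- 3
  expect_equal(masked_tpf_intensity(vals, mask), 3)
  expect_equal(masked_tpf_intensity(array(7, c(2, 8, 8)), mask), 7)
  expect_equal(masked_tpf_intensity(2 * vals, mask),
               2 * masked_tpf_intensity(vals, mask))
  expect_error(masked_tpf_intensity(vals, array(FALSE, c(2, 8, 8))),
               class = "collacomp_degenerate_input")
  expect_error(masked_tpf_intensity(vals, mask[, , 1:4]),
               class = "collacomp_invalid_argument")
})

test_that("intensity profiles are flat when uniform and conserve total intensity", {
  set.seed(11)
  arr <- array(1 + 0.01 * rnorm(5 * 64 * 64), c(5, 64, 64))
  st <- image_stack(arr, 1, 1, "SHG")
  prof <- radial_shg_profile(st, c(32, 32), bin_width_um = 4)
  core <- prof[prof$radius_um < 30, ]
  expect_lt(max(abs(core$mean_intensity - 1)), 0.02)

  # re-binning conserves the count-weighted mean within 1 %
  p2 <- radial_shg_profile(st, c(32, 32), bin_width_um = 2)
  m1 <- sum(prof$mean_intensity * prof$n) / sum(prof$n)
  m2 <- sum(p2$mean_intensity * p2$n) / sum(p2$n)
  expect_equal(m1, m2, tolerance = 0.01)

  ax <- axial_shg_profile(st)
  expect_identical(nrow(ax), 5L)
  one <- image_stack(array(1, c(1, 8, 8)), 1, 1, "SHG")
  expect_error(axial_shg_profile(one), class = "collacomp_invalid_argument")
})

test_that("gel thickness is read between surface onset and coverslip", {
  arr <- array(0, c(120, 24, 24))
  arr[6:106, , ] <- 1
  st <- image_stack(arr, 1, 10, "SHG")
  th <- gel_thickness(st)
  expect_equal(as.numeric(th), 1000, tolerance = 10 / 1000)

  # a sharp-edged gel is insensitive to the onset fraction
  th_lo <- gel_thickness(st, onset_fraction = 0.3)
  th_hi <- gel_thickness(st, onset_fraction = 0.7)
  expect_lte(abs(th_lo - th_hi), 10)

  empty <- image_stack(array(0, c(20, 8, 8)), 1, 10, "SHG")
  expect_error(gel_thickness(empty),
               class = "collacomp_unreliable_detection")
})

test_that("densified-layer detection separates peaks from attenuation baselines", {
  x <- 0:30
  base <- 10 * exp(-x / 20)
  mono <- tibble::tibble(depth_um = x, mean_intensity = base)
  expect_false(densified_layer_metrics(mono)$layer_detected)

  peak <- base + 6 * exp(-(x - 12)^2 / 4)
  res <- densified_layer_metrics(tibble::tibble(depth_um = x,
                                                mean_intensity = peak))
  expect_true(res$layer_detected)
  expect_lte(abs(res$peak_position - 12), 1)
  # Gaussian of SD 2: FWHM ~ 4.7; detrended half-prominence width similar
  expect_equal(res$width, 4.7, tolerance = 0.35)

  # of two peaks the more prominent wins
  two <- base + 3 * exp(-(x - 8)^2 / 3) + 6 * exp(-(x - 22)^2 / 3)
  res2 <- densified_layer_metrics(tibble::tibble(depth_um = x,
                                                 mean_intensity = two))
  expect_lte(abs(res2$peak_position - 22), 1)

  # generated densified slab is found where it was rendered
  st <- gen_shg_stack(dim_zyx = c(11, 96, 96), densified_layer = c(3, 6, 4),
                      seed = 21)
  res3 <- densified_layer_metrics(axial_shg_profile(st))
  expect_true(res3$layer_detected)
  expect_gte(res3$peak_position, 2)
  expect_lte(res3$peak_position, 7)
})

test_that("stacks round-trip through multi-page TIFF", {
  st <- gen_shg_stack(dim_zyx = c(4, 32, 32), seed = 8)
  path <- withr::local_tempfile(fileext = ".tif")
  write_image_stack(st, path)
  back <- read_image_stack(path, st$pixel_size_xy, st$step_z)
  expect_identical(dim(back$intensities), dim(st$intensities))
  # intensities preserved up to the write-scaling and 16-bit quantization
  sc <- max(st$intensities)
  expect_lt(max(abs(back$intensities - st$intensities / sc)), 1e-4)
})
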