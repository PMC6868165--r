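# FFT-based "same"-size correlation of an image with a small symmetric
# kernel, zero-padded (so partially overlapping kernels near the border see
# only the in-frame pixels). Used by the disk-energy center search.
fft_conv_same <- function(x, kern) {
  dx <- dim(x); dk <- dim(kern)
  P <- c(nextn(dx[1] + dk[1] - 1L, 2), nextn(dx[2] + dk[2] - 1L, 2))
  X <- matrix(0, P[1], P[2]); X[seq_len(dx[1]), seq_len(dx[2])] <- x
  K <- matrix(0, P[1], P[2]); K[seq_len(dk[1]), seq_len(dk[2])] <- kern
  full <- Re(fft(fft(X) * fft(K), inverse = TRUE)) / prod(P)
  ctr <- (dk + 1L) %/% 2L
  full[ctr[1]:(ctr[1] + dx[1] - 1L), ctr[2]:(ctr[2] + dx[2] - 1L)]
}

disk_kernel <- function(r) {
  d <- 2L * as.integer(r) + 1L
  ctr <- r + 1
  xs <- matrix(rep(seq_len(d), each = d), d)
  ys <- matrix(rep(seq_len(d), times = d), d)
  (sqrt((xs - ctr)^2 + (ys - ctr)^2) <= r) * 1
}

#' Locate a spheroid centre by two-phase disk energy minimization
#'
#' Finds the centre of the darkest-vs-brightest two-region partition of the
#' frame over a family of candidate disks: for every centre and every
#' candidate radius, the piecewise-constant segmentation energy (the
#' within-region sum of squares inside and outside the disk, the
#' region-fidelity term of the Mumford-Shah functional) is evaluated in
#' closed form via FFT box sums, the radius is marginalized by taking the
#' best one per centre, and the global minimizer is returned. The search is
#' exhaustive over pixel centres, hence deterministic.
#'
#' @param frame 2-D numeric matrix (rows = y, columns = x).
#' @param radii Candidate disk radii (pixels); default 6 radii spanning
#'   10-45 % of the frame's smaller edge.
#' @return Named numeric `c(cx, cy)` in pixel coordinates (x = column,
#'   y = row, 1-based).
#' @export
find_center <- function(frame, radii = NULL) {
  if (!is.matrix(frame) || !is.numeric(frame)) {
    stop_invalid("`frame` must be a numeric matrix")
  }
  if (sd(frame) == 0) stop_degenerate("frame is constant; no centre exists")
  if (is.null(radii)) {
    radii <- unique(pmax(3L, round(seq(0.10, 0.45, length.out = 6) *
                                     min(dim(frame)))))
  }
  T1 <- sum(frame); T2 <- sum(frame^2); N <- length(frame)
  best <- NULL
  for (r in radii) {
    kern <- disk_kernel(r)
    n_in <- fft_conv_same(matrix(1, nrow(frame), ncol(frame)), kern)
    S1 <- fft_conv_same(frame, kern)
    S2 <- fft_conv_same(frame^2, kern)
    n_in <- pmax(n_in, 1e-9)
    n_out <- pmax(N - n_in, 1e-9)
    ssw <- (S2 - S1^2 / n_in) + ((T2 - S2) - (T1 - S1)^2 / n_out)
    best <- if (is.null(best)) ssw else pmin(best, ssw)
  }
  idx <- arrayInd(which.min(best), dim(best))
  c(cx = idx[1, 2], cy = idx[1, 1])
}

#' Radial graininess profile
#'
#' The graininess of a frame is a first-order approximation to the squared
#' image gradient, `g = (dI/dx)^2 + (dI/dy)^2` by forward differences. This
#' function averages it in annular bins around a centre: textured regions
#' (the spheroid interior) score high, smooth background scores low.
#'
#' @param frame 2-D numeric matrix.
#' @param center Numeric `c(cx, cy)` pixel coordinates, inside the frame.
#' @param bin_width Radial bin width (pixels). Default 1.
#' @return A tibble with columns `radius_px` (bin centre), `graininess`
#'   (mean squared gradient) and `n` (pixels per bin).
#' @export
radial_graininess <- function(frame, center, bin_width = 1) {
  if (!is.matrix(frame)) stop_invalid("`frame` must be a matrix")
  cx <- center[[1]]; cy <- center[[2]]
  if (cx < 1 || cx > ncol(frame) || cy < 1 || cy > nrow(frame)) {
    stop_domain("`center` lies outside the frame")
  }
  nr <- nrow(frame); nc <- ncol(frame)
  gx <- cbind(frame[, -1L, drop = FALSE] - frame[, -nc, drop = FALSE], 0)
  gy <- rbind(frame[-1L, , drop = FALSE] - frame[-nr, , drop = FALSE], 0)
  g <- gx^2 + gy^2
  xs <- matrix(rep(seq_len(nc), each = nr), nr)
  ys <- matrix(rep(seq_len(nr), times = nc), nr)
  rr <- sqrt((xs - cx)^2 + (ys - cy)^2)
  bin <- floor(rr / bin_width)
  counts <- tapply(g, bin, length)
  means <- tapply(g, bin, mean)
  out <- tibble(
    radius_px = (as.numeric(names(means)) + 0.5) * bin_width,
    graininess = as.numeric(means),
    n = as.integer(counts)
  )
  out[order(out$radius_px), ]
}

# The "drops below 75 % of maximum" reading: scanning outward from the
# profile maximum, the radius of the furthest (last) run of >= 2
# consecutive bins in which the profile has fallen below the fraction.
graininess_cutoff_radius <- function(profile, fraction = 0.75) {
  p <- profile$graininess
  im <- which.max(p)
  thr <- fraction * p[im]
  below <- p < thr
  below[seq_len(im)] <- FALSE
  r <- rle(below)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  ok <- which(r$values & r$lengths >= 2L)
  if (length(ok) == 0L) return(NA_real_)
  s <- starts[ok[length(ok)]]
  # interpolate the crossing between the last above-threshold bin and the
  # first bin of the qualifying below-run
  if (s > 1L && p[s - 1L] >= thr && p[s - 1L] != p[s]) {
    return(approx(p[(s - 1L):s], profile$radius_px[(s - 1L):s],
                  xout = thr)$y)
  }
  profile$radius_px[s]
}

#' Spheroid radius from one frame
#'
#' Detects the spheroid centre ([find_center()]), computes the radial
#' graininess profile and reads the radius as the furthest point at which
#' the graininess drops below `fraction` (default 75 %) of its maximum and
#' stays there for at least two bins. A detection is declared unreliable
#' (classed error) when the graininess profile carries no contrast: its
#' maximum is zero or below `reliability_factor` times its median, as for
#' a contrast-free disk or pure noise.
#'
#' @inheritParams radial_graininess
#' @param pixel_size Calibration (um/pixel). Default 1.
#' @param fraction Drop fraction of the 75 % rule. Default 0.75.
#' @param reliability_factor Minimum contrast between the 90th and 10th
#'   percentile of the binned graininess. Default 2.
#' @param min_bin_pixels Bins with fewer pixels (the innermost annuli and
#'   the partially covered outermost ones, whose means are noisy) are
#'   ignored. Default 30.
#' @return A one-row tibble: `radius_um`, `radius_px`, `cx`, `cy`.
#' @export
spheroid_radius <- function(frame, pixel_size = 1, bin_width = 1,
                            fraction = 0.75, reliability_factor = 2,
                            min_bin_pixels = 30) {
  ctr <- find_center(frame)
  prof <- radial_graininess(frame, ctr, bin_width)
  prof <- prof[prof$n >= min_bin_pixels, ]
  g <- prof$graininess
  qs <- quantile(g, c(0.1, 0.9), names = FALSE)
  if (max(g) <= 0 || (qs[1] > 0 && qs[2] < reliability_factor * qs[1])) {
    stop_unreliable("graininess profile is flat; radius detection unreliable")
  }
  r_px <- graininess_cutoff_radius(prof, fraction)
  if (is.na(r_px)) {
    stop_unreliable("graininess never settles below the cutoff; no boundary found")
  }
  tibble(radius_um = r_px * pixel_size, radius_px = r_px,
         cx = ctr[["cx"]], cy = ctr[["cy"]])
}

#' Radius time course from a synthetic or measured time-lapse
#'
#' Applies [spheroid_radius()] to every frame.
#'
#' @param timelapse A [gen_spheroid_timelapse()] result, or a list of
#'   frames.
#' @param pixel_size Calibration (um/pixel); taken from the time-lapse
#'   object when available.
#' @param ... Passed to [spheroid_radius()].
#' @return A tibble with columns `frame`, `time_s` (when known),
#'   `radius_um`.
#' @export
track_spheroid <- function(timelapse, pixel_size = NULL, ...) {
  if (inherits(timelapse, "spheroid_timelapse")) {
    frames <- timelapse$frames
    if (is.null(pixel_size)) pixel_size <- timelapse$pixel_size
    times <- timelapse$track$time_s
  } else {
    frames <- timelapse
    if (is.null(pixel_size)) pixel_size <- 1
    times <- rep(NA_real_, length(frames))
  }
  rows <- purrr::imap(frames, function(fr, i) {
    r <- spheroid_radius(fr, pixel_size = pixel_size, ...)
    tibble(frame = i, time_s = times[i], radius_um = r$radius_um)
  })
  bind_rows(rows)
}

#' Minimum-intensity projection of a stack
#'
#' Collapses a volumetric stack to a 2-D frame by taking the per-pixel
#' minimum across slices, the standard flattening for transmitted-light
#' time-lapse volumes before radius detection.
#'
#' @param stack An [image_stack()].
#' @return A 2-D matrix.
#' @export
min_projection <- function(stack) {
  stopifnot(inherits(stack, "image_stack"))
  apply(stack$intensities, c(2, 3), min)
}

#' Global SHG intensity threshold from background regions
#'
#' For each experimental group, collects the per-image maximum SHG
#' intensity inside a fiber-free background region and sets the group
#' threshold to mean + 2 SD of those maxima (sample SD; a single image
#' gives SD 0). The global threshold is the largest group threshold, so
#' one binarization rule applies across all groups.
#'
#' @param background_rois A named list (one element per group) of lists of
#'   numeric matrices/arrays, each a background ROI from one image.
#' @return An object of class `threshold_report`: list with `by_group`
#'   (tibble: `group`, `n_images`, `mean_max`, `sd_max`, `threshold`) and
#'   `global`.
#' @examples
#' global_threshold(list(
#'   ctrl = list(matrix(c(7, 8, 9, 8), 2)),
#'   xl = list(matrix(c(9, 10, 12, 11), 2))
#' ))
#' @export
global_threshold <- function(background_rois) {
  if (!is.list(background_rois) || length(background_rois) == 0L) {
    stop_invalid("`background_rois` must be a non-empty list of groups")
  }
  if (is.null(names(background_rois))) {
    names(background_rois) <- paste0("group", seq_along(background_rois))
  }
  rows <- purrr::imap(background_rois, function(rois, grp) {
    if (!is.list(rois) || length(rois) == 0L) {
      stop_invalid(sprintf("group '%s' must contain at least one ROI", grp))
    }
    maxima <- vapply(rois, function(r) {
      if (length(r) == 0L) stop_invalid("empty ROI")
      max(r)
    }, numeric(1))
    s <- if (length(maxima) > 1L) sd(maxima) else 0
    tibble(group = grp, n_images = length(maxima),
           mean_max = mean(maxima), sd_max = s,
           threshold = mean(maxima) + 2 * s)
  })
  by_group <- bind_rows(rows)
  structure(
    list(by_group = by_group, global = max(by_group$threshold)),
    class = "threshold_report"
  )
}

#' @export
print.threshold_report <- function(x, ...) {
  cat("<threshold_report>\n")
  print(as.data.frame(x$by_group), row.names = FALSE)
  cat(sprintf("  global threshold (max over groups): %.4g\n", x$global))
  invisible(x)
}

#' Binarize a stack and quantify porosity
#'
#' Pixels at or above the threshold are fiber; the fiber area fraction is
#' the per-slice mean of the mask averaged over slices, and the areal
#' porosity its complement. For randomly oriented fibers the areal porosity
#' equals the volumetric porosity, so this is the porosity estimate
#' reported for a gel.
#'
#' @param stack An [image_stack()] (SHG channel).
#' @param threshold Intensity threshold, >= 0 (from [global_threshold()]).
#' @return An object of class `porosity_result`: list with `mask` (logical
#'   array), `fiber_area_fraction`, `porosity`
#'   (`= 1 - fiber_area_fraction`, exactly) and `by_slice` (tibble:
#'   `slice`, `fiber_area_fraction`).
#' @export
binarize_and_porosity <- function(stack, threshold) {
  stopifnot(inherits(stack, "image_stack"))
  if (!is.numeric(threshold) || threshold < 0) {
    stop_invalid("`threshold` must be >= 0")
  }
  mask <- stack$intensities >= threshold
  by_slice <- tibble(
    slice = seq_len(n_slices(stack)),
    fiber_area_fraction = apply(mask, 1, mean)
  )
  faf <- mean(by_slice$fiber_area_fraction)
  structure(
    list(mask = mask, fiber_area_fraction = faf, porosity = 1 - faf,
         by_slice = by_slice),
    class = "porosity_result"
  )
}

#' @export
print.porosity_result <- function(x, ...) {
  cat(sprintf("<porosity_result> fiber area fraction %.4g, porosity %.4g (%d slices)\n",
              x$fiber_area_fraction, x$porosity, nrow(x$by_slice)))
  invisible(x)
}

#' Mean TPF intensity under the SHG fiber mask
#'
#' Applies the SHG-derived fiber mask to the co-registered TPF channel and
#' averages the TPF intensity over fiber pixels only, isolating the
#' autofluorescence of the collagen itself.
#'
#' @param tpf An [image_stack()] (TPF channel) or numeric array.
#' @param mask Logical array of identical dimensions (from
#'   [binarize_and_porosity()], element `mask`).
#' @return Mean intensity (scalar).
#' @export
masked_tpf_intensity <- function(tpf, mask) {
  arr <- if (inherits(tpf, "image_stack")) tpf$intensities else tpf
  if (!identical(dim(arr), dim(mask))) {
    stop_invalid("TPF stack and mask dimensions must match")
  }
  if (!any(mask)) {
    stop_degenerate("mask is empty; masked mean intensity is undefined")
  }
  mean(arr[mask])
}

#' Radial mean-intensity profile around a centre
#'
#' Pools all slices of a stack and averages intensity in annular bins of
#' width `bin_width_um` around the given centre (e.g. the spheroid centre
#' from [find_center()]). The densified collagen capsule around a grown
#' spheroid appears as a sharp peak on this profile.
#'
#' @param stack An [image_stack()].
#' @param center `c(cx, cy)` pixel coordinates.
#' @param bin_width_um Radial bin width (um). Default 2.
#' @return A tibble with columns `radius_um` (bin centre),
#'   `mean_intensity`, `n`.
#' @export
radial_shg_profile <- function(stack, center, bin_width_um = 2) {
  stopifnot(inherits(stack, "image_stack"))
  d <- dim(stack$intensities)
  cx <- center[[1]]; cy <- center[[2]]
  if (cx < 1 || cx > d[3] || cy < 1 || cy > d[2]) {
    stop_domain("`center` lies outside the frame")
  }
  xs <- matrix(rep(seq_len(d[3]), each = d[2]), d[2])
  ys <- matrix(rep(seq_len(d[2]), times = d[3]), d[2])
  r_um <- sqrt((xs - cx)^2 + (ys - cy)^2) * stack$pixel_size_xy
  bin <- floor(r_um / bin_width_um)
  sums <- counts <- numeric(0)
  for (z in seq_len(d[1])) {
    sl <- stack$intensities[z, , ]
    s <- tapply(sl, bin, sum)
    if (z == 1L) {
      sums <- s
      counts <- tapply(sl, bin, length)
    } else {
      sums <- sums + s
      counts <- counts + tapply(sl, bin, length)
    }
  }
  out <- tibble(
    radius_um = (as.numeric(names(sums)) + 0.5) * bin_width_um,
    mean_intensity = as.numeric(sums / counts),
    n = as.integer(counts)
  )
  out[order(out$radius_um), ]
}

#' Axial mean-intensity profile of a stack
#'
#' Mean intensity of each optical section against depth
#' `zeta = (slice - 1) * step_z`. The natural decay with depth reflects
#' scattering and absorption; a densified surface layer appears as a peak
#' riding on that decay (see [densified_layer_metrics()]).
#'
#' @param stack An [image_stack()] with at least 2 slices.
#' @return A tibble with columns `depth_um`, `mean_intensity`, `n`.
#' @export
axial_shg_profile <- function(stack) {
  stopifnot(inherits(stack, "image_stack"))
  nz <- n_slices(stack)
  if (nz < 2L) stop_invalid("axial profile requires at least 2 slices")
  tibble(
    depth_um = (seq_len(nz) - 1) * stack$step_z,
    mean_intensity = apply(stack$intensities, 1, mean),
    n = as.integer(rep(prod(dim(stack$intensities)[2:3]), nz))
  )
}

#' Gel thickness from an axial profile
#'
#' The gel occupies the depth range over which the axial intensity profile
#' stays above `onset_fraction` of its maximum: the thickness is the
#' distance between the surface onset (first sustained crossing, at least
#' two consecutive slices) and the coverslip-side end (last sustained
#' crossing). The frame is split into `n_regions` lateral sub-regions, each
#' measured independently, and the mean is reported.
#'
#' @param stack An [image_stack()] spanning the full gel depth.
#' @param onset_fraction Fraction of the per-region profile maximum that
#'   counts as gel signal. Default 0.5.
#' @param n_regions Number of lateral sub-regions. Default 3.
#' @return Thickness (um), the mean over sub-regions, with per-region
#'   values in attribute `"by_region"`.
#' @export
gel_thickness <- function(stack, onset_fraction = 0.5, n_regions = 3) {
  stopifnot(inherits(stack, "image_stack"))
  if (onset_fraction <= 0 || onset_fraction >= 1) {
    stop_invalid("`onset_fraction` must be in (0, 1)")
  }
  d <- dim(stack$intensities)
  if (d[1] < 3L) stop_invalid("thickness measurement requires >= 3 slices")
  edges <- round(seq(0, d[3], length.out = n_regions + 1L))
  per_region <- vapply(seq_len(n_regions), function(rg) {
    cols <- (edges[rg] + 1L):edges[rg + 1L]
    prof <- apply(stack$intensities[, , cols, drop = FALSE], 1, mean)
    if (max(prof) <= 0) return(NA_real_)
    above <- prof >= onset_fraction * max(prof)
    r <- rle(above)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    ok <- which(r$values & r$lengths >= 2L)
    if (length(ok) == 0L) return(NA_real_)
    onset <- starts[ok[1]]
    bottom <- ends[ok[length(ok)]]
    (bottom - onset) * stack$step_z
  }, numeric(1))
  if (all(is.na(per_region))) {
    stop_unreliable("no sustained gel signal detected in any sub-region")
  }
  out <- mean(per_region, na.rm = TRUE)
  attr(out, "by_region") <- per_region
  out
}

#' Detect a densified layer on an intensity profile
#'
#' Removes the attenuation baseline by fitting a single exponential to the
#' profile (excluding a guard band around the candidate peak) and searches
#' the detrended residual for local maxima. The most prominent peak above
#' the prominence floor is reported with its position and full width at
#' half prominence; ties break towards the smaller coordinate. A profile
#' without a qualifying peak returns a `layer_detected = FALSE` row, not an
#' error: "no densified layer" is a legitimate measurement.
#'
#' @param profile A tibble from [axial_shg_profile()] or
#'   [radial_shg_profile()] (coordinate column first, then
#'   `mean_intensity`); at least 5 bins.
#' @param prominence_floor Minimum peak prominence as a fraction of the
#'   profile's intensity range. Default 0.1.
#' @param guard_frac Half-width of the baseline-exclusion guard band
#'   around the candidate peak, as a fraction of the coordinate range.
#'   Default 0.15.
#' @return A one-row tibble: `layer_detected`, `peak_position`,
#'   `prominence`, `width` (same units as the coordinate column).
#' @export
densified_layer_metrics <- function(profile, prominence_floor = 0.1,
                                    guard_frac = 0.15) {
  if (!is.data.frame(profile) || !("mean_intensity" %in% names(profile))) {
    stop_invalid("`profile` must contain a `mean_intensity` column")
  }
  xcol <- setdiff(names(profile), c("mean_intensity", "n"))[1]
  x <- profile[[xcol]]
  y <- profile$mean_intensity
  if (length(x) < 5L) stop_invalid("profile must have at least 5 bins")

  no_layer <- tibble(layer_detected = FALSE, peak_position = NA_real_,
                     prominence = NA_real_, width = NA_real_)
  rng <- max(y) - min(y)
  if (rng <= 0) return(no_layer)

  fit_baseline <- function(exclude) {
    keep <- setdiff(seq_along(x), exclude)
    if (length(keep) < 3L) keep <- seq_along(x)
    eps <- 1e-6 * max(y)
    co <- coef(lm(log(pmax(y[keep], eps)) ~ x[keep]))
    exp(co[1] + co[2] * x)
  }
  resid1 <- y - fit_baseline(integer(0))
  cand <- which.max(resid1)
  guard <- which(abs(x - x[cand]) <= guard_frac * (max(x) - min(x)))
  detr <- y - fit_baseline(guard)

  pk <- peak_prominences(detr)
  # floor: a fraction of the profile range, but never below the noise level
  # of the detrended baseline (5 x its robust SD outside the guard band)
  noise <- stats::mad(detr[setdiff(seq_along(x), guard)])
  floor_abs <- max(prominence_floor * rng, 5 * noise, 0)
  pk <- pk[detr[pk$index] > 0 & pk$prominence >= floor_abs, ]
  if (nrow(pk) == 0L) return(no_layer)
  pk <- pk[order(-pk$prominence, x[pk$index]), ]
  ip <- pk$index[1]
  prom <- pk$prominence[1]
  half <- detr[ip] - prom / 2

  cross <- function(side) {
    idx <- if (side == "left") rev(seq_len(ip - 1L)) else
      (ip + 1L):length(x)
    if (ip == 1L && side == "left") return(x[1])
    if (ip == length(x) && side == "right") return(x[length(x)])
    for (i in idx) {
      if (detr[i] <= half) {
        j <- if (side == "left") i + 1L else i - 1L
        return(approx(detr[c(i, j)], x[c(i, j)], xout = half)$y)
      }
    }
    if (side == "left") x[1] else x[length(x)]
  }
  tibble(layer_detected = TRUE, peak_position = x[ip], prominence = prom,
         width = cross("right") - cross("left"))
}
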