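#' Synthetic SHG stack of a random fiber suspension
#'
#' Renders straight 3-D line segments (uniform positions and orientations)
#' into a voxel grid, blurs each slice with a Gaussian point-spread
#' stand-in, attenuates exponentially with depth, and optionally adds a
#' densified surface slab with amplified fiber density. This is a
#' structural phantom sufficient to exercise thresholding, porosity and
#' profile analyses; it is not a physical SHG image-formation model.
#'
#' @param fiber_density Fibers per um^3 of box volume. Default 0.02.
#' @param dim_zyx Stack dimensions `(z, y, x)` in voxels. Default
#'   `c(11, 128, 128)`.
#' @param pixel_size_xy Lateral calibration (um/pixel). Default 0.805.
#' @param step_z Axial step (um). Default 1.
#' @param fiber_length_um Rendered segment length (um). Default 8.
#' @param attenuation_length Depth attenuation length (um), > 0.
#'   Default 50.
#' @param psf_sigma Gaussian blur SD (um). Default 0.8.
#' @param densified_layer Optional `c(depth_from, depth_to, amplification)`
#'   (um, um, fold-increase in local fiber density) describing a densified
#'   surface slab.
#' @param noise_sd Additive Gaussian noise SD, in units of the mean fiber
#'   signal. Default 0.02.
#' @param seed Integer seed.
#' @return An [image_stack()] (channel `"SHG"`) with the generation ground
#'   truth in attribute `"truth"`.
#' @export
gen_shg_stack <- function(fiber_density = 0.02, dim_zyx = c(11, 128, 128),
                          pixel_size_xy = 0.805, step_z = 1,
                          fiber_length_um = 8, attenuation_length = 50,
                          psf_sigma = 0.8, densified_layer = NULL,
                          noise_sd = 0.02, seed = NULL) {
  check_positive_scalar(fiber_density, "fiber_density")
  check_positive_scalar(attenuation_length, "attenuation_length")
  if (!is.null(densified_layer) &&
      (length(densified_layer) != 3L || densified_layer[1] < 0 ||
       densified_layer[2] <= densified_layer[1] || densified_layer[3] <= 0)) {
    stop_invalid("`densified_layer` must be c(depth_from, depth_to, amplification)")
  }
  nz <- dim_zyx[1]; ny <- dim_zyx[2]; nx <- dim_zyx[3]
  Lx <- nx * pixel_size_xy; Ly <- ny * pixel_size_xy; Lz <- nz * step_z
  n_fibers <- max(1L, round(fiber_density * Lx * Ly * Lz))
  # count scaled up for the extended sampling volume
  ext <- (Lx + fiber_length_um) * (Ly + fiber_length_um) *
    (Lz + fiber_length_um) / (Lx * Ly * Lz)
  n_fibers_ext <- max(1L, round(n_fibers * ext))

  arr <- with_seed(seed, {
    a <- array(0, c(nz, ny, nx))
    # fiber centres are sampled in a margin-extended volume so every voxel
    # sees the same expected fiber coverage (no edge depletion)
    mrg <- fiber_length_um / 2
    render_fibers <- function(a, n, z_range) {
      for (f in seq_len(n)) {
        ctr <- c(runif(1, -mrg, Lx + mrg), runif(1, -mrg, Ly + mrg),
                 runif(1, z_range[1], z_range[2]))
        u <- rnorm(3); u <- u / sqrt(sum(u^2))
        s <- seq(-fiber_length_um / 2, fiber_length_um / 2,
                 by = pixel_size_xy / 2)
        px <- ctr[1] + s * u[1]
        py <- ctr[2] + s * u[2]
        pz <- ctr[3] + s * u[3]
        ix <- floor(px / pixel_size_xy) + 1L
        iy <- floor(py / pixel_size_xy) + 1L
        iz <- floor(pz / step_z) + 1L
        ok <- ix >= 1L & ix <= nx & iy >= 1L & iy <= ny &
          iz >= 1L & iz <= nz
        if (!any(ok)) next
        idx <- cbind(iz[ok], iy[ok], ix[ok])
        for (r in seq_len(nrow(idx))) {
          a[idx[r, 1], idx[r, 2], idx[r, 3]] <-
            a[idx[r, 1], idx[r, 2], idx[r, 3]] + 1
        }
      }
      a
    }
    a <- render_fibers(a, n_fibers_ext, c(-mrg, Lz + mrg))
    if (!is.null(densified_layer)) {
      slab <- c(densified_layer[1], min(densified_layer[2], Lz))
      frac <- (slab[2] - slab[1]) / Lz
      n_extra <- round(n_fibers * ext * frac * (densified_layer[3] - 1))
      if (n_extra > 0) a <- render_fibers(a, n_extra, slab)
    }
    # per-slice Gaussian blur as PSF stand-in
    sig_px <- psf_sigma / pixel_size_xy
    if (sig_px > 0.05) {
      for (z in seq_len(nz)) {
        a[z, , ] <- as.numeric(EBImage::gblur(a[z, , ], sigma = sig_px))
      }
    }
    mean_sig <- mean(a[a > 0])
    if (!is.finite(mean_sig)) mean_sig <- 1
    # depth attenuation (scattering/absorption) then additive noise
    for (z in seq_len(nz)) {
      zeta <- (z - 1) * step_z
      a[z, , ] <- a[z, , ] * exp(-zeta / attenuation_length)
    }
    if (noise_sd > 0) {
      a <- a + array(rnorm(length(a), 0, noise_sd * mean_sig), dim(a))
    }
    pmax(a, 0)
  })
  out <- image_stack(arr, pixel_size_xy, step_z, "SHG")
  attr(out, "truth") <- list(
    n_fibers = n_fibers, fiber_density = fiber_density,
    densified_layer = densified_layer,
    attenuation_length = attenuation_length, seed = seed
  )
  out
}

#' Synthetic time-lapse of a growing textured spheroid
#'
#' Produces one frame per row of `track`: a disk of the prescribed radius
#' carrying high-frequency speckle texture (amplitude `texture_contrast`)
#' on a smooth, weakly textured background, lightly blurred. The frames
#' emulate minimum-intensity-projected transmitted-light images of a
#' spheroid in a gel, and the texture step at the boundary is what the
#' graininess radius detector keys on.
#'
#' @param track Data frame with columns `time_s`, `radius_um`.
#' @param frame_size Frame edge (pixels). Default 128.
#' @param pixel_size Calibration (um/pixel). Default 1.126.
#' @param texture_contrast Speckle amplitude inside the spheroid relative
#'   to the background level; 0 gives an (undetectable) contrast-free
#'   disk. Default 0.5.
#' @param seed Integer seed.
#' @return An object of class `spheroid_timelapse`: list with `frames`
#'   (list of matrices), `track` (ground truth) and `pixel_size`.
#' @export
gen_spheroid_timelapse <- function(track, frame_size = 128,
                                   pixel_size = 1.126,
                                   texture_contrast = 0.5, seed = NULL) {
  track <- validate_spheroid_track(track)
  if (texture_contrast < 0) stop_invalid("`texture_contrast` must be >= 0")
  r_px <- track$radius_um / pixel_size
  if (any(r_px >= frame_size / 2)) {
    stop_invalid("spheroid radius must stay below half the frame width")
  }
  ctr <- (frame_size + 1) / 2
  xg <- matrix(rep(seq_len(frame_size), each = frame_size), frame_size)
  yg <- matrix(rep(seq_len(frame_size), times = frame_size), frame_size)
  rr <- sqrt((xg - ctr)^2 + (yg - ctr)^2)
  frames <- with_seed(seed, {
    lapply(r_px, function(r) {
      speck <- matrix(runif(frame_size^2, -1, 1), frame_size)
      img <- matrix(0.55, frame_size, frame_size)
      inside <- rr <= r
      # the spheroid is darker on average and speckled; both the offset and
      # the texture scale with the contrast so zero contrast is invisible
      img[inside] <- 0.55 - 0.3 * texture_contrast +
        0.5 * texture_contrast * speck[inside]
      # camera noise over the whole frame
      img <- img + matrix(rnorm(frame_size^2, 0, 0.01), frame_size)
      as.numeric(EBImage::gblur(img, sigma = 0.6)) |>
        matrix(frame_size, frame_size) |>
        pmax(0)
    })
  })
  structure(
    list(frames = frames, track = track, pixel_size = pixel_size),
    class = "spheroid_timelapse"
  )
}
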