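#' Calibrated volumetric image stack
#'
#' A 3-D intensity array (z, y, x) with lateral pixel size, axial step and
#' a channel label. Slice index 1 is the objective-side (compressed)
#' surface; depth `zeta = (slice - 1) * step_z`.
#'
#' @param intensities 3-D numeric array `(z, y, x)`, non-negative.
#' @param pixel_size_xy Lateral calibration (um/pixel).
#' @param step_z Axial step between slices (um).
#' @param channel Channel label, `"SHG"` or `"TPF"`.
#' @return An object of class `image_stack`.
#' @export
image_stack <- function(intensities, pixel_size_xy, step_z,
                        channel = c("SHG", "TPF")) {
  channel <- match.arg(channel)
  if (!is.array(intensities) || length(dim(intensities)) != 3L) {
    stop_invalid("`intensities` must be a 3-D array (z, y, x)")
  }
  if (any(dim(intensities) < 1L)) stop_invalid("all dimensions must be >= 1")
  if (any(intensities < 0)) stop_invalid("intensities must be non-negative")
  check_positive_scalar(pixel_size_xy, "pixel_size_xy")
  check_positive_scalar(step_z, "step_z")
  structure(
    list(intensities = intensities, pixel_size_xy = pixel_size_xy,
         step_z = step_z, channel = channel),
    class = "image_stack"
  )
}

#' @export
print.image_stack <- function(x, ...) {
  d <- dim(x$intensities)
  cat(sprintf("<image_stack> %s, %d slices of %d x %d px (%.3g um/px, dz = %g um)\n",
              x$channel, d[1], d[2], d[3], x$pixel_size_xy, x$step_z))
  invisible(x)
}

n_slices <- function(stack) dim(stack$intensities)[1]

#' Read / write an image stack as multi-page TIFF
#'
#' Grayscale multi-page TIFF; intensities are scaled to \[0, 1\] on write
#' (the scale factor is irrelevant to every threshold-relative
#' quantification in the package) and calibration must be re-supplied on
#' read, as baseline TIFF carries no reliable axial metadata.
#'
#' @param stack An [image_stack()].
#' @param path File path.
#' @return `write_image_stack()` returns `path` invisibly;
#'   `read_image_stack()` returns an [image_stack()].
#' @export
write_image_stack <- function(stack, path) {
  stopifnot(inherits(stack, "image_stack"))
  mx <- max(stack$intensities)
  sc <- if (mx > 0) mx else 1
  pages <- lapply(seq_len(n_slices(stack)), function(z) {
    stack$intensities[z, , ] / sc
  })
  tiff::writeTIFF(pages, path, bits.per.sample = 16L)
  invisible(path)
}

#' @inheritParams image_stack
#' @rdname write_image_stack
#' @export
read_image_stack <- function(path, pixel_size_xy, step_z, channel = "SHG") {
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  arr <- array(0, c(length(pages), nrow(pages[[1]]), ncol(pages[[1]])))
  for (z in seq_along(pages)) {
    pg <- pages[[z]]
    if (length(dim(pg)) == 3L) pg <- pg[, , 1]  # collapse RGB if present
    arr[z, , ] <- pg
  }
  image_stack(arr, pixel_size_xy, step_z, channel)
}
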