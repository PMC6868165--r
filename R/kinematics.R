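#' Principal stretches at the boundary of an expanding spheroid
#'
#' Models the growing spheroid as an expanding spherical inclusion in an
#' infinite, isotropic, incompressible matrix. A material point on the
#' spheroid-collagen boundary (initial radius `a0`) displaced to current
#' radius `a` experiences tangential stretches `lambda_theta = lambda_phi =
#' a/a0` and, by incompressibility, a radial stretch `lambda_r = (a0/a)^2`.
#' For a growing spheroid (`a > a0`) the matrix is therefore radially
#' compressed and tangentially stretched.
#'
#' @param a0 Initial spheroid radius (um), positive scalar.
#' @param a Current spheroid radius (um), positive; vectorized.
#' @return A tibble with columns `lambda_r`, `lambda_theta`, `lambda_phi`.
#' @examples
#' boundary_stretches(100, 125)  # lambda_theta = 1.25, lambda_r = 0.64
#' @export
boundary_stretches <- function(a0, a) {
  check_positive_scalar(a0, "a0")
  if (!is.numeric(a) || any(!is.finite(a)) || any(a <= 0)) {
    stop_invalid("`a` must be positive and finite")
  }
  lt <- a / a0
  tibble(lambda_r = 1 / lt^2, lambda_theta = lt, lambda_phi = lt)
}

#' Stretch field around an expanding spherical inclusion
#'
#' For a material point initially at radius `R >= a0` in the matrix, cavity
#' expansion of an incompressible medium maps it to the current radius
#' `(R^3 + a^3 - a0^3)^(1/3)` (called `r` below), giving
#' `lambda_theta = r/R` and
#' `lambda_r = (R/r)^2`. At `R = a0` this reduces to [boundary_stretches()],
#' and both stretches tend to 1 far from the spheroid.
#'
#' @inheritParams boundary_stretches
#' @param R Initial (material) radius of the evaluation point (um),
#'   vectorized; must satisfy `R >= a0`.
#' @return A tibble with columns `R`, `r`, `lambda_r`, `lambda_theta`,
#'   `lambda_phi`.
#' @examples
#' stretch_field(100, 125, c(100, 200, 1000))
#' @export
stretch_field <- function(a0, a, R) {
  check_positive_scalar(a0, "a0")
  check_positive_scalar(a, "a")
  if (any(!is.finite(R)) || any(R < a0)) {
    stop_domain("`R` must be finite and >= a0 (points inside the inclusion have no matrix stretch)")
  }
  r <- (R^3 + a^3 - a0^3)^(1 / 3)
  lt <- r / R
  tibble(R = R, r = r, lambda_r = 1 / lt^2, lambda_theta = lt, lambda_phi = lt)
}

#' Stretch time course from a spheroid growth track
#'
#' Applies [boundary_stretches()] along a measured radius time course, taking
#' the first radius as the reference `a0`.
#'
#' @param track A data frame with columns `time_s` and `radius_um` (radii
#'   positive, times strictly increasing), e.g. from [read_spheroid_track()]
#'   or [track_spheroid()].
#' @return A tibble with columns `time_s`, `radius_um`, `lambda_r`,
#'   `lambda_theta`, `lambda_phi`.
#' @examples
#' track <- tibble::tibble(time_s = c(0, 3600, 7200),
#'                         radius_um = c(100, 110, 125))
#' track_to_stretches(track)
#' @export
track_to_stretches <- function(track) {
  track <- validate_spheroid_track(track)
  st <- boundary_stretches(track$radius_um[1], track$radius_um)
  dplyr::bind_cols(track[c("time_s", "radius_um")], st)
}

validate_spheroid_track <- function(track) {
  if (!is.data.frame(track) || !all(c("time_s", "radius_um") %in% names(track))) {
    stop_invalid("track must have columns `time_s` and `radius_um`")
  }
  if (nrow(track) < 1L) stop_invalid("track must contain at least one sample")
  if (any(track$radius_um <= 0)) stop_invalid("radii must be positive")
  if (is.unsorted(track$time_s, strictly = TRUE)) {
    stop_invalid("times must be strictly increasing")
  }
  as_tibble(track)
}

#' Read / write a spheroid radius track
#'
#' Delimited text with header columns `time_s,radius_um`.
#'
#' @param path File path.
#' @return A tibble with columns `time_s`, `radius_um`.
#' @export
read_spheroid_track <- function(path) {
  df <- utils::read.csv(path)
  validate_spheroid_track(df)
}

#' @param track Data frame with columns `time_s`, `radius_um`.
#' @rdname read_spheroid_track
#' @export
write_spheroid_track <- function(track, path) {
  track <- validate_spheroid_track(track)
  utils::write.csv(as.data.frame(track)[c("time_s", "radius_um")], path,
                   row.names = FALSE)
  invisible(path)
}

#' Plot matrix stretches along a growth track
#'
#' @param stretches Output of [track_to_stretches()].
#' @return A ggplot object.
#' @export
plot_stretch_track <- function(stretches) {
  df <- tidyr::pivot_longer(stretches, c("lambda_r", "lambda_theta"),
                            names_to = "component", values_to = "lambda")
  ggplot(df, aes(x = .data$time_s / 3600, y = .data$lambda,
                 colour = .data$component)) +
    geom_line() +
    geom_hline(yintercept = 1, linetype = 2, colour = "grey50") +
    labs(x = "time (h)", y = "stretch ratio",
         colour = NULL)
}
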