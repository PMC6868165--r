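#' Confined-compression specimen geometry
#'
#' Describes one cylindrical gel mounted in the confined-compression chamber.
#' All lengths are in metres (SI units throughout the package). The unloaded
#' thickness `H` is the gel height after the initial precompression that seats
#' the indenter; it is metadata of the experiment and is never inferred from
#' the trace. The rheometer gap includes the glass coverslip, so the deformed
#' gel thickness is `gap - coverslip_thickness`.
#'
#' @param thickness Unloaded gel thickness H (m). Default 3 mm.
#' @param indenter_diameter Diameter D of the porous indenter (m). Default 8 mm.
#' @param coverslip_thickness Glass coverslip thickness (m). Default 170 um
#'   (a #1.5 coverslip).
#' @param force_offset Baseline force f_off (N) registered at contact, any
#'   sign. Subtracted from measured force before converting to stress.
#' @return An object of class `gel_geometry`.
#' @examples
#' gel_geometry()
#' @export
gel_geometry <- function(thickness = 3e-3,
                         indenter_diameter = 8e-3,
                         coverslip_thickness = 170e-6,
                         force_offset = 0) {
  check_positive_scalar(thickness, "thickness")
  check_positive_scalar(indenter_diameter, "indenter_diameter")
  check_positive_scalar(coverslip_thickness, "coverslip_thickness")
  if (!is.numeric(force_offset) || length(force_offset) != 1L ||
      !is.finite(force_offset)) {
    stop_invalid("`force_offset` must be a single finite number")
  }
  structure(
    list(
      thickness = thickness,
      indenter_diameter = indenter_diameter,
      coverslip_thickness = coverslip_thickness,
      force_offset = force_offset
    ),
    class = "gel_geometry"
  )
}

#' @export
print.gel_geometry <- function(x, ...) {
  cat("<gel_geometry>\n")
  cat(sprintf("  H (unloaded thickness): %.3g mm\n", x$thickness * 1e3))
  cat(sprintf("  indenter diameter D:    %.3g mm\n", x$indenter_diameter * 1e3))
  cat(sprintf("  coverslip thickness:    %.3g um\n", x$coverslip_thickness * 1e6))
  cat(sprintf("  force offset f_off:     %.3g N\n", x$force_offset))
  invisible(x)
}

indenter_area <- function(geometry) {
  pi * geometry$indenter_diameter^2 / 4
}

#' Multi-step stress-relaxation protocol
#'
#' A sequence of identical compression steps: each step ramps the axial
#' stretch down by `step_strain` at a constant rate `ramp_rate` and then holds
#' the gap fixed for `hold_duration` while the force relaxes.
#'
#' @param step_strain Strain increment per step, as a fraction of the unloaded
#'   thickness. Default 0.03 (3 % steps).
#' @param ramp_rate Compression rate in strain per second. Default 0.01
#'   (1 %/s), giving a 3 s ramp for a 3 % step.
#' @param hold_duration Hold time after each ramp (s). Default 180.
#' @param n_steps Number of steps. Default 6 (18 % total compression).
#' @return An object of class `step_protocol`.
#' @examples
#' step_protocol()                 # 6 x 3 % steps, 180 s holds
#' step_protocol(n_steps = 5)      # 15 % total
#' @export
step_protocol <- function(step_strain = 0.03,
                          ramp_rate = 0.01,
                          hold_duration = 180,
                          n_steps = 6) {
  check_positive_scalar(step_strain, "step_strain")
  if (step_strain >= 1) stop_invalid("`step_strain` must be < 1")
  check_positive_scalar(ramp_rate, "ramp_rate")
  check_positive_scalar(hold_duration, "hold_duration")
  check_positive_scalar(n_steps, "n_steps")
  n_steps <- as.integer(n_steps)
  if (n_steps * step_strain >= 1) {
    stop_invalid("total compression `n_steps * step_strain` must be < 1")
  }
  structure(
    list(
      step_strain = step_strain,
      ramp_rate = ramp_rate,
      hold_duration = hold_duration,
      n_steps = n_steps
    ),
    class = "step_protocol"
  )
}

#' @export
print.step_protocol <- function(x, ...) {
  cat("<step_protocol>\n")
  cat(sprintf("  %d step(s) of %.3g %% at %.3g %%/s, %.4g s holds\n",
              x$n_steps, 100 * x$step_strain, 100 * x$ramp_rate,
              x$hold_duration))
  invisible(x)
}

protocol_ramp_time <- function(protocol) {
  protocol$step_strain / protocol$ramp_rate
}

protocol_step_time <- function(protocol) {
  protocol_ramp_time(protocol) + protocol$hold_duration
}

#' Total duration of a step protocol
#'
#' @param protocol A [step_protocol()].
#' @return Duration in seconds (ramps plus holds).
#' @export
protocol_duration <- function(protocol) {
  protocol$n_steps * protocol_step_time(protocol)
}

#' Target axial stretch ratio imposed by a protocol
#'
#' Evaluates the prescribed stretch `lambda(t) = h(t)/H` of a step protocol:
#' piecewise-linear ramps joined by constant holds, starting from `lambda = 1`
#' at `t = 0`.
#'
#' @param protocol A [step_protocol()].
#' @param time Numeric vector of times (s).
#' @return Numeric vector of stretch ratios, same length as `time`.
#' @examples
#' protocol_stretch(step_protocol(), c(0, 3, 183, 366))
#' @export
protocol_stretch <- function(protocol, time) {
  t_ramp <- protocol_ramp_time(protocol)
  t_step <- protocol_step_time(protocol)
  step_idx <- pmin(floor(time / t_step), protocol$n_steps - 1)
  step_idx <- pmax(step_idx, 0)
  t_in <- time - step_idx * t_step
  within <- pmin(pmax(t_in, 0), t_ramp) * protocol$ramp_rate
  lam <- 1 - step_idx * protocol$step_strain - within
  lam[time <= 0] <- 1
  lam[time >= protocol$n_steps * t_step] <- 1 - protocol$n_steps * protocol$step_strain
  lam
}

# Rate of change of prescribed stretch (1/s); negative during ramps.
protocol_stretch_rate <- function(protocol, time) {
  t_ramp <- protocol_ramp_time(protocol)
  t_step <- protocol_step_time(protocol)
  t_in <- time %% t_step
  in_ramp <- time > 0 & time < protocol_duration(protocol) & t_in < t_ramp
  ifelse(in_ramp, -protocol$ramp_rate, 0)
}

#' Phase table of a step protocol
#'
#' One row per ramp/hold phase with absolute start and end times.
#'
#' @param protocol A [step_protocol()].
#' @return A tibble with columns `step`, `phase`, `t_start`, `t_end`.
#' @export
protocol_phases <- function(protocol) {
  t_ramp <- protocol_ramp_time(protocol)
  t_step <- protocol_step_time(protocol)
  steps <- seq_len(protocol$n_steps)
  tibble(
    step = rep(steps, each = 2L),
    phase = rep(c("ramp", "hold"), protocol$n_steps),
    t_start = rep((steps - 1) * t_step, each = 2L) + c(0, t_ramp),
    t_end = rep((steps - 1) * t_step, each = 2L) + c(t_ramp, t_step)
  )
}
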