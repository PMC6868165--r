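#' Generalized-Maxwell mode set
#'
#' Parameterizes a discrete stress-relaxation law
#' `sigma(t) = sigma_e + sum_i A_i exp(-t / tau_i)`, the forward model whose
#' continuous counterpart is inverted by [fit_spectrum()]. Relaxation times
#' must be strictly increasing and amplitudes positive.
#'
#' @param amplitudes Mode amplitudes A_i (Pa), positive.
#' @param taus Relaxation times tau_i (s), positive and strictly increasing.
#' @param equilibrium_stress Equilibrium stress sigma_e (Pa), >= 0.
#' @param noise_sd Standard deviation of additive Gaussian measurement noise
#'   (Pa), >= 0.
#' @return An object of class `maxwell_modes`.
#' @examples
#' maxwell_modes(c(5, 5), c(1, 100), equilibrium_stress = 0)
#' @export
maxwell_modes <- function(amplitudes, taus, equilibrium_stress = 0,
                          noise_sd = 0) {
  if (length(amplitudes) != length(taus)) {
    stop_invalid("`amplitudes` and `taus` must have equal length")
  }
  if (length(amplitudes) > 0L) {
    if (any(amplitudes <= 0)) stop_invalid("amplitudes must be positive")
    if (any(taus <= 0)) stop_invalid("relaxation times must be positive")
    if (is.unsorted(taus, strictly = TRUE)) {
      stop_invalid("relaxation times must be strictly increasing")
    }
  }
  if (equilibrium_stress < 0) stop_invalid("`equilibrium_stress` must be >= 0")
  if (noise_sd < 0) stop_invalid("`noise_sd` must be >= 0")
  structure(
    list(
      amplitudes = as.numeric(amplitudes),
      taus = as.numeric(taus),
      equilibrium_stress = equilibrium_stress,
      noise_sd = noise_sd
    ),
    class = "maxwell_modes"
  )
}

maxwell_stress <- function(modes, time) {
  s <- rep(modes$equilibrium_stress, length(time))
  for (i in seq_along(modes$amplitudes)) {
    s <- s + modes$amplitudes[i] * exp(-time / modes$taus[i])
  }
  s
}

#' Synthetic stress-relaxation decay
#'
#' Samples the multi-exponential decay defined by a [maxwell_modes()] set at
#' a fixed rate, adding i.i.d. Gaussian noise of standard deviation
#' `modes$noise_sd`. With a fixed `seed` the output is bit-identical across
#' calls.
#'
#' @param modes A [maxwell_modes()] object.
#' @param duration Trace duration (s), > 0.
#' @param rate Sampling rate (Hz), > 0. Default 100.
#' @param seed Optional integer seed for the noise.
#' @return A tibble with columns `time_s` and `stress_pa`.
#' @examples
#' m <- maxwell_modes(20, 10, equilibrium_stress = 50)
#' gen_relaxation_trace(m, duration = 60, rate = 10)
#' @export
gen_relaxation_trace <- function(modes, duration, rate = 100, seed = NULL) {
  stopifnot(inherits(modes, "maxwell_modes"))
  check_positive_scalar(duration, "duration")
  check_positive_scalar(rate, "rate")
  time <- seq(0, duration, by = 1 / rate)
  stress <- maxwell_stress(modes, time)
  if (modes$noise_sd > 0) {
    stress <- stress + with_seed(seed, rnorm(length(time), 0, modes$noise_sd))
  }
  tibble(time_s = time, stress_pa = stress)
}

#' Synthetic confined-compression experiment
#'
#' Runs the forward biphasic solver under a step protocol and converts the
#' boundary stress into the rheometer observables: gap height (thickness plus
#' coverslip) and axial force (`f = f_off + (-sigma_ZZ(0,t)) * pi D^2 / 4`).
#' Noise can be additive (`noise_sd`, N) and/or multiplicative (`noise_rel`,
#' fractional), both i.i.d. Gaussian on the force channel.
#'
#' @param params A [biphasic_params()] object.
#' @param protocol A [step_protocol()].
#' @param geometry A [gel_geometry()].
#' @param noise_sd Additive force noise SD (N). Default 0.
#' @param noise_rel Multiplicative force noise SD (fraction of the
#'   instantaneous force). Default 0.
#' @param rate Sampling rate (Hz). Default 100.
#' @param seed Optional integer seed.
#' @param n_nodes Spatial resolution passed to
#'   [solve_confined_compression()]. Default 60.
#' @return A [compression_trace()] with the generating solution attached as
#'   attribute `"solution"` and the noiseless force as attribute
#'   `"force_true"`.
#' @export
gen_biphasic_trace <- function(params, protocol, geometry = gel_geometry(),
                               noise_sd = 0, noise_rel = 0, rate = 100,
                               seed = NULL, n_nodes = 60) {
  stopifnot(inherits(params, "biphasic_params"))
  if (noise_sd < 0 || noise_rel < 0) stop_invalid("noise SDs must be >= 0")
  check_positive_scalar(rate, "rate")
  times <- seq(0, protocol_duration(protocol), by = 1 / rate)
  sol <- solve_confined_compression(params, protocol, geometry,
                                    n_nodes = n_nodes, times = times)
  area <- indenter_area(geometry)
  force_true <- geometry$force_offset - sol$sigma_zz0 * area
  force <- force_true
  if (noise_rel > 0 || noise_sd > 0) {
    force <- with_seed(seed, {
      f <- force_true
      if (noise_rel > 0) f <- f * (1 + rnorm(length(f), 0, noise_rel))
      if (noise_sd > 0) f <- f + rnorm(length(f), 0, noise_sd)
      f
    })
  }
  gap <- sol$thickness + geometry$coverslip_thickness
  out <- compression_trace(times, gap, force)
  attr(out, "solution") <- sol
  attr(out, "force_true") <- force_true
  out
}
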