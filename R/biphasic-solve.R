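#' Forward solver for nonlinear biphasic confined compression
#'
#' Solves the one-dimensional consolidation problem for a gel column of
#' unloaded thickness `H` compressed through a free-draining porous indenter
#' at `Z = 0` against an impermeable bottom at `Z = H` (material
#' coordinates). Quasi-static equilibrium makes the total axial stress
#' uniform in `Z`, `sigma_ZZ(t) = sigma_e(lambda(Z,t)) - p(Z,t)`; combining
#' Darcy's law (constant permeability applied in the material frame) with
#' fluid incompressibility yields the nonlinear diffusion equation
#' `d lambda / dt = d/dZ [ k d sigma_e(lambda) / dZ ]`.
#'
#' Boundary conditions: zero flux at the impermeable bottom, and at the
#' indenter face a flux equal to the prescribed rate of thickness change
#' (displacement control: the column must lose exactly the fluid volume the
#' ramp expels, `Q(0,t) = -h'(t)`). Free drainage (`p = 0`) at `Z = 0` then
#' recovers the pressure field as
#' `p(Z,t) = sigma_e(lambda(Z,t)) - sigma_e(lambda(0,t))` and the measurable
#' boundary stress as `sigma_ZZ(0,t) = sigma_e(lambda(0,t))`.
#'
#' The PDE is discretized by a conservative finite-volume method of lines on
#' a uniform material grid (`n_nodes` cells) and integrated with the stiff
#' LSODA solver phase by phase, restarting at every ramp/hold transition so
#' the piecewise-constant compression rate is seen exactly.
#'
#' @param params A [biphasic_params()].
#' @param protocol A [step_protocol()].
#' @param geometry A [gel_geometry()].
#' @param n_nodes Number of finite-volume cells. Default 60.
#' @param times Output times (s); default 2 Hz over the protocol.
#' @param rtol,atol Integration tolerances passed to [deSolve::ode()].
#' @return An object of class `consolidation_solution`: list with `times`,
#'   `Z` (cell-centre material coordinates, m), `lambda` (time x node
#'   matrix), `pressure` (time x node matrix, Pa), `sigma_zz0` (boundary
#'   stress sigma_ZZ(0,t), Pa), `p_bottom` (p(H,t), Pa), `thickness`
#'   (prescribed h(t), m), plus the inputs.
#' @examples
#' p <- biphasic_params(250, -200, 2000, 1e-11)
#' sol <- solve_confined_compression(p, step_protocol(n_steps = 1),
#'                                   n_nodes = 30)
#' @export
solve_confined_compression <- function(params, protocol,
                                       geometry = gel_geometry(),
                                       n_nodes = 60, times = NULL,
                                       rtol = 1e-8, atol = 1e-10) {
  stopifnot(inherits(params, "biphasic_params"),
            inherits(protocol, "step_protocol"),
            inherits(geometry, "gel_geometry"))
  check_positive_scalar(n_nodes, "n_nodes")
  n_nodes <- as.integer(n_nodes)
  H <- geometry$thickness
  dZ <- H / n_nodes
  k <- params$k
  total_t <- protocol_duration(protocol)
  if (is.null(times)) times <- seq(0, total_t, by = 0.5)
  if (any(times < 0) || any(times > total_t + 1e-9)) {
    stop_invalid("`times` must lie within the protocol duration")
  }
  times <- sort(unique(times))

  # conservative flux form: dlam_i/dt = (F_{i+1/2} - F_{i-1/2}) / dZ with
  # F = k dsigma_e/dZ at interior interfaces, F(0) = -h'(t), F(H) = 0
  rhs <- function(t, lam, parms) {
    se <- yeoh_stress(params, lam)
    Fint <- k * diff(se) / dZ
    Fall <- c(parms$flux0, Fint, 0)
    list(diff(Fall) / dZ)
  }

  phases <- protocol_phases(protocol)
  lam <- rep(1, n_nodes)
  out_t <- numeric(0)
  out_lam <- NULL
  if (any(times == 0)) {
    out_t <- 0
    out_lam <- matrix(1, 1, n_nodes)
  }
  for (ph in seq_len(nrow(phases))) {
    t0 <- phases$t_start[ph]
    t1 <- phases$t_end[ph]
    # h'(t) = H * dlambda_target/dt; negative during ramps
    hdot <- if (phases$phase[ph] == "ramp") -H * protocol$ramp_rate else 0
    tt <- times[times > t0 + 1e-12 & times <= t1 + 1e-12]
    tt_run <- unique(c(t0, tt, t1))
    sol <- deSolve::ode(
      y = lam, times = tt_run, func = rhs,
      parms = list(flux0 = -hdot),
      method = "lsoda", jactype = "bandint", bandup = 1L, banddown = 1L,
      rtol = rtol, atol = atol
    )
    if (attr(sol, "istate")[1] < 0) {
      stop_nonconvergence(sprintf(
        "consolidation solver failed in phase %d (%s of step %d); istate = %d",
        ph, phases$phase[ph], phases$step[ph], attr(sol, "istate")[1]))
    }
    lam <- as.numeric(sol[nrow(sol), -1])
    keep <- sol[, 1] %in% tt
    if (any(keep)) {
      out_t <- c(out_t, sol[keep, 1])
      out_lam <- rbind(out_lam, sol[keep, -1, drop = FALSE])
    }
  }
  dimnames(out_lam) <- NULL

  se <- matrix(yeoh_stress(params, as.numeric(out_lam)), nrow(out_lam))
  # boundary stress: extrapolate sigma_e to Z = 0 using the known boundary
  # flux, sigma_e(0) = sigma_e(lam_1) - (dZ/2) * (-h'/k)
  hdot_t <- H * protocol_stretch_rate(protocol, out_t)
  sigma0 <- se[, 1] + hdot_t * dZ / (2 * k)
  pressure <- se - sigma0
  structure(
    list(
      times = out_t,
      Z = (seq_len(n_nodes) - 0.5) * dZ,
      lambda = out_lam,
      pressure = pressure,
      sigma_zz0 = sigma0,
      p_bottom = pressure[, n_nodes],
      thickness = H * protocol_stretch(protocol, out_t),
      params = params, protocol = protocol, geometry = geometry,
      n_nodes = n_nodes
    ),
    class = "consolidation_solution"
  )
}

#' @export
print.consolidation_solution <- function(x, ...) {
  cat("<consolidation_solution>\n")
  cat(sprintf("  %d output times over [0, %.4g] s, %d nodes\n",
              length(x$times), max(x$times), x$n_nodes))
  cat(sprintf("  final boundary stress %.4g Pa, final p(H) %.4g Pa\n",
              x$sigma_zz0[length(x$times)], x$p_bottom[length(x$times)]))
  invisible(x)
}

#' Interstitial pressure at the chamber bottom
#'
#' Extracts `p(H, t)` from a consolidation solution together with its peak
#' and the time at which it decays to half the peak.
#'
#' @param solution A `consolidation_solution`.
#' @return A tibble with columns `time_s`, `p_pa`, plus attributes
#'   `peak` (Pa), `t_peak` (s) and `t_half` (first time after the peak at
#'   which the pressure falls below half of it; NA if never).
#' @export
pressure_at_bottom <- function(solution) {
  stopifnot(inherits(solution, "consolidation_solution"))
  p <- solution$p_bottom
  tt <- solution$times
  ipk <- which.max(p)
  after <- which(tt > tt[ipk] & p < p[ipk] / 2)
  out <- tibble(time_s = tt, p_pa = p)
  attr(out, "peak") <- p[ipk]
  attr(out, "t_peak") <- tt[ipk]
  attr(out, "t_half") <- if (length(after)) tt[after[1]] else NA_real_
  out
}

#' @export
autoplot.consolidation_solution <- function(object, ...) {
  df <- bind_rows(
    tibble(time_s = object$times, value = -object$sigma_zz0,
           quantity = "boundary stress -sigma_ZZ(0,t) (Pa)"),
    tibble(time_s = object$times, value = object$p_bottom,
           quantity = "bottom pressure p(H,t) (Pa)")
  )
  ggplot(df, aes(x = .data$time_s, y = .data$value)) +
    geom_line() +
    facet_wrap(~quantity, ncol = 1, scales = "free_y") +
    labs(x = "time (s)", y = NULL)
}
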