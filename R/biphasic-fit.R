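#' Fit hydraulic permeability to the transient response
#'
#' With the Yeoh coefficients fixed (from [fit_equilibrium()]), the
#' permeability `k` is estimated by nonlinear least squares on the pooled
#' transient data from all compression steps: the objective is
#' `sum_i [sigma_ZZ(0, t_i) - sigma_exp(t_i)]^2` over every retained sample,
#' weighting all steps equally. `k` is searched in log10 space: a fixed
#' coarse grid over `log10_k_range` brackets the minimum, which is then
#' refined by golden-section search. The procedure is fully deterministic.
#'
#' @param trace A [compression_trace()].
#' @param material A list with Yeoh coefficients `c1`, `c2`, `c3` (e.g. a
#'   `yeoh_fit` or [biphasic_params()]).
#' @param geometry A [gel_geometry()].
#' @param protocol A [step_protocol()].
#' @param log10_k_range Search interval for log10(k). Default `c(-14, -8)`.
#' @param n_grid Coarse bracketing grid size. Default 7.
#' @param max_points Maximum number of trace samples entering the objective
#'   (uniform thinning; keeps equal weighting across steps). Default 1500.
#' @param n_nodes Spatial resolution of the forward solver. Default 40.
#' @return An object of class `permeability_fit`: list with `k`, `log10_k`,
#'   `objective` (sum of squares, Pa^2), `residual_rms`, `n_points`,
#'   `at_bound` (TRUE when the optimum sits on the search boundary;
#'   flagged with a warning) and `sensitivity` (relative objective change
#'   under k x/÷ 2).
#' @export
fit_transient <- function(trace, material, geometry = gel_geometry(),
                          protocol = step_protocol(),
                          log10_k_range = c(-14, -8), n_grid = 7,
                          max_points = 1500, n_nodes = 40) {
  stopifnot(inherits(trace, "compression_trace"))
  cc <- material[c("c1", "c2", "c3")]
  if (any(vapply(cc, is.null, TRUE))) {
    stop_invalid("`material` must carry Yeoh coefficients c1, c2, c3")
  }
  tt <- trace$time_s
  sigma_exp <- -cauchy_stress(trace$force_N, geometry)  # signed stress
  keep <- tt <= protocol_duration(protocol)
  tt <- tt[keep]; sigma_exp <- sigma_exp[keep]
  if (length(tt) > max_points) {
    idx <- unique(round(seq(1, length(tt), length.out = max_points)))
    tt <- tt[idx]; sigma_exp <- sigma_exp[idx]
  }

  objective <- function(l10k) {
    par <- biphasic_params(cc$c1, cc$c2, cc$c3, 10^l10k)
    sol <- solve_confined_compression(par, protocol, geometry,
                                      n_nodes = n_nodes, times = tt,
                                      rtol = 1e-7, atol = 1e-9)
    sum((sol$sigma_zz0 - sigma_exp)^2)
  }

  grid <- seq(log10_k_range[1], log10_k_range[2], length.out = n_grid)
  vals <- vapply(grid, objective, numeric(1))
  if (!any(is.finite(vals))) stop_nonconvergence("objective not finite anywhere on the search grid")
  ibest <- which.min(vals)
  # flat objective: either the data/model signal is vanishingly small, or
  # the variation across the whole k grid is negligible against the
  # objective and the data's total energy
  flat_scale <- max(max(abs(vals)), sum(sigma_exp^2), 1)
  if (max(vals) < 1e-6 || max(vals) - min(vals) < 1e-8 * flat_scale) {
    stop_nonconvergence(
      "objective is flat in k over the search range; the trace carries no transient information")
  }
  lo <- grid[max(1L, ibest - 1L)]
  hi <- grid[min(n_grid, ibest + 1L)]
  opt <- optimize(objective, c(lo, hi), tol = 5e-4)
  l10k <- opt$minimum
  at_bound <- min(abs(l10k - log10_k_range)) < 0.05
  if (at_bound) warn("fitted permeability sits at the search bound")
  obj <- opt$objective
  sens <- c(down = objective(l10k - log10(2)), up = objective(l10k + log10(2)))
  structure(
    list(
      k = 10^l10k, log10_k = l10k, objective = obj,
      residual_rms = sqrt(obj / length(tt)),
      n_points = length(tt), at_bound = at_bound,
      sensitivity = sens / obj - 1
    ),
    class = "permeability_fit"
  )
}

#' @export
print.permeability_fit <- function(x, ...) {
  cat("<permeability_fit>\n")
  cat(sprintf("  k = %.4g m^4/(N s)  (residual RMS %.3g Pa over %d points)%s\n",
              x$k, x$residual_rms, x$n_points,
              if (x$at_bound) " [at search bound]" else ""))
  invisible(x)
}

#' @export
tidy.permeability_fit <- function(x, ...) {
  tibble(term = "k", estimate = x$k)
}

#' @export
glance.permeability_fit <- function(x, ...) {
  tibble(residual_rms = x$residual_rms, n = x$n_points,
         at_bound = x$at_bound)
}

#' Two-step biphasic parameter estimation
#'
#' The canonical fitting pipeline for a multi-step confined-compression
#' experiment: (1) segment the trace and extract relaxed equilibrium
#' stress-stretch points, fit the Yeoh coefficients to them
#' ([fit_equilibrium()]); (2) with the material fixed, fit the hydraulic
#' permeability to the pooled transient response ([fit_transient()]). Both
#' stages are deterministic, so repeated runs on the same input give
#' identical output.
#'
#' @inheritParams fit_transient
#' @param ... Passed on to [fit_transient()].
#' @return An object of class `biphasic_fit`: list with `params`
#'   ([biphasic_params()]), `equilibrium` (`yeoh_fit`), `transient`
#'   (`permeability_fit`) and `points` (the equilibrium table).
#' @examples
#' \donttest{
#' truth <- biphasic_params(250, -200, 2000, 1e-11)
#' prot <- step_protocol(n_steps = 3, hold_duration = 90)
#' tr <- gen_biphasic_trace(truth, prot, rate = 10)
#' fit <- two_step_fit(tr, protocol = prot)
#' tidy(fit)
#' }
#' @export
two_step_fit <- function(trace, geometry = gel_geometry(),
                         protocol = step_protocol(), ...) {
  pts <- equilibrium_points(trace, protocol, geometry)
  eq <- fit_equilibrium(pts)
  tr <- fit_transient(trace, eq, geometry, protocol, ...)
  c2 <- if (eq$c2 < 0) eq$c2 else -1e-12  # constraint boundary: keep admissible
  c1 <- max(eq$c1, 1e-12)
  c3 <- max(eq$c3, 1e-12)
  structure(
    list(
      params = biphasic_params(c1, c2, c3, tr$k),
      equilibrium = eq,
      transient = tr,
      points = pts
    ),
    class = "biphasic_fit"
  )
}

#' @export
print.biphasic_fit <- function(x, ...) {
  cat("<biphasic_fit> two-step estimate\n")
  print(x$params)
  cat(sprintf("  equilibrium residual RMS: %.3g Pa; transient residual RMS: %.3g Pa\n",
              x$equilibrium$residual_rms, x$transient$residual_rms))
  invisible(x)
}

#' @export
tidy.biphasic_fit <- function(x, ...) {
  tibble(
    term = c("c1", "c2", "c3", "k"),
    estimate = c(x$params$c1, x$params$c2, x$params$c3, x$params$k),
    stage = c(rep("equilibrium", 3), "transient")
  )
}

#' @export
glance.biphasic_fit <- function(x, ...) {
  tibble(
    equilibrium_rms = x$equilibrium$residual_rms,
    transient_rms = x$transient$residual_rms,
    n_equilibrium = nrow(x$points),
    n_transient = x$transient$n_points,
    flagged = x$equilibrium$flagged || x$transient$at_bound
  )
}

#' @export
autoplot.biphasic_fit <- function(object, ...) {
  autoplot(object$equilibrium, ...)
}
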