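#' Biphasic material parameters
#'
#' The solid matrix follows a Yeoh strain-energy function
#' `W = c1 (I - 3) + c2 (I - 3)^2 + c3 (I - 3)^3` with the admissibility
#' constraints `c1 > 0`, `c3 > 0`, `c2 < 0`; the interstitial fluid obeys
#' Darcy's law with a constant isotropic hydraulic permeability `k`.
#'
#' @param c1,c2,c3 Yeoh coefficients (Pa); `c1 > 0`, `c2 < 0`, `c3 > 0`.
#' @param k Hydraulic permeability (m^4 N^-1 s^-1), > 0.
#' @return An object of class `biphasic_params`.
#' @examples
#' biphasic_params(c1 = 250, c2 = -200, c3 = 2000, k = 5e-12)
#' @export
biphasic_params <- function(c1, c2, c3, k) {
  check_positive_scalar(c1, "c1")
  check_positive_scalar(c3, "c3")
  check_positive_scalar(k, "k")
  if (!is.numeric(c2) || length(c2) != 1L || !is.finite(c2) || c2 >= 0) {
    stop_invalid("`c2` must be a single negative number")
  }
  structure(list(c1 = c1, c2 = c2, c3 = c3, k = k),
            class = "biphasic_params")
}

#' @export
print.biphasic_params <- function(x, ...) {
  cat("<biphasic_params>\n")
  cat(sprintf("  Yeoh: c1 = %.4g Pa, c2 = %.4g Pa, c3 = %.4g Pa\n",
              x$c1, x$c2, x$c3))
  cat(sprintf("  permeability k = %.4g m^4/(N s)\n", x$k))
  invisible(x)
}

# In confined (laterally constrained) uniaxial kinematics the deformation
# gradient is diag(1, 1, lambda), so I = tr C = lambda^2 + 2.
confined_invariant <- function(lambda) lambda^2 + 2

yeoh_wprime <- function(params, lambda) {
  x <- confined_invariant(lambda) - 3
  params$c1 + 2 * params$c2 * x + 3 * params$c3 * x^2
}

#' Yeoh strain-energy density in confined compression
#'
#' Evaluates `W(I)` at the confined-compression invariant `I = lambda^2 + 2`.
#' The stored compressive energy reported alongside equilibrium fits is
#' `-W`, which is positive for admissible parameters under compression.
#'
#' @param params A [biphasic_params()] (the permeability is ignored) or any
#'   list with elements `c1`, `c2`, `c3`.
#' @param lambda Axial stretch ratio, vectorized; > 0.
#' @return Energy density W (Pa).
#' @examples
#' p <- biphasic_params(1000, -200, 500, 1e-12)
#' yeoh_energy(p, 0.9)   # -200.65 Pa, so -W = 200.65 Pa
#' @export
yeoh_energy <- function(params, lambda) {
  if (any(lambda <= 0)) stop_invalid("`lambda` must be positive")
  x <- confined_invariant(lambda) - 3
  params$c1 * x + params$c2 * x^2 + params$c3 * x^3
}

#' Effective axial solid stress of the Yeoh matrix
#'
#' The axial Cauchy stress carried by the solid skeleton in confined
#' uniaxial kinematics, `sigma_e(lambda) = (2 / lambda) W'(I) (lambda^2 - 1)`
#' with `W'(I) = c1 + 2 c2 (I - 3) + 3 c3 (I - 3)^2`. It vanishes in the
#' reference state and is negative (compressive) for `lambda < 1`; its
#' small-strain slope at `lambda = 1` is `4 c1`, the aggregate modulus of
#' the linearized model.
#'
#' @inheritParams yeoh_energy
#' @return Signed axial stress (Pa).
#' @examples
#' p <- biphasic_params(1000, -200, 500, 1e-12)
#' yeoh_stress(p, 0.9)   # ~ -477.2 Pa
#' @export
yeoh_stress <- function(params, lambda) {
  if (any(lambda <= 0)) stop_invalid("`lambda` must be positive")
  (2 / lambda) * yeoh_wprime(params, lambda) * (lambda^2 - 1)
}

#' Strain-dependent shear modulus
#'
#' `mu(lambda) = 2 W'(I)`; at the reference state `mu(1) = 2 c1`. With
#' `c2 < 0` the modulus initially rises as the gel is compressed, the
#' nonlinear stiffening signature of the Yeoh law.
#'
#' @inheritParams yeoh_energy
#' @return Shear modulus (Pa).
#' @export
shear_modulus <- function(params, lambda) {
  if (any(lambda <= 0)) stop_invalid("`lambda` must be positive")
  2 * yeoh_wprime(params, lambda)
}

# d sigma_e / d lambda, needed by the consolidation solver (tangent
# aggregate modulus). Analytic, exact.
yeoh_stress_dlambda <- function(params, lambda) {
  x <- lambda^2 - 1
  wp <- yeoh_wprime(params, lambda)
  wpp <- 2 * params$c2 + 6 * params$c3 * x
  (-2 / lambda^2) * wp * x + (2 / lambda) * (wpp * 2 * lambda) * x +
    (2 / lambda) * wp * 2 * lambda
}

#' Fit Yeoh coefficients to equilibrium stress-stretch data
#'
#' Least-squares fit of `sigma_e(lambda)` to relaxed (drained) equilibrium
#' points under the sign constraints `c1 > 0`, `c2 < 0`, `c3 > 0`. Because
#' the stress is linear in the coefficients, the constrained problem is
#' solved exactly (and deterministically) by non-negative least squares
#' after absorbing the signs into the design matrix. Coefficients pinned at
#' zero by the constraints are flagged.
#'
#' @param points A data frame with columns `lambda` and `sigma` (signed
#'   Cauchy stress, Pa), e.g. from [equilibrium_points()]. At least 3 points.
#' @return An object of class `yeoh_fit` with elements `c1`, `c2`, `c3`,
#'   `fitted`, `residuals`, `residual_rms`, `flagged` (TRUE when a
#'   constraint is active) and `points`.
#' @examples
#' p <- biphasic_params(1000, -200, 500, 1e-12)
#' lam <- seq(0.97, 0.82, by = -0.03)
#' fit <- fit_equilibrium(tibble::tibble(lambda = lam,
#'                                       sigma = yeoh_stress(p, lam)))
#' tidy(fit)
#' @export
fit_equilibrium <- function(points) {
  if (!is.data.frame(points) || !all(c("lambda", "sigma") %in% names(points))) {
    stop_invalid("`points` must have columns `lambda` and `sigma`")
  }
  if (nrow(points) < 3L) {
    stop_invalid("at least 3 equilibrium points are required to fit 3 coefficients")
  }
  lam <- points$lambda
  if (any(lam <= 0)) stop_invalid("stretches must be positive")
  x <- lam^2 - 1
  # sigma_e = (2x/lam) c1 + (4x^2/lam) c2 + (6x^3/lam) c3, linear in c
  basis <- cbind(2 * x / lam, 4 * x^2 / lam, 6 * x^3 / lam)
  # impose c1 >= 0, -c2 >= 0, c3 >= 0 by flipping the sign of column 2
  A <- basis %*% diag(c(1, -1, 1))
  sol <- pracma::lsqnonneg(A, points$sigma)
  cc <- c(sol$x[1], -sol$x[2], sol$x[3])
  fitted <- as.numeric(basis %*% cc)
  resid <- points$sigma - fitted
  flagged <- any(sol$x <= 0)
  if (flagged) {
    warn("one or more Yeoh coefficients pinned at the constraint boundary")
  }
  structure(
    list(
      c1 = cc[1], c2 = cc[2], c3 = cc[3],
      fitted = fitted, residuals = resid,
      residual_rms = sqrt(mean(resid^2)),
      flagged = flagged,
      points = as_tibble(points)
    ),
    class = "yeoh_fit"
  )
}

#' @export
print.yeoh_fit <- function(x, ...) {
  cat("<yeoh_fit>\n")
  cat(sprintf("  c1 = %.4g Pa, c2 = %.4g Pa, c3 = %.4g Pa\n", x$c1, x$c2, x$c3))
  cat(sprintf("  residual RMS = %.3g Pa over %d points%s\n",
              x$residual_rms, nrow(x$points),
              if (x$flagged) " [constraint active]" else ""))
  invisible(x)
}

#' @export
tidy.yeoh_fit <- function(x, ...) {
  tibble(term = c("c1", "c2", "c3"), estimate = c(x$c1, x$c2, x$c3))
}

#' @export
glance.yeoh_fit <- function(x, ...) {
  tibble(residual_rms = x$residual_rms, n = nrow(x$points),
         flagged = x$flagged)
}

#' @export
autoplot.yeoh_fit <- function(object, ...) {
  lam_grid <- seq(min(object$points$lambda), 1, length.out = 100)
  pars <- list(c1 = object$c1, c2 = object$c2, c3 = object$c3)
  curve <- tibble(strain = 1 - lam_grid,
                  stress = -yeoh_stress(pars, lam_grid))
  ggplot(object$points, aes(x = 1 - .data$lambda, y = -.data$sigma)) +
    geom_point() +
    geom_line(data = curve, aes(x = .data$strain, y = .data$stress)) +
    labs(x = expression(1 - lambda), y = expression(-sigma ~ "(Pa)"))
}
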