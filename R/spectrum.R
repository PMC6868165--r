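#' Invert a stress decay into a continuous relaxation-time spectrum
#'
#' Fits the generalized-Maxwell representation
#' `sigma(t) = sigma_e + integral H(tau) exp(-t/tau) dln(tau)` to a measured
#' decay. The spectrum `H(tau)` is discretized on a log-spaced grid
#' (`grid_points_per_decade` nodes per decade over `tau_range`) and the
#' integral approximated by trapezoidal quadrature in `ln tau`. The inverse
#' problem is ill-posed, so the fit minimizes
#' `||sigma - model||^2 + w ||D2 H||^2` subject to `H >= 0` and
#' `sigma_e >= 0`, where `D2` is the second difference of `H` over `ln tau`
#' (curvature penalty). The constrained problem is solved by non-negative
#' least squares on the stacked system. When `reg_weight` is `NULL` the
#' weight is chosen automatically at the corner of the L-curve (maximum
#' curvature of log residual norm vs log seminorm).
#'
#' Long traces are thinned to at most `n_subsample` log-spaced time points
#' before fitting; the decay carries information per decade of time, not per
#' sample, so this loses essentially nothing while keeping the design matrix
#' small.
#'
#' @param decay A data frame with columns `time_s` and `stress_pa` (time
#'   re-zeroed at the start of the decay), e.g. from
#'   [gen_relaxation_trace()]. At least 50 samples spanning at least one
#'   decade of time.
#' @param tau_range Range of relaxation times (s). Default `c(1e-2, 1e4)`.
#' @param grid_points_per_decade Grid resolution. Default 10 (61 nodes over
#'   the default range).
#' @param reg_weight Curvature penalty weight, or `NULL` (default) for
#'   L-curve selection.
#' @param n_subsample Maximum number of time points used in the fit.
#'   Default 300.
#' @return An object of class `relaxation_spectrum`: a list with elements
#'   `spectrum` (tibble `tau_s`, `H_pa`), `sigma_e`, `reg_weight`,
#'   `residual_rms`, `area`, `flagged` (TRUE when the trace contains no
#'   measurable decay and the zero spectrum is returned) and `n_used`.
#' @examples
#' m <- maxwell_modes(20, 10, equilibrium_stress = 50)
#' d <- gen_relaxation_trace(m, duration = 180, rate = 10)
#' fit <- fit_spectrum(d)
#' glance(fit)
#' @export
fit_spectrum <- function(decay, tau_range = c(1e-2, 1e4),
                         grid_points_per_decade = 10, reg_weight = NULL,
                         n_subsample = 300) {
  if (!is.data.frame(decay) || !all(c("time_s", "stress_pa") %in% names(decay))) {
    stop_invalid("`decay` must have columns `time_s` and `stress_pa`")
  }
  tt <- decay$time_s - min(decay$time_s)
  ss <- decay$stress_pa
  if (length(tt) < 50L) stop_invalid("decay must contain at least 50 samples")
  pos <- tt[tt > 0]
  if (length(pos) < 2L || max(pos) / min(pos) < 10) {
    stop_invalid("decay must span at least one decade of time")
  }
  # log-spaced thinning (always keep t = 0 and the final sample)
  if (length(tt) > n_subsample) {
    targets <- exp(seq(log(min(pos)), log(max(tt)), length.out = n_subsample - 1L))
    idx <- unique(c(1L, vapply(targets, function(x) which.min(abs(tt - x)), 1L)))
    tt <- tt[idx]; ss <- ss[idx]
  }
  m <- length(tt)

  grid <- spectrum_tau_grid(tau_range, grid_points_per_decade)
  tau <- grid$tau
  wq <- grid$weights
  nk <- length(tau)
  K <- exp(-outer(tt, tau, "/")) * rep(wq, each = m)
  A <- cbind(K, 1)          # last column: sigma_e >= 0

  # degenerate input: no measurable decay -> zero spectrum, flagged
  if (sd(ss) < 1e-12 * max(abs(ss), 1) || all(ss == ss[1])) {
    return(new_relaxation_spectrum(tau, rep(0, nk), mean(ss),
                                   reg_weight = 0, residual_rms = 0,
                                   flagged = TRUE, n_used = m))
  }

  D2 <- second_difference_matrix(nk)
  L <- cbind(D2, 0)          # the penalty does not act on sigma_e
  scale_w <- sum(K^2) / max(sum(D2^2), 1)  # dimensionless weight scale

  solve_one <- function(w) {
    Aaug <- rbind(A, sqrt(w * scale_w) * L)
    b <- c(ss, rep(0, nrow(L)))
    x <- pracma::lsqnonneg(Aaug, b)$x
    resid <- ss - as.numeric(A %*% x)
    list(x = x, rho = sqrt(sum(resid^2)),
         eta = sqrt(sum((D2 %*% x[seq_len(nk)])^2)))
  }

  if (is.null(reg_weight)) {
    ws <- 10^seq(-7, 1, length.out = 17)
    fits <- lapply(ws, solve_one)
    pick <- lcurve_corner(log10(pmax(vapply(fits, `[[`, 0, "rho"), 1e-300)),
                          log10(pmax(vapply(fits, `[[`, 0, "eta"), 1e-300)))
    reg_weight <- ws[pick]
    fit <- fits[[pick]]
  } else {
    if (reg_weight < 0) stop_invalid("`reg_weight` must be >= 0")
    fit <- solve_one(reg_weight)
  }

  H <- fit$x[seq_len(nk)]
  sigma_e <- fit$x[nk + 1L]
  new_relaxation_spectrum(tau, H, sigma_e, reg_weight = reg_weight,
                          residual_rms = fit$rho / sqrt(m),
                          flagged = FALSE, n_used = m)
}

spectrum_tau_grid <- function(tau_range, points_per_decade) {
  if (length(tau_range) != 2L || any(tau_range <= 0) ||
      tau_range[2] <= tau_range[1]) {
    stop_invalid("`tau_range` must be an increasing positive pair")
  }
  lt <- seq(log10(tau_range[1]), log10(tau_range[2]),
            by = 1 / points_per_decade)
  tau <- 10^lt
  dln <- log(10) / points_per_decade
  w <- rep(dln, length(tau))
  w[c(1, length(tau))] <- dln / 2     # trapezoid end weights
  list(tau = tau, weights = w)
}

second_difference_matrix <- function(n) {
  if (n < 3L) return(matrix(0, 0, n))
  D <- matrix(0, n - 2L, n)
  for (i in seq_len(n - 2L)) D[i, i:(i + 2L)] <- c(1, -2, 1)
  D
}

# Discrete L-curve corner: point of maximum Menger curvature of the
# (log rho, log eta) polyline, restricted to interior points.
lcurve_corner <- function(lrho, leta) {
  n <- length(lrho)
  if (n < 3L) return(ceiling(n / 2))
  curv <- rep(-Inf, n)
  for (i in 2:(n - 1L)) {
    a <- c(lrho[i - 1], leta[i - 1])
    b <- c(lrho[i], leta[i])
    c_ <- c(lrho[i + 1], leta[i + 1])
    ab <- sqrt(sum((b - a)^2)); bc <- sqrt(sum((c_ - b)^2))
    ca <- sqrt(sum((a - c_)^2))
    if (ab * bc * ca == 0) next
    cross <- (b[1] - a[1]) * (c_[2] - a[2]) - (b[2] - a[2]) * (c_[1] - a[1])
    curv[i] <- 2 * cross / (ab * bc * ca)   # signed: convex corners positive
  }
  if (all(!is.finite(curv)) || max(curv) <= 0) return(ceiling(n / 2))
  which.max(curv)
}

new_relaxation_spectrum <- function(tau, H, sigma_e, reg_weight,
                                    residual_rms, flagged, n_used) {
  obj <- structure(
    list(
      spectrum = tibble(tau_s = tau, H_pa = H),
      sigma_e = sigma_e,
      reg_weight = reg_weight,
      residual_rms = residual_rms,
      flagged = flagged,
      n_used = n_used
    ),
    class = "relaxation_spectrum"
  )
  obj$area <- spectrum_area(obj)
  obj
}

#' @export
print.relaxation_spectrum <- function(x, ...) {
  cat("<relaxation_spectrum>\n")
  cat(sprintf("  grid: %d nodes over [%.3g, %.3g] s\n",
              nrow(x$spectrum), min(x$spectrum$tau_s), max(x$spectrum$tau_s)))
  cat(sprintf("  sigma_e = %.4g Pa, area = %.4g Pa, peaks = %d\n",
              x$sigma_e, x$area, count_peaks(x)))
  cat(sprintf("  residual RMS = %.3g Pa, reg_weight = %.3g%s\n",
              x$residual_rms, x$reg_weight,
              if (x$flagged) " [flagged: no decay]" else ""))
  invisible(x)
}

#' Count peaks in a relaxation spectrum
#'
#' Local maxima of `H(tau)` whose topographic prominence is at least
#' `prominence_floor` times the spectrum maximum.
#'
#' @param spectrum A `relaxation_spectrum` object (or a tibble with columns
#'   `tau_s`, `H_pa`).
#' @param prominence_floor Fraction of `max(H)` a local maximum must rise
#'   above its surroundings to count. Default 0.05.
#' @return Integer peak count.
#' @export
count_peaks <- function(spectrum, prominence_floor = 0.05) {
  H <- spectrum_values(spectrum)$H_pa
  if (max(H) <= 0) return(0L)
  pk <- peak_prominences(H)
  sum(pk$prominence >= prominence_floor * max(H))
}

#' Area under a relaxation spectrum
#'
#' Trapezoidal integral of `H(tau)` over `ln tau`; for well-separated modes
#' this recovers the total decaying stress amplitude and serves as a proxy
#' for the energy dissipated during the step.
#'
#' @inheritParams count_peaks
#' @return Area (Pa).
#' @export
spectrum_area <- function(spectrum) {
  sp <- spectrum_values(spectrum)
  if (nrow(sp) < 2L) return(0)
  pracma::trapz(log(sp$tau_s), sp$H_pa)
}

spectrum_values <- function(spectrum) {
  if (inherits(spectrum, "relaxation_spectrum")) return(spectrum$spectrum)
  if (is.data.frame(spectrum) && all(c("tau_s", "H_pa") %in% names(spectrum))) {
    return(as_tibble(spectrum))
  }
  stop_invalid("`spectrum` must be a relaxation_spectrum or a tau_s/H_pa table")
}

# Local maxima with topographic prominence. For each local maximum, walk
# left and right to the nearest higher value; the prominence is the peak
# height minus the higher of the two intervening minima.
peak_prominences <- function(y) {
  n <- length(y)
  if (n < 3L) return(tibble(index = integer(), prominence = numeric()))
  is_max <- which(vapply(2:(n - 1L), function(i) {
    y[i] > y[i - 1L] && y[i] >= y[i + 1L]
  }, logical(1))) + 1L
  prom <- vapply(is_max, function(i) {
    left_min <- min(y[1:i])
    j <- i
    while (j > 1L && y[j - 1L] <= y[i]) j <- j - 1L
    if (j > 1L) left_min <- min(y[j:i])
    right_min <- min(y[i:n])
    j <- i
    while (j < n && y[j + 1L] <= y[i]) j <- j + 1L
    if (j < n) right_min <- min(y[i:j])
    y[i] - max(left_min, right_min)
  }, numeric(1))
  tibble(index = is_max, prominence = prom)
}

#' Fit one spectrum per compression step
#'
#' Segments a multi-step trace into holds, converts each hold's force decay
#' to compressive Cauchy stress, re-zeroes time at the hold start and runs
#' [fit_spectrum()] on it. A warning is issued when a hold is shorter than
#' ten times the smallest grid relaxation time (the first tau decade is then
#' unconstrained by the data).
#'
#' @inheritParams segment_steps
#' @param ... Passed on to [fit_spectrum()].
#' @return A tibble with one row per step: `step`, `strain` (nominal step
#'   strain total), `sigma_e`, `area`, `n_peaks`, `residual_rms`, and the
#'   full fit in the list-column `spectrum`.
#' @export
per_step_spectra <- function(trace, protocol, geometry = gel_geometry(), ...) {
  seg <- segment_steps(trace, protocol, geometry)
  holds <- seg[seg$phase == "hold", ]
  if (nrow(holds) == 0L) stop_degenerate("no hold phases detected")
  rows <- purrr::pmap(holds, function(step, phase, i_start, i_end,
                                      t_start, t_end, ...) {
    if ((t_end - t_start) < 10 * 1e-2) {
      warn(sprintf("hold %d is shorter than the smallest tau decade", step))
    }
    idx <- i_start:i_end
    decay <- tibble(
      time_s = trace$time_s[idx] - trace$time_s[idx[1]],
      stress_pa = cauchy_stress(trace$force_N[idx], geometry)
    )
    fit <- fit_spectrum(decay, ...)
    tibble(
      step = step,
      strain = step * protocol$step_strain,
      sigma_e = fit$sigma_e,
      area = fit$area,
      n_peaks = count_peaks(fit),
      residual_rms = fit$residual_rms,
      spectrum = list(fit)
    )
  }, ... = ...)
  bind_rows(rows)
}

#' @export
tidy.relaxation_spectrum <- function(x, ...) {
  x$spectrum
}

#' @export
glance.relaxation_spectrum <- function(x, ...) {
  tibble(
    sigma_e = x$sigma_e,
    area = x$area,
    n_peaks = count_peaks(x),
    residual_rms = x$residual_rms,
    reg_weight = x$reg_weight,
    flagged = x$flagged,
    n_used = x$n_used
  )
}

#' @export
autoplot.relaxation_spectrum <- function(object, ...) {
  ggplot(object$spectrum, aes(x = .data$tau_s, y = .data$H_pa)) +
    geom_line() +
    scale_x_log10() +
    labs(x = expression(tau ~ "(s)"), y = expression(H(tau) ~ "(Pa)"))
}
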