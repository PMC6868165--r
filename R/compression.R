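#' Build a confined-compression trace
#'
#' Bundles the three synchronously sampled rheometer channels (time, gap
#' height, axial force) into a validated tibble of class `compression_trace`.
#' Time must be strictly increasing once duplicate timestamps are dropped
#' (duplicates raise a warning); gaps must be positive.
#'
#' @param time Time stamps (s), nominally sampled at 100 Hz.
#' @param gap Rheometer gap height (m), including the coverslip.
#' @param force Axial force (N).
#' @return A tibble with columns `time_s`, `gap_m`, `force_N` and class
#'   `compression_trace`.
#' @examples
#' compression_trace(0:3 / 100, rep(3.17e-3, 4), c(0, 1e-3, 2e-3, 2e-3))
#' @export
compression_trace <- function(time, gap, force) {
  if (length(time) != length(gap) || length(time) != length(force)) {
    stop_invalid("`time`, `gap` and `force` must have equal length")
  }
  if (length(time) == 0L) stop_invalid("trace must contain at least one sample")
  if (any(!is.finite(time)) || any(!is.finite(gap)) || any(!is.finite(force))) {
    stop_invalid("trace channels must be finite")
  }
  dup <- duplicated(time)
  if (any(dup)) {
    warn(sprintf("dropping %d duplicate timestamp(s)", sum(dup)))
    time <- time[!dup]; gap <- gap[!dup]; force <- force[!dup]
  }
  if (is.unsorted(time, strictly = TRUE)) {
    stop_invalid("`time` must be strictly increasing")
  }
  if (any(gap <= 0)) stop_invalid("`gap` must be positive")
  out <- tibble(time_s = as.numeric(time), gap_m = as.numeric(gap),
                force_N = as.numeric(force))
  class(out) <- c("compression_trace", class(out))
  out
}

#' Read / write a compression trace as delimited text
#'
#' The on-disk dialect is a comma-separated file with header columns
#' `time_s,gap_m,force_N` in SI units.
#'
#' @param path File path.
#' @return `read_compression_trace()` returns a `compression_trace`;
#'   `write_compression_trace()` returns `path` invisibly.
#' @export
read_compression_trace <- function(path) {
  df <- utils::read.csv(path)
  need <- c("time_s", "gap_m", "force_N")
  if (!all(need %in% names(df))) {
    stop_invalid(sprintf("trace file must contain columns %s",
                         paste(need, collapse = ", ")))
  }
  compression_trace(df$time_s, df$gap_m, df$force_N)
}

#' @param trace A `compression_trace`.
#' @rdname read_compression_trace
#' @export
write_compression_trace <- function(trace, path) {
  utils::write.csv(as.data.frame(trace)[c("time_s", "gap_m", "force_N")],
                   path, row.names = FALSE)
  invisible(path)
}

#' Compressive Cauchy stress from axial force
#'
#' Converts measured axial force to the compressive Cauchy stress
#' `-sigma = (f - f_off) / (pi D^2 / 4)`. Following the convention that the
#' Cauchy stress is positive under tension, the value returned here is
#' `-sigma`, i.e. positive while the gel is compressed.
#'
#' @param force Axial force (N), vectorized.
#' @param geometry A [gel_geometry()].
#' @return Compressive stress `-sigma` (Pa).
#' @examples
#' cauchy_stress(5.0265e-2, gel_geometry())  # ~1000 Pa for D = 8 mm
#' @export
cauchy_stress <- function(force, geometry) {
  stopifnot(inherits(geometry, "gel_geometry"))
  (force - geometry$force_offset) / indenter_area(geometry)
}

#' Axial stretch ratio from rheometer gap
#'
#' The deformed gel thickness is `h = gap - coverslip_thickness`; the stretch
#' ratio is `lambda = h / H` with `H` the unloaded thickness.
#'
#' @param gap Gap height (m), vectorized.
#' @inheritParams cauchy_stress
#' @return Stretch ratio `lambda` (dimensionless).
#' @examples
#' g <- gel_geometry()
#' stretch_from_gap(g$coverslip_thickness + 2.55e-3, g)  # 0.85
#' @export
stretch_from_gap <- function(gap, geometry) {
  stopifnot(inherits(geometry, "gel_geometry"))
  if (any(gap <= geometry$coverslip_thickness)) {
    stop_invalid("`gap` must exceed the coverslip thickness")
  }
  (gap - geometry$coverslip_thickness) / geometry$thickness
}

#' Segment a trace into ramp and hold phases
#'
#' Change-point segmentation of the gap signal. The gap velocity is estimated
#' by a centred first difference smoothed over a 1 s window; samples whose
#' speed is below 1 % of the protocol ramp speed are classified as holding,
#' samples moving downwards at a substantial fraction of the ramp speed as
#' ramping. Consecutive runs are paired into (ramp, hold) phases, at most
#' `protocol$n_steps` of them.
#'
#' @param trace A [compression_trace()].
#' @param protocol A [step_protocol()] describing the nominal loading.
#' @param geometry A [gel_geometry()]; its thickness sets the nominal ramp
#'   speed in m/s.
#' @param hold_tol Fraction of the ramp speed below which the gap is
#'   considered stationary. Default 0.01.
#' @return A tibble with one row per detected phase: `step`, `phase`
#'   (`"ramp"`/`"hold"`), `i_start`, `i_end` (sample indices), `t_start`,
#'   `t_end`.
#' @export
segment_steps <- function(trace, protocol, geometry = gel_geometry(),
                          hold_tol = 0.01) {
  stopifnot(inherits(trace, "compression_trace"),
            inherits(protocol, "step_protocol"))
  n <- nrow(trace)
  if (n < 5L) stop_invalid("trace too short to segment")
  tt <- trace$time_s
  gg <- trace$gap_m
  dt <- median(diff(tt))
  # centred derivative, then a ~1 s moving average to suppress sensor noise
  vel <- c(NA, (gg[-1] - gg[-n]) / (tt[-1] - tt[-n]))
  vel[1] <- vel[2]
  win <- max(1L, round(1 / dt))
  if (win > 1L && n > win) {
    kern <- rep(1 / win, win)
    sm <- stats::filter(vel, kern, sides = 2)
    vel <- ifelse(is.na(sm), vel, as.numeric(sm))
  }
  ramp_speed <- protocol$ramp_rate * geometry$thickness
  moving <- vel < -hold_tol * ramp_speed
  r <- rle(moving)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  # keep only substantial runs (> 20 % of the nominal ramp duration)
  min_len <- max(2L, round(0.2 * protocol_ramp_time(protocol) / dt))
  keep <- r$lengths >= min_len | !r$values
  phases <- list()
  step <- 0L
  i <- 1L
  while (i <= length(r$lengths)) {
    if (r$values[i] && keep[i]) {
      step <- step + 1L
      if (step > protocol$n_steps) break
      phases[[length(phases) + 1L]] <- tibble(
        step = step, phase = "ramp",
        i_start = starts[i], i_end = ends[i]
      )
      # the following stationary run (if any) is this step's hold
      if (i + 1L <= length(r$lengths) && !r$values[i + 1L]) {
        phases[[length(phases) + 1L]] <- tibble(
          step = step, phase = "hold",
          i_start = starts[i + 1L], i_end = ends[i + 1L]
        )
        i <- i + 1L
      }
    }
    i <- i + 1L
  }
  if (length(phases) == 0L) {
    stop_degenerate("no compression steps detected in trace")
  }
  out <- bind_rows(phases)
  out$t_start <- tt[out$i_start]
  out$t_end <- tt[out$i_end]
  out
}

#' Equilibrium stretch/stress pairs from the hold phases
#'
#' For each detected hold, averages the gap and force over the final 60 s of
#' the hold (the relaxed plateau) and converts them to a stretch ratio and a
#' signed Cauchy stress. Holds shorter than the averaging window fall back to
#' their final third, with a warning.
#'
#' @inheritParams segment_steps
#' @param window Averaging window at the end of each hold (s). Default 60.
#' @return A tibble with columns `step`, `lambda`, `sigma` (signed Cauchy
#'   stress, Pa; negative in compression) and `stress_compressive`
#'   (`-sigma`, positive in compression).
#' @export
equilibrium_points <- function(trace, protocol, geometry = gel_geometry(),
                               window = 60) {
  seg <- segment_steps(trace, protocol, geometry)
  holds <- seg[seg$phase == "hold", ]
  if (nrow(holds) == 0L) stop_degenerate("no hold phases detected")
  rows <- purrr::pmap(holds, function(step, phase, i_start, i_end,
                                      t_start, t_end, ...) {
    dur <- t_end - t_start
    if (dur >= window) {
      t0 <- t_end - window
    } else {
      warn(sprintf("hold %d lasts %.3g s < %.3g s window; using final third",
                   step, dur, window))
      t0 <- t_end - dur / 3
    }
    idx <- which(trace$time_s >= t0 & trace$time_s <= t_end)
    idx <- idx[idx >= i_start & idx <= i_end]
    lam <- stretch_from_gap(mean(trace$gap_m[idx]), geometry)
    s <- cauchy_stress(mean(trace$force_N[idx]), geometry)
    tibble(step = step, lambda = lam, sigma = -s, stress_compressive = s)
  })
  bind_rows(rows)
}

#' Per-step peak forces
#'
#' Reports, for each detected compression step, both the maximum force over
#' the whole step (ramp plus hold; the default reading) and the force at the
#' end of the ramp.
#'
#' @inheritParams segment_steps
#' @return A tibble with columns `step`, `peak_force` (global per-step
#'   maximum, N), `ramp_end_force` (N), `t_peak` (s).
#' @export
peak_forces <- function(trace, protocol, geometry = gel_geometry()) {
  seg <- segment_steps(trace, protocol, geometry)
  steps <- unique(seg$step)
  rows <- purrr::map(steps, function(s) {
    ph <- seg[seg$step == s, ]
    i0 <- min(ph$i_start)
    i1 <- max(ph$i_end)
    f <- trace$force_N[i0:i1]
    ramp <- ph[ph$phase == "ramp", ]
    tibble(
      step = s,
      peak_force = max(f),
      ramp_end_force = trace$force_N[ramp$i_end[1]],
      t_peak = trace$time_s[i0:i1][which.max(f)]
    )
  })
  bind_rows(rows)
}

#' @export
autoplot.compression_trace <- function(object, ...) {
  df <- tidyr::pivot_longer(
    as_tibble(object),
    c("gap_m", "force_N"),
    names_to = "channel", values_to = "value"
  )
  ggplot(df, aes(x = .data$time_s, y = .data$value)) +
    geom_line() +
    facet_wrap(~channel, ncol = 1, scales = "free_y") +
    labs(x = "time (s)", y = NULL)
}
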