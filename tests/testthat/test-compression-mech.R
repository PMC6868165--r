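make_gap_trace <- function(protocol, geometry, rate = 20, noise_sd = 0,
                           force = NULL, seed = 1) {
  tt <- seq(0, protocol_duration(protocol), by = 1 / rate)
  gap <- geometry$thickness * protocol_stretch(protocol, tt) +
    geometry$coverslip_thickness
  if (noise_sd > 0) {
    set.seed(seed)
    gap <- gap + rnorm(length(tt), 0, noise_sd)
  }
  if (is.null(force)) force <- rep(0, length(tt))
  compression_trace(tt, gap, force)
}

test_that("stress and stretch conversions match the loading geometry", {
  g <- gel_geometry()
  # f - f_off = 5.0265e-2 N on an 8 mm indenter is ~1 kPa
  expect_equal(cauchy_stress(5.0265e-2, g), 1000, tolerance = 1e-4)
  expect_equal(cauchy_stress(g$force_offset, g), 0)
  # affine with slope 4 / (pi D^2) exactly
  f <- c(0.01, 0.02, 0.05)
  expect_equal(cauchy_stress(f, g), (f - g$force_offset) * 4 / (pi * 8e-3^2),
               tolerance = 1e-15)
  expect_equal(cauchy_stress(2 * f[1], g) - cauchy_stress(0, g),
               2 * (cauchy_stress(f[1], g) - cauchy_stress(0, g)))

  expect_equal(stretch_from_gap(g$coverslip_thickness + 3e-3, g), 1)
  expect_equal(stretch_from_gap(g$coverslip_thickness + 2.55e-3, g), 0.85)
  expect_equal(stretch_from_gap(g$coverslip_thickness + 2.46e-3, g), 0.82)
  expect_error(stretch_from_gap(g$coverslip_thickness, g),
               class = "collacomp_invalid_argument")
})

test_that("trace constructor and text round-trip preserve the channels", {
  tr <- compression_trace(0:9 / 10, rep(3.17e-3, 10), sin(0:9))
  path <- withr::local_tempfile(fileext = ".csv")
  write_compression_trace(tr, path)
  back <- read_compression_trace(path)
  expect_equal(back$force_N, tr$force_N)
  expect_warning(compression_trace(c(0, 1, 1, 2), rep(1e-3, 4), rep(0, 4)),
                 "duplicate")
  expect_error(compression_trace(c(0, 1), c(1e-3, -1e-3), c(0, 0)),
               class = "collacomp_invalid_argument")
})

test_that("step segmentation finds ramps and holds, robustly to gap noise", {
  g <- gel_geometry()
  prot <- step_protocol(n_steps = 5)
  tr <- make_gap_trace(prot, g)
  seg <- segment_steps(tr, prot, g)
  expect_identical(sum(seg$phase == "ramp"), 5L)
  expect_identical(sum(seg$phase == "hold"), 5L)
  expect_identical(unique(seg$step), 1:5)

  # a single continuous ramp has one ramp and no holds
  ramp_only <- step_protocol(step_strain = 0.15, ramp_rate = 0.01,
                             hold_duration = 1e-6, n_steps = 1)
  tt <- seq(0, 15, by = 0.05)
  gap <- g$thickness * (1 - 0.01 * tt) + g$coverslip_thickness
  tr2 <- compression_trace(tt, gap, rep(0, length(tt)))
  seg2 <- segment_steps(tr2, ramp_only, g)
  expect_identical(sum(seg2$phase == "ramp"), 1L)
  expect_identical(sum(seg2$phase == "hold"), 0L)

  # 1 um gap noise on 90 um steps leaves the segmentation unchanged
  trn <- make_gap_trace(prot, g, noise_sd = 1e-6)
  segn <- segment_steps(trn, prot, g)
  expect_identical(segn$phase, seg$phase)
  expect_true(all(abs(segn$t_start - seg$t_start) < 1))
})

test_that("equilibrium extraction reproduces the protocol stretch ladder", {
  g <- gel_geometry()
  prot <- step_protocol(n_steps = 6)
  tr <- make_gap_trace(prot, g, force = NULL)
  pts <- equilibrium_points(tr, prot, g)
  expect_equal(pts$lambda, c(0.97, 0.94, 0.91, 0.88, 0.85, 0.82),
               tolerance = 1e-6)
  expect_true(all(diff(pts$lambda) < 0))

  # constant force during a hold averages to itself
  tr$force_N <- rep(0.02, nrow(tr))
  pts2 <- equilibrium_points(tr, prot, g)
  expect_equal(pts2$stress_compressive,
               rep(cauchy_stress(0.02, g), 6), tolerance = 1e-12)
})

test_that("equilibrium stresses of a synthetic biphasic trace match the Yeoh law", {
  g <- gel_geometry()
  prot <- step_protocol(n_steps = 3, hold_duration = 300)
  truth <- ref_params()
  tr <- gen_biphasic_trace(truth, prot, g, rate = 5)
  pts <- equilibrium_points(tr, prot, g)
  expect_equal(pts$sigma, yeoh_stress(truth, pts$lambda), tolerance = 5e-3)
  # round-trip stretch targets
  expect_equal(pts$lambda, 1 - prot$step_strain * (1:3), tolerance = 1e-6)
})

test_that("peak forces sit at ramp end and grow with ramp rate", {
  g <- gel_geometry()
  prot <- step_protocol(n_steps = 2, hold_duration = 120)
  tr <- gen_biphasic_trace(ref_params(), prot, g, rate = 5)
  pk <- peak_forces(tr, prot, g)
  seg <- segment_steps(tr, prot, g)
  ramp_ends <- seg$t_end[seg$phase == "ramp"]
  # monotone relaxation after each ramp: global max is at/near ramp end
  expect_true(all(abs(pk$t_peak - ramp_ends) < 1))
  expect_equal(pk$peak_force, pk$ramp_end_force, tolerance = 0.05)

  fast <- step_protocol(step_strain = 0.03, ramp_rate = 0.03,
                        hold_duration = 120, n_steps = 2)
  tr_fast <- gen_biphasic_trace(ref_params(), fast, g, rate = 5)
  pk_fast <- peak_forces(tr_fast, fast, g)
  expect_true(all(pk_fast$peak_force > pk$peak_force))

  # zero-amplitude force channel gives zero peaks
  tr0 <- make_gap_trace(prot, g)
  expect_true(all(peak_forces(tr0, prot, g)$peak_force == 0))
})
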