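test_that("relaxation trace generator matches the closed form", {
  # sum at t = 0 and decay limit
  m <- maxwell_modes(20, 10, equilibrium_stress = 50)
  tr <- gen_relaxation_trace(m, duration = 200, rate = 10)
  expect_equal(tr$stress_pa[1], 70)
  expect_equal(tr$stress_pa[nrow(tr)], 50, tolerance = 1e-6)

  # direct evaluation of a two-mode decay at t = 1 s
  m2 <- maxwell_modes(c(5, 5), c(1, 100), equilibrium_stress = 0)
  tr2 <- gen_relaxation_trace(m2, duration = 2, rate = 1)
  expect_equal(tr2$stress_pa[2], 5 * exp(-1) + 5 * exp(-0.01),
               tolerance = 1e-12)

  # noiseless trace equals the closed form at every sample
  taus <- c(0.5, 7, 300)
  amps <- c(3, 8, 2)
  m3 <- maxwell_modes(amps, taus, equilibrium_stress = 12)
  tr3 <- gen_relaxation_trace(m3, duration = 100, rate = 25)
  closed <- 12 + rowSums(sapply(seq_along(amps), function(i) {
    amps[i] * exp(-tr3$time_s / taus[i])
  }))
  expect_equal(tr3$stress_pa, closed, tolerance = 1e-12)
})

test_that("generators are reproducible under a fixed seed", {
  m <- maxwell_modes(20, 10, equilibrium_stress = 50, noise_sd = 1)
  a <- gen_relaxation_trace(m, 10, 50, seed = 11)
  b <- gen_relaxation_trace(m, 10, 50, seed = 11)
  expect_identical(a, b)
  c <- gen_relaxation_trace(m, 10, 50, seed = 12)
  expect_false(identical(a$stress_pa, c$stress_pa))

  s1 <- gen_shg_stack(dim_zyx = c(5, 48, 48), seed = 4)
  s2 <- gen_shg_stack(dim_zyx = c(5, 48, 48), seed = 4)
  expect_identical(s1$intensities, s2$intensities)

  tr <- tibble::tibble(time_s = 0:1, radius_um = c(20, 22))
  t1 <- gen_spheroid_timelapse(tr, frame_size = 64, seed = 9)
  t2 <- gen_spheroid_timelapse(tr, frame_size = 64, seed = 9)
  expect_identical(t1$frames, t2$frames)
})

test_that("mode-set validation rejects inadmissible inputs", {
  expect_error(maxwell_modes(c(1, -1), c(1, 2)), class = "collacomp_invalid_argument")
  expect_error(maxwell_modes(c(1, 1), c(2, 1)), class = "collacomp_invalid_argument")
  expect_error(gen_relaxation_trace(maxwell_modes(1, 1), duration = -1),
               class = "collacomp_invalid_argument")
  expect_error(gen_relaxation_trace(maxwell_modes(1, 1), duration = 1, rate = 0),
               class = "collacomp_invalid_argument")
})

test_that("biphasic trace generator honours the drained limit and permeability ordering", {
  prot <- step_protocol(n_steps = 1, hold_duration = 400)
  geom <- gel_geometry()
  tr <- gen_biphasic_trace(ref_params(), prot, geom, rate = 2)
  # end of a long hold: force equals the equilibrium Yeoh stress
  sig_end <- -cauchy_stress(tr$force_N[nrow(tr)], geom)
  expect_equal(sig_end, yeoh_stress(ref_params(), 0.97), tolerance = 1e-3)

  # doubling k shortens the time to reach halfway between peak and plateau
  half_time <- function(k) {
    p <- biphasic_params(250, -200, 2000, k)
    t <- gen_biphasic_trace(p, prot, geom, rate = 2)
    f <- t$force_N
    ipk <- which.max(f)
    target <- (f[ipk] + f[length(f)]) / 2
    t$time_s[ipk + which(f[(ipk + 1):length(f)] < target)[1]] - t$time_s[ipk]
  }
  expect_lt(half_time(2e-10), half_time(1e-10))

  # determinism with noise
  a <- gen_biphasic_trace(ref_params(), prot, geom, noise_rel = 0.01,
                          rate = 2, seed = 5)
  b <- gen_biphasic_trace(ref_params(), prot, geom, noise_rel = 0.01,
                          rate = 2, seed = 5)
  expect_identical(a$force_N, b$force_N)
})

test_that("imaging manifest enumerates the design exactly", {
  d <- imaging_design()
  expect_identical(manifest_count(d), 2112L)
  expect_identical(nrow(imaging_manifest(d)), 2112L)
  expect_identical(manifest_count(imaging_design(1, 1, 1, 1, 1, 1)), 1L)
  d3 <- imaging_design(n_concentrations = 1)
  expect_identical(manifest_count(d3), 528L)
  expect_identical(nrow(imaging_manifest(d3)), manifest_count(d3))
  expect_error(imaging_design(n_channels = 0), class = "collacomp_invalid_argument")
})

test_that("SHG stack generator produces the structures it promises", {
  # densified slab: axial profile peaks inside the slab
  st <- gen_shg_stack(dim_zyx = c(11, 96, 96), densified_layer = c(3, 6, 4),
                      seed = 21)
  prof <- axial_shg_profile(st)
  pk <- prof$depth_um[which.max(prof$mean_intensity)]
  expect_gte(pk, 3)
  expect_lte(pk, 6)

  # attenuation only: profile is non-increasing after light smoothing
  st2 <- gen_shg_stack(dim_zyx = c(11, 96, 96), attenuation_length = 6,
                       noise_sd = 0.01, seed = 22)
  p2 <- axial_shg_profile(st2)$mean_intensity
  sm <- stats::filter(p2, rep(1 / 3, 3))
  sm <- sm[!is.na(sm)]
  expect_true(all(diff(sm) < 0.02 * max(p2)))
})
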