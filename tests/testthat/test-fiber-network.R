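test_that("segment stiffnesses follow k_s = EA/l0 and k_b = EI/l0", {
  cfg <- network_config(E_pa = 5e7)
  st <- segment_stiffnesses(cfg)
  R <- 77.5e-9
  expect_equal(st$k_s, 5e7 * pi * R^2 / 1e-6, tolerance = 1e-12)
  expect_equal(st$k_s, 0.943, tolerance = 1e-3)
  expect_equal(st$k_b, 5e7 * pi * R^4 / 4 / 1e-6, tolerance = 1e-12)
  expect_equal(st$k_b, 1.417e-15, tolerance = 1e-3)
  # k_s linear in E; k_b quartic in radius
  expect_equal(segment_stiffnesses(network_config(E_pa = 1e8))$k_s,
               2 * st$k_s)
  expect_equal(segment_stiffnesses(network_config(fiber_diameter_nm = 310))$k_b,
               16 * st$k_b)
})

test_that("network generation hits the target concentration and is reproducible", {
  cfg <- network_config(box_um = 25, seed = 3)
  net <- generate_network(cfg)
  # mass/density arithmetic: 4 mg/mL in a 25 um box is ~2454 um of fiber
  expected_len <- 4 * (25e-6)^3 / (1350 * pi * (77.5e-9)^2) * 1e6
  expect_equal(net$total_length_um, expected_len, tolerance = 0.05)
  expect_equal(network_porosity(cfg), 1 - 4 / 1350, tolerance = 1e-12)

  net2 <- generate_network(cfg)
  expect_identical(net$nodes, net2$nodes)
  expect_identical(net$crosslinks, net2$crosslinks)

  # segments carry their realized rest lengths; cross-links join distinct
  # fibers at positive rest length
  expect_true(all(net$segments$l0_m > 0))
  expect_equal(median(net$segments$l0_m), 1e-6, tolerance = 0.05)
  fib <- net$segments$fiber[match(net$crosslinks$i, net$segments$i)]
  expect_true(all(net$crosslinks$rest_m >= 0))
  expect_gt(nrow(net$crosslinks) / net$n_fibers, 1)
})

test_that("single-segment stretch matches the hand formula to 1e-10", {
  cfg <- network_config(box_um = 25, waviness = 0)
  ks <- segment_stiffnesses(cfg)$k_s
  l0 <- 1e-6
  nodes <- rbind(c(0, 0, 0), c(l0, 0, 0))
  segs <- tibble::tibble(i = 1L, j = 2L, l0_m = l0, fiber = 1L, k_s = ks)
  net <- toy_network(nodes, segs, config = cfg)
  delta <- 1e-8
  stretched <- nodes
  stretched[2, 1] <- l0 + delta
  en <- elastic_energies(net, stretched)
  expect_equal(en$U_s, 0.5 * ks * delta^2, tolerance = 1e-10)
  expect_equal(en$U_b, 0)
  f <- network_static_forces(net, stretched)
  expect_equal(f$forces[1, 1], ks * delta, tolerance = 1e-10)
  expect_equal(f$forces[2, 1], -ks * delta, tolerance = 1e-10)
})

test_that("three-node bending matches the hand formula to 1e-10", {
  cfg <- network_config(box_um = 25, waviness = 0)
  st <- segment_stiffnesses(cfg)
  l0 <- 1e-6
  theta <- 0.1
  nodes <- toy_bent_chain(theta, l0)
  segs <- tibble::tibble(i = 1:2, j = 2:3, l0_m = l0, fiber = 1L,
                         k_s = st$k_s)
  bends <- tibble::tibble(i = 1L, j = 2L, k = 3L, theta0 = 0)
  net <- toy_network(nodes, segs, bends, config = cfg)
  en <- elastic_energies(net)
  expect_equal(en$U_b, 0.5 * st$k_b * theta^2, tolerance = 1e-10)
  expect_equal(en$U_s, 0, tolerance = 1e-20)
  # the k_b = 1.417e-15, theta = 0.1 case: U_b ~ 7.08e-18 J
  expect_equal(en$U_b, 7.08e-18, tolerance = 1e-3)
})

test_that("boundary stress of a single spanning rod is k_s strain l / area", {
  box <- 25e-6
  cfg <- network_config(box_um = 25, waviness = 0)
  ks_rod <- cfg$E_pa * pi * (77.5e-9)^2 / box  # EA / l for an l = box rod
  nodes <- rbind(c(box / 2, box / 2, 0), c(box / 2, box / 2, box))
  segs <- tibble::tibble(i = 1L, j = 2L, l0_m = box, fiber = 1L,
                         k_s = ks_rod)
  frozen <- rbind(c(1L, 1L, 1L), c(0L, 0L, 0L))
  net <- toy_network(nodes, segs, config = cfg, frozen = frozen,
                     moving = c(FALSE, TRUE))
  squeezed <- nodes
  squeezed[2, 3] <- box * 0.99
  expect_equal(network_boundary_stress(net, squeezed),
               ks_rod * 0.01 * box / box^2, tolerance = 1e-10)
  expect_equal(network_boundary_stress(net, nodes), 0)
})

test_that("cross-links rupture at the transmitted-force threshold, irreversibly", {
  cfg <- network_config(box_um = 25, waviness = 0, f_break_n = 1e-9)
  ks <- segment_stiffnesses(cfg)$k_s
  box <- 25e-6
  # two nodes joined only by a cross-link; the top one moves down,
  # compressing the coupling until it trips the threshold
  nodes <- rbind(c(box / 2, box / 2, box - 2e-6),
                 c(box / 2, box / 2, box))
  segs <- tibble::tibble(i = integer(), j = integer(), l0_m = numeric(),
                         fiber = integer(), k_s = numeric())
  xl <- tibble::tibble(i = 1L, j = 2L, rest_m = 2e-6, intact = TRUE)
  frozen <- rbind(c(1L, 1L, 1L), c(0L, 0L, 0L))
  net <- toy_network(nodes, segs, crosslinks = xl, config = cfg,
                     frozen = frozen, moving = c(FALSE, TRUE))
  # static transmitted force matches k_s * |ext| exactly
  moved <- nodes
  moved[2, 3] <- box - 1e-7
  f <- network_static_forces(net, moved)
  expect_equal(f$xl_force, ks * 1e-7, tolerance = 1e-10)

  # displacement large enough that k_s * ext > f_break: bond breaks and
  # the count never recovers
  prot <- network_protocol(strain = 0.2, ramp_time = 1e-6, hold_time = 5e-6)
  traj <- simulate_network(net, prot, n_record = 100)
  expect_false(traj$intact[1])
  expect_true(all(diff(traj$states$n_crosslinks) <= 0))
  expect_identical(traj$states$n_crosslinks[nrow(traj$states)], 0L)

  # with an unbreakable bond the count never changes
  net2 <- net
  net2$config$f_break_n <- Inf
  traj2 <- simulate_network(net2, prot, n_record = 100)
  expect_true(all(traj2$states$n_crosslinks == 1L))
})

test_that("a zero-displacement protocol leaves the network untouched", {
  cfg <- network_config(box_um = 15, seed = 5)
  net <- generate_network(cfg)
  prot <- network_protocol(strain = 1e-9, ramp_time = 1e-6, hold_time = 5e-6)
  traj <- simulate_network(net, prot, n_record = 20)
  expect_lt(max(traj$states$U_s + traj$states$U_b),
            1e-6 * segment_stiffnesses(cfg)$k_s * (1e-6)^2)
  expect_equal(traj$final_positions, net$nodes, tolerance = 1e-6)
})

test_that("energy decays during holds and cross-link count is monotone", {
  cfg <- network_config(box_um = 15, seed = 5)
  net <- generate_network(cfg)
  traj <- simulate_network(net, network_protocol(strain = 0.03),
                           n_record = 150)
  s <- traj$states
  expect_true(all(diff(s$n_crosslinks) <= 0))
  hold <- which(s$time_s > traj$protocol$ramp_time * 1.2)
  e_tot <- s$U_s + s$U_b
  quiet <- hold[-1][s$ruptures[hold[-1]] == 0]
  drops <- diff(e_tot)[quiet - 1]
  expect_true(all(drops <= 1e-6 * max(e_tot)))
  # bending dominates stretching during the hold
  expect_gt(median(s$U_b[hold] / pmax(s$U_s[hold], 1e-300)), 10)
})

test_that("depth and angle profiles behave on uniform and compressed networks", {
  cfg <- network_config(box_um = 25, seed = 8)
  net <- generate_network(cfg)
  dens <- node_density_profile(net, n_bins = 10)
  expect_identical(sum(dens$count), nrow(net$nodes))
  # flat within counting noise on the undeformed network
  expect_lt(max(abs(dens$count - mean(dens$count))),
            6 * sqrt(mean(dens$count)))
  ang <- fiber_angle_distribution(net)
  expect_true(all(ang$theta_deg >= 0 & ang$theta_deg <= 90))
  expect_true(all(abs(ang$phi_deg) <= 180))
})

test_that("the sweep rejects parameters outside the physical ranges", {
  expect_error(parameter_sweep(5e6, 1e-9), class = "collacomp_invalid_argument")
  expect_error(parameter_sweep(5e7, 1e-13), class = "collacomp_invalid_argument")
})

test_that("trajectories export as multi-frame XYZ text", {
  cfg <- network_config(box_um = 15, seed = 5)
  net <- generate_network(cfg)
  prot <- network_protocol(strain = 0.03, ramp_time = 1e-6, hold_time = 4e-6)
  traj <- simulate_network(net, prot, n_record = 3, save_positions = TRUE)
  path <- withr::local_tempfile(fileext = ".xyz")
  write_network_xyz(traj, path)
  lines <- readLines(path)
  n <- nrow(net$nodes)
  n_frames <- dim(traj$positions)[1]
  expect_identical(length(lines), n_frames * (n + 2L))
  expect_identical(lines[1], as.character(n))
})
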