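#' Compression protocol for a fiber-network simulation
#'
#' One or more identical steps: the moving face is displaced axially by
#' `strain * box` at constant speed over `ramp_time`, then held for
#' `hold_time`. Because the dynamics are overdamped and athermal, the only
#' intrinsic timescales are the drag/stiffness ratios; the defaults place
#' the ramp well above the stretching relaxation time and the hold at a few
#' bending relaxation times so both the stress peak and its decay are
#' resolved.
#'
#' @param strain Compression per step as a fraction of the box edge.
#'   Default 0.03.
#' @param n_steps Number of steps. Default 1.
#' @param ramp_time Ramp duration per step (s). Default 2e-6.
#' @param hold_time Hold duration per step (s). Default 6e-5.
#' @return An object of class `network_protocol`.
#' @export
network_protocol <- function(strain = 0.03, n_steps = 1, ramp_time = 2e-6,
                             hold_time = 6e-5) {
  check_positive_scalar(strain, "strain")
  check_positive_scalar(n_steps, "n_steps")
  check_positive_scalar(ramp_time, "ramp_time")
  check_positive_scalar(hold_time, "hold_time")
  if (strain * n_steps >= 1) stop_invalid("total compression must be < 100 %")
  structure(
    list(strain = strain, n_steps = as.integer(n_steps),
         ramp_time = ramp_time, hold_time = hold_time),
    class = "network_protocol"
  )
}

#' Simulate overdamped network dynamics under boundary compression
#'
#' Integrates `drag * dx/dt = -grad U` for every free node with explicit
#' Euler steps at the stability-bounded timestep, while the moving-face
#' nodes follow the prescribed axial displacement and wall-constrained
#' coordinates stay fixed (frictionless rigid walls). Thermal (Brownian) forces are absent: collagen fiber mechanics is
#' athermal at these scales. At every step each intact cross-link's
#' transmitted force is compared against `f_break`; exceeding it removes
#' the bond irreversibly. Cross-links are realized as near-rigid couplings
#' of stiffness `k_s` between the closest nodes of the two fibers: this is
#' already two to three orders of magnitude stiffer than the bending modes
#' that set network compliance, and the force a coupling transmits at
#' mechanical balance does not depend on its stiffness. If the integration goes unstable the timestep is
#' reduced four-fold and the run restarted (up to three times) before
#' aborting with diagnostics.
#'
#' @param network A [generate_network()] result.
#' @param protocol A [network_protocol()].
#' @param n_record Approximate number of recorded states. Default 200.
#' @param save_positions Record node positions at every recorded state (for
#'   [depth_profiles()] time courses). The initial and final positions are
#'   always kept. Default FALSE.
#' @return An object of class `network_trajectory`: list with `states` (a
#'   tibble: `time_s`, `stress_pa`, `U_s`, `U_b`, `n_crosslinks`,
#'   `ruptures`), `final_positions`, `initial_positions`, `intact`,
#'   `displacement_m`, `network`, `protocol`, `dt`, and (optionally)
#'   `positions`, an array `n_record x n_nodes x 3`.
#' @export
simulate_network <- function(network, protocol = network_protocol(),
                             n_record = 200, save_positions = FALSE) {
  stopifnot(inherits(network, "fiber_network"),
            inherits(protocol, "network_protocol"))
  cfg <- network$config
  st <- segment_stiffnesses(cfg)
  xl_stiff <- st$k_s
  k_bend <- st$k_b
  l0 <- cfg$l0_um * 1e-6
  # explicit-Euler stability: the fastest mode is bounded by the total
  # elastic stiffness attached to a single node (segments + cross-links +
  # bending); dt = drag / max(k_node) is the worst-case Gershgorin bound,
  # taken with a 3x safety factor
  n_nodes_all <- nrow(network$nodes)
  k_node <- numeric(n_nodes_all)
  for (col in c("i", "j")) {
    k_node <- k_node + tabulate_weighted(network$segments[[col]],
                                         network$segments$k_s, n_nodes_all)
    if (nrow(network$crosslinks) > 0L) {
      k_node <- k_node + tabulate_weighted(network$crosslinks[[col]],
                                           rep(xl_stiff, nrow(network$crosslinks)),
                                           n_nodes_all)
    }
  }
  k_node <- k_node + 4 * k_bend / l0^2
  dt <- if (is.null(cfg$dt)) cfg$drag / (3 * max(k_node)) else cfg$dt

  box <- cfg$box_um * 1e-6
  disp <- protocol$strain * box
  face_area <- box^2

  for (attempt in 1:4) {
    t_step <- protocol$ramp_time + protocol$hold_time
    total_t <- protocol$n_steps * t_step
    n_steps_int <- ceiling(total_t / dt)
    # per-Euler-step moving-face velocity (piecewise constant schedule)
    tt <- (seq_len(n_steps_int) - 1L) * dt
    in_ramp <- (tt %% t_step) < protocol$ramp_time
    vz <- ifelse(in_ramp, -disp / protocol$ramp_time, 0)
    record_every <- max(1L, floor(n_steps_int / n_record))

    res <- network_simulate_cpp(
      network$nodes,
      as.matrix(network$segments[, c("i", "j")]) - 1L,
      network$segments$l0_m, network$segments$k_s,
      as.matrix(network$bends[, c("i", "j", "k")]) - 1L,
      network$bends$theta0, k_bend,
      as.matrix(network$crosslinks[, c("i", "j")]) - 1L,
      network$crosslinks$rest_m,
      xl_stiff, cfg$f_break_n,
      network$frozen, network$moving, cfg$drag, dt, n_steps_int, vz,
      record_every, face_area, save_positions
    )
    if (!res$unstable) break
    warn(sprintf("network integration unstable at dt = %.3g s; retrying at dt/4", dt))
    if (attempt == 4) {
      stop_nonconvergence(sprintf(
        "network integration unstable down to dt = %.3g s (energies diverged)", dt))
    }
    dt <- dt / 4
  }

  n_nodes <- nrow(network$nodes)
  out <- list(
    states = tibble(
      time_s = res$time, stress_pa = res$stress,
      U_s = res$U_s, U_b = res$U_b,
      n_crosslinks = res$n_xl, ruptures = res$ruptures
    ),
    final_positions = matrix(res$final_positions, n_nodes, 3, byrow = TRUE),
    initial_positions = network$nodes,
    intact = res$intact,
    displacement_m = disp * protocol$n_steps,
    network = network, protocol = protocol, dt = dt
  )
  if (save_positions) {
    nr <- res$n_recorded
    out$positions <- aperm(
      array(res$positions[seq_len(nr * 3 * n_nodes)], c(3, n_nodes, nr)),
      c(3, 2, 1)
    )
  }
  structure(out, class = "network_trajectory")
}

#' @export
print.network_trajectory <- function(x, ...) {
  s <- x$states
  cat("<network_trajectory>\n")
  cat(sprintf("  %d states over %.3g s (dt = %.3g s)\n",
              nrow(s), max(s$time_s), x$dt))
  cat(sprintf("  peak stress %.4g Pa, final stress %.4g Pa\n",
              max(s$stress_pa), s$stress_pa[nrow(s)]))
  cat(sprintf("  cross-links %d -> %d (%.2g %% ruptured)\n",
              s$n_crosslinks[1], s$n_crosslinks[nrow(s)],
              100 * (1 - s$n_crosslinks[nrow(s)] / max(s$n_crosslinks[1], 1L))))
  invisible(x)
}

#' @export
autoplot.network_trajectory <- function(object, ...) {
  df <- tidyr::pivot_longer(
    object$states,
    c("stress_pa", "U_s", "U_b", "n_crosslinks"),
    names_to = "quantity", values_to = "value"
  )
  ggplot(df, aes(x = .data$time_s, y = .data$value)) +
    geom_line() +
    facet_wrap(~quantity, scales = "free_y") +
    labs(x = "time (s)", y = NULL)
}

#' Elastic energies of a network configuration
#'
#' Total stretching energy `sum 1/2 k_s (l - l0)^2` and bending energy
#' `sum 1/2 k_b (theta - theta0)^2` at the given node positions (default:
#' the generated, undeformed positions).
#'
#' @param network A [generate_network()] result.
#' @param positions Optional n x 3 position matrix (m); default
#'   `network$nodes`.
#' @return A tibble with columns `U_s` and `U_b` (J).
#' @export
elastic_energies <- function(network, positions = network$nodes) {
  f <- network_static_forces(network, positions)
  tibble(U_s = f$U_s, U_b = f$U_b)
}

#' Static nodal forces and cross-link loads
#'
#' Evaluates the elastic force on every node and the transmitted force in
#' every intact cross-link at the given positions. Used for force-balance
#' audits and for checking the rupture criterion against hand calculations.
#'
#' @inheritParams elastic_energies
#' @param intact Logical vector of cross-link states; default all intact.
#' @return A list with `forces` (n x 3, N), `U_s`, `U_b` (J), `xl_force`
#'   (N per cross-link, NA when ruptured).
#' @export
network_static_forces <- function(network, positions = network$nodes,
                                  intact = NULL) {
  stopifnot(inherits(network, "fiber_network"))
  cfg <- network$config
  st <- segment_stiffnesses(cfg)
  if (is.null(intact)) intact <- rep(TRUE, nrow(network$crosslinks))
  network_forces_cpp(
    positions,
    as.matrix(network$segments[, c("i", "j")]) - 1L,
    network$segments$l0_m, network$segments$k_s,
    as.matrix(network$bends[, c("i", "j", "k")]) - 1L,
    network$bends$theta0, st$k_b,
    as.matrix(network$crosslinks[, c("i", "j")]) - 1L,
    network$crosslinks$rest_m, st$k_s, intact
  )
}

#' Boundary stress at given node positions
#'
#' Net axial elastic force transmitted to the moving-face nodes divided by
#' the face area; positive in compression.
#'
#' @inheritParams network_static_forces
#' @return Stress (Pa).
#' @export
network_boundary_stress <- function(network, positions = network$nodes,
                                    intact = NULL) {
  f <- network_static_forces(network, positions, intact)
  sum(f$forces[network$moving, 3]) / (network$config$box_um * 1e-6)^2
}

#' Node density versus depth below the compressed surface
#'
#' Bins node counts along the compression axis, with depth `zeta` measured
#' from the current moving-face plane downwards. On an undeformed uniform
#' network the profile is flat to within counting noise; after compression
#' of a soft, rupturing network the density peaks in the bins nearest the
#' moving face (surface densification).
#'
#' @param network A [generate_network()] result.
#' @param positions n x 3 position matrix; default the undeformed nodes.
#' @param displacement_m Axial displacement of the moving face (m), used to
#'   locate the current surface. Default 0.
#' @param n_bins Number of depth bins. Default 20.
#' @return A tibble with columns `zeta_um` (bin centre), `count`,
#'   `density_um3` (nodes per um^3).
#' @export
node_density_profile <- function(network, positions = network$nodes,
                                 displacement_m = 0, n_bins = 20) {
  stopifnot(inherits(network, "fiber_network"))
  box <- network$config$box_um * 1e-6
  z_face <- box - displacement_m
  zeta <- (z_face - positions[, 3]) * 1e6      # um, 0 at the moving face
  depth_max <- z_face * 1e6
  breaks <- seq(0, depth_max, length.out = n_bins + 1L)
  idx <- cut(zeta, breaks, include.lowest = TRUE, labels = FALSE)
  counts <- tabulate(idx, nbins = n_bins)
  bin_vol <- (network$config$box_um)^2 * diff(breaks)
  tibble(
    zeta_um = (breaks[-1] + breaks[-length(breaks)]) / 2,
    count = counts,
    density_um3 = counts / bin_vol
  )
}

#' Fiber segment angle distributions
#'
#' In-plane azimuth `phi` (degrees, in the plane perpendicular to the
#' compression axis) and out-of-plane elevation `theta` (degrees, angle
#' between the segment and that plane) for every segment at the given
#' positions. Compression of a soft network shifts `|theta|` towards zero:
#' fibers realign perpendicular to the loading direction.
#'
#' @inheritParams node_density_profile
#' @return A tibble with columns `segment`, `phi_deg`, `theta_deg`.
#' @export
fiber_angle_distribution <- function(network, positions = network$nodes) {
  stopifnot(inherits(network, "fiber_network"))
  p1 <- positions[network$segments$i, , drop = FALSE]
  p2 <- positions[network$segments$j, , drop = FALSE]
  d <- p2 - p1
  len <- sqrt(rowSums(d^2))
  tibble(
    segment = seq_len(nrow(d)),
    phi_deg = atan2(d[, 2], d[, 1]) * 180 / pi,
    theta_deg = asin(pmin(1, abs(d[, 3]) / pmax(len, 1e-300))) * 180 / pi
  )
}

#' Depth and orientation profiles of a network state
#'
#' Convenience wrapper returning both [node_density_profile()] and
#' [fiber_angle_distribution()] for one state of a trajectory.
#'
#' @param trajectory A [simulate_network()] result.
#' @param which `"final"` (default) or `"initial"`.
#' @param n_bins Depth bins for the density profile.
#' @return A list with elements `density` and `angles`.
#' @export
depth_profiles <- function(trajectory, which = c("final", "initial"),
                           n_bins = 20) {
  stopifnot(inherits(trajectory, "network_trajectory"))
  which <- match.arg(which)
  pos <- if (which == "final") trajectory$final_positions else
    trajectory$initial_positions
  disp <- if (which == "final") trajectory$displacement_m else 0
  list(
    density = node_density_profile(trajectory$network, pos, disp, n_bins),
    angles = fiber_angle_distribution(trajectory$network, pos)
  )
}

#' Sweep fiber modulus and cross-link strength
#'
#' Runs one simulation per `(E, f_break)` grid point on a shared network
#' geometry (the same seed, so the same fibers and cross-links) and
#' summarizes each run. Failures in individual cells are recorded and the
#' sweep continues.
#'
#' Overdamped athermal dynamics is self-similar in the dimensionless time
#' `t k_s / drag`: scaling every stiffness by a factor and time by its
#' inverse reproduces the identical trajectory with stresses scaled up.
#' Comparing cells of different `E` at the same absolute time would
#' therefore conflate the modulus with the stage of relaxation reached. By
#' default (`scale_time = TRUE`) the protocol is interpreted at the
#' reference modulus `config$E_pa` and each cell's ramp and hold durations
#' are scaled by `config$E_pa / E`, so all cells are loaded and observed at
#' matched dimensionless times; cross-link rupture, whose threshold
#' `f_break` is an absolute force, is then the only symmetry-breaking
#' difference between cells besides the stress scale.
#'
#' @param E_values Fiber Young's moduli (Pa).
#' @param f_break_values Cross-link breaking forces (N).
#' @param config Base [network_config()] providing geometry and seed.
#' @param protocol A [network_protocol()], interpreted at the reference
#'   modulus `config$E_pa`.
#' @param scale_time Scale each cell's protocol durations by
#'   `config$E_pa / E` (matched dimensionless time). Default TRUE.
#' @return A tibble with one row per grid cell: `E_pa`, `f_break_n`,
#'   `peak_stress_pa`, `eq_stress_pa` (mean over the final 10 % of the last
#'   hold), `delta_U_s`, `delta_U_b` (J), `xl_initial`, `xl_final`,
#'   `xl_rupture_frac`, `error` (NA on success).
#' @export
parameter_sweep <- function(E_values, f_break_values,
                            config = network_config(box_um = 25),
                            protocol = network_protocol(n_steps = 2),
                            scale_time = TRUE) {
  if (any(E_values < 1e7 - 1e-9) || any(E_values > 2.5e8 + 1e-9)) {
    stop_invalid("`E_values` must lie within [1e7, 2.5e8] Pa")
  }
  if (any(f_break_values < 1e-12) || any(f_break_values > 1e-6)) {
    stop_invalid("`f_break_values` must lie within [1e-12, 1e-6] N")
  }
  base <- generate_network(config)
  grid <- tidyr::expand_grid(E_pa = E_values, f_break_n = f_break_values)
  rows <- purrr::pmap(grid, function(E_pa, f_break_n) {
    res <- tryCatch({
      net <- base
      scale <- E_pa / config$E_pa
      net$config$E_pa <- E_pa
      net$config$f_break_n <- f_break_n
      net$segments$k_s <- net$segments$k_s * scale
      prot <- protocol
      if (scale_time) {
        prot$ramp_time <- protocol$ramp_time / scale
        prot$hold_time <- protocol$hold_time / scale
      }
      traj <- simulate_network(net, prot)
      s <- traj$states
      n_tail <- max(1L, round(0.1 * nrow(s)))
      xl0 <- s$n_crosslinks[1]
      tibble(
        E_pa = E_pa, f_break_n = f_break_n,
        peak_stress_pa = max(s$stress_pa),
        eq_stress_pa = mean(s$stress_pa[(nrow(s) - n_tail + 1L):nrow(s)]),
        delta_U_s = s$U_s[nrow(s)] - s$U_s[1],
        delta_U_b = s$U_b[nrow(s)] - s$U_b[1],
        xl_initial = xl0,
        xl_final = s$n_crosslinks[nrow(s)],
        xl_rupture_frac = if (xl0 > 0) 1 - s$n_crosslinks[nrow(s)] / xl0 else 0,
        error = NA_character_
      )
    }, error = function(e) {
      tibble(E_pa = E_pa, f_break_n = f_break_n,
             peak_stress_pa = NA_real_, eq_stress_pa = NA_real_,
             delta_U_s = NA_real_, delta_U_b = NA_real_,
             xl_initial = NA_integer_, xl_final = NA_integer_,
             xl_rupture_frac = NA_real_, error = conditionMessage(e))
    })
    res
  })
  bind_rows(rows)
}


# sum of weights per index (like tabulate() with weights)
tabulate_weighted <- function(idx, w, n) {
  out <- numeric(n)
  agg <- rowsum(w, idx)
  out[as.integer(rownames(agg))] <- agg[, 1]
  out
}

#' Export network node positions as an XYZ trajectory file
#'
#' Writes one XYZ frame per recorded state (requires a trajectory run with
#' `save_positions = TRUE`) or a single frame of the final positions, with
#' coordinates in micrometres. XYZ is the lowest-common-denominator format
#' read by molecular visualization tools, which render fiber networks well
#' when nodes are displayed as bonded beads.
#'
#' @param trajectory A [simulate_network()] result.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_network_xyz <- function(trajectory, path) {
  stopifnot(inherits(trajectory, "network_trajectory"))
  frames <- if (!is.null(trajectory$positions)) {
    lapply(seq_len(dim(trajectory$positions)[1]), function(i) {
      trajectory$positions[i, , ]
    })
  } else {
    list(trajectory$final_positions)
  }
  con <- file(path, "w")
  on.exit(close(con))
  for (fr in frames) {
    writeLines(as.character(nrow(fr)), con)
    writeLines("collacomp fiber network (um)", con)
    writeLines(sprintf("C %.6f %.6f %.6f",
                       fr[, 1] * 1e6, fr[, 2] * 1e6, fr[, 3] * 1e6), con)
  }
  invisible(path)
}
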