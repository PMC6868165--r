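#' Discrete fiber-network configuration
#'
#' Parameters for generating and simulating a three-dimensional collagen
#' fiber network. Fibers of fixed diameter are laid down with random
#' positions and orientations inside a cubic box until the prescribed mass
#' concentration is reached, then discretized into segments of nominal
#' length `l0_um` that behave as linear elastic rods (stretching stiffness
#' `k_s = E A / l0`, bending stiffness `k_b = E I / l0`). Rigid cross-links
#' form wherever two fibers pass within `d_xl_um` of each other and rupture
#' irreversibly when the transmitted force exceeds `f_break_n`.
#'
#' Fiber lengths are drawn from a lognormal distribution (median
#' `length_median_um`, log-SD `length_sdlog`) truncated to
#' `length_range_um`, a shape consistent with fiber-tracing measurements on
#' reconstituted collagen.
#'
#' The per-node drag coefficient defaults to the Stokes drag of one rod
#' segment in water, `4 pi eta l0 / ln(l0 / d)` with `eta = 8.9e-4` Pa s;
#' together with `k_s` it sets the (sub-microsecond) relaxation timescale
#' of the simulated dynamics.
#'
#' @param box_um Cube edge (um). Default 50; 25 is a convenient desk scale.
#' @param concentration_mg_ml Collagen concentration (mg/mL). Default 4.
#' @param fiber_diameter_nm Fiber diameter (nm). Default 155.
#' @param l0_um Segment rest length (um). Default 1.
#' @param length_median_um,length_sdlog,length_range_um Fiber-length
#'   distribution: lognormal median (um), log-SD, truncation range (um).
#' @param mass_density_g_cm3 Collagen mass density (g/cm^3). Default 1.35.
#' @param d_xl_um Maximum fiber-fiber distance for cross-link formation
#'   (um). Default 0.6, which yields roughly two cross-links per fiber and
#'   a mechanically percolated network; sparser networks cannot transmit
#'   equilibrium load at all.
#' @param waviness Natural fiber undulation: interior nodes are displaced
#'   transversally by a Gaussian of SD `waviness * l0`, and the perturbed
#'   geometry is taken as the stress-free state (rest lengths and rest
#'   angles are measured from it). Real collagen fibers are not perfectly
#'   straight, and a perfectly straight rod under axial load can never
#'   buckle in deterministic athermal dynamics; the undulation supplies the
#'   physical imperfection that lets compressed fibers buckle. Default
#'   0.05.
#' @param E_pa Fiber Young's modulus (Pa), in \[1e7, 2.5e8\] for the
#'   physiological sweep. Default 5e7.
#' @param f_break_n Cross-link breaking force (N). Default 1e-9.
#' @param drag Per-node drag coefficient (N s/m); `NULL` for the Stokes
#'   default.
#' @param dt Integration timestep (s); `NULL` for the stability bound
#'   `drag / (10 k_max)` with `k_max` the stiffest coupling in the system.
#' @param clamp_depth_um Nodes within this distance of a fixed face are
#'   clamped; same depth defines the moving-face slab. Default 1.
#' @param seed Integer seed controlling network geometry. Default 1.
#' @return An object of class `network_config`.
#' @examples
#' network_config(box_um = 25)
#' @export
network_config <- function(box_um = 50, concentration_mg_ml = 4,
                           fiber_diameter_nm = 155, l0_um = 1,
                           length_median_um = 8, length_sdlog = 0.5,
                           length_range_um = c(2, 25),
                           mass_density_g_cm3 = 1.35,
                           d_xl_um = 0.6, waviness = 0.05, E_pa = 5e7,
                           f_break_n = 1e-9,
                           drag = NULL, dt = NULL, clamp_depth_um = 1,
                           seed = 1) {
  for (nm in c("box_um", "concentration_mg_ml", "fiber_diameter_nm", "l0_um",
               "length_median_um", "length_sdlog", "mass_density_g_cm3",
               "d_xl_um", "E_pa", "f_break_n", "clamp_depth_um")) {
    check_positive_scalar(get(nm), nm)
  }
  if (waviness < 0) stop_invalid("`waviness` must be >= 0")
  if (length(length_range_um) != 2L || any(length_range_um <= 0) ||
      length_range_um[2] <= length_range_um[1]) {
    stop_invalid("`length_range_um` must be an increasing positive pair")
  }
  if (l0_um > length_range_um[1]) {
    stop_invalid("`l0_um` must not exceed the shortest admissible fiber")
  }
  cfg <- structure(
    list(
      box_um = box_um, concentration_mg_ml = concentration_mg_ml,
      fiber_diameter_nm = fiber_diameter_nm, l0_um = l0_um,
      length_median_um = length_median_um, length_sdlog = length_sdlog,
      length_range_um = length_range_um,
      mass_density_g_cm3 = mass_density_g_cm3,
      d_xl_um = d_xl_um, waviness = waviness, E_pa = E_pa,
      f_break_n = f_break_n,
      drag = drag, dt = dt, clamp_depth_um = clamp_depth_um,
      seed = as.integer(seed)
    ),
    class = "network_config"
  )
  if (is.null(cfg$drag)) {
    eta <- 8.9e-4  # water at ~25 C, Pa s
    l0 <- l0_um * 1e-6
    d <- fiber_diameter_nm * 1e-9
    cfg$drag <- 4 * pi * eta * l0 / log(l0 / d)
  }
  cfg
}

#' @export
print.network_config <- function(x, ...) {
  st <- segment_stiffnesses(x)
  cat("<network_config>\n")
  cat(sprintf("  box %g um, %g mg/mL, fiber diameter %g nm, l0 = %g um\n",
              x$box_um, x$concentration_mg_ml, x$fiber_diameter_nm, x$l0_um))
  cat(sprintf("  E = %.3g Pa, f_break = %.3g N, d_xl = %g um\n",
              x$E_pa, x$f_break_n, x$d_xl_um))
  cat(sprintf("  k_s = %.4g N/m, k_b = %.4g N m, drag = %.3g N s/m\n",
              st$k_s, st$k_b, x$drag))
  invisible(x)
}

#' Segment stretching and bending stiffness
#'
#' `k_s = E A / l0` and `k_b = E I / l0` with `A = pi R^2` and
#' `I = pi R^4 / 4` for a rod of radius `R`.
#'
#' @param config A [network_config()].
#' @return A tibble with columns `k_s` (N/m) and `k_b` (N m).
#' @examples
#' segment_stiffnesses(network_config(E_pa = 5e7))  # k_s ~ 0.943 N/m
#' @export
segment_stiffnesses <- function(config) {
  stopifnot(inherits(config, "network_config"))
  R <- config$fiber_diameter_nm * 1e-9 / 2
  l0 <- config$l0_um * 1e-6
  A <- pi * R^2
  I <- pi * R^4 / 4
  tibble(k_s = config$E_pa * A / l0, k_b = config$E_pa * I / l0)
}

#' Generate a random fiber network at a target concentration
#'
#' Straight fibers (uniform random centre, orientation uniform on the
#' sphere, lognormal length) are added and clipped to the box until the
#' contained fiber mass reaches `concentration * box volume`; each fiber is
#' discretized into segments of nominal length `l0` (a terminal remainder
#' segment keeps the sampled length). Cross-link candidates are detected by
#' sampling points along every segment on a uniform spatial grid: any two
#' fibers passing within `d_xl_um` are joined by a stiff coupling (stiffness
#' `10 k_s`) between their nearest nodes. The confining walls are rigid and
#' frictionless: nodes within `clamp_depth_um` of a fixed face have the
#' wall-normal coordinate frozen (they may still slide along the wall),
#' and nodes within the same depth of the top face (`z = box`) form the
#' moving face whose axial coordinate follows the compression protocol.
#'
#' The generator is deterministic given `config$seed`.
#'
#' @param config A [network_config()].
#' @return An object of class `fiber_network`: list with `nodes` (n x 3
#'   matrix, m), `segments` (tibble `i`, `j`, `l0_m`, `fiber`, `k_s`),
#'   `bends` (tibble `i`, `j`, `k`, `theta0`), `crosslinks` (tibble `i`,
#'   `j`, `rest_m`, `intact`), `node_role` (0 free / 1 wall-constrained /
#'   2 moving face), `frozen` (n x 3, per-coordinate wall constraints),
#'   `moving` (logical), `n_fibers`, `total_length_um`, `config`.
#' @export
generate_network <- function(config) {
  stopifnot(inherits(config, "network_config"))
  box <- config$box_um * 1e-6
  l0 <- config$l0_um * 1e-6
  R <- config$fiber_diameter_nm * 1e-9 / 2
  rho <- config$mass_density_g_cm3 * 1000           # kg/m^3
  mass_per_len <- rho * pi * R^2                    # kg/m
  target_mass <- config$concentration_mg_ml * box^3 # mg/mL == kg/m^3
  max_mass_len <- box / 1.05
  if (mass_per_len * max_mass_len <= 0) {
    stop_invalid("degenerate fiber geometry")
  }
  # sanity: a single fully contained fiber must carry a useful mass fraction
  if (target_mass / mass_per_len > 1e9 * box) {
    stop_invalid("target concentration unreachable with this fiber diameter/box")
  }

  with_seed(config$seed, {
    nodes <- list(); segs <- list(); fibers_n <- 0L
    mass <- 0
    node_count <- 0L
    mu <- log(config$length_median_um * 1e-6)
    lo <- config$length_range_um[1] * 1e-6
    hi <- config$length_range_um[2] * 1e-6
    guard <- 0L
    while (mass < target_mass) {
      guard <- guard + 1L
      if (guard > 5e5) stop_invalid("network generation failed to reach the target concentration")
      L <- exp(rnorm(1, mu, config$length_sdlog))
      if (L < lo || L > hi) next
      ctr <- runif(3, 0, box)
      # uniform direction on the sphere
      u <- rnorm(3); u <- u / sqrt(sum(u^2))
      n_seg <- floor(L / l0)
      s_break <- seq(0, n_seg * l0, by = l0)
      rem <- L - n_seg * l0
      if (rem > 0.1 * l0) s_break <- c(s_break, L)
      if (length(s_break) < 2L) next
      pos <- outer(s_break - L / 2, u) + rep(ctr, each = length(s_break))
      inside <- rowSums(pos >= 0 & pos <= box) == 3L
      # straight fiber: the inside nodes form one contiguous run; keep the
      # longest such run
      r <- rle(inside)
      if (!any(r$values)) next
      runs <- which(r$values)
      lens <- r$lengths[runs]
      best <- runs[which.max(lens)]
      i1 <- sum(r$lengths[seq_len(best - 1L)]) + 1L
      i2 <- i1 + r$lengths[best] - 1L
      if (i2 - i1 < 1L) next
      keep <- i1:i2
      pos <- pos[keep, , drop = FALSE]
      fibers_n <- fibers_n + 1L
      nn <- nrow(pos)
      if (config$waviness > 0 && nn > 2L) {
        # natural undulation: transverse Gaussian displacement of the nodes,
        # taken up below as the stress-free reference geometry
        g <- matrix(rnorm(3L * nn, 0, config$waviness * l0), nn, 3)
        g <- g - outer(as.numeric(g %*% u), u)
        pos <- pos + g
      }
      nodes[[fibers_n]] <- pos
      segs[[fibers_n]] <- tibble(
        i = node_count + seq_len(nn - 1L),
        j = node_count + seq_len(nn - 1L) + 1L,
        l0_m = diff(s_break[keep]),
        fiber = fibers_n
      )
      node_count <- node_count + nn
      mass <- mass + mass_per_len * sum(diff(s_break[keep]))
    }
    nodes <- do.call(rbind, nodes)
    segments <- bind_rows(segs)
    # the as-generated (wavy) geometry is the stress-free state: rest
    # lengths are the realized node spacings
    segments$l0_m <- sqrt(rowSums((nodes[segments$j, , drop = FALSE] -
                                     nodes[segments$i, , drop = FALSE])^2))
    A <- pi * R^2
    segments$k_s <- config$E_pa * A / segments$l0_m

    # bends: consecutive segment pairs within a fiber, rest angle 0 (straight)
    bends <- segments |>
      group_by(.data$fiber) |>
      summarise(bi = list(.data$i[-length(.data$i)]),
                bj = list(.data$j[-length(.data$j)]),
                bk = list(.data$j[-1L]), .groups = "drop") |>
      tidyr::unnest(c("bi", "bj", "bk")) |>
      dplyr::transmute(i = .data$bi, j = .data$bj, k = .data$bk)
    if (nrow(bends) > 0L) {
      v1 <- nodes[bends$j, , drop = FALSE] - nodes[bends$i, , drop = FALSE]
      v2 <- nodes[bends$k, , drop = FALSE] - nodes[bends$j, , drop = FALSE]
      cosb <- rowSums(v1 * v2) /
        pmax(sqrt(rowSums(v1^2)) * sqrt(rowSums(v2^2)), 1e-300)
      bends$theta0 <- acos(pmin(1, pmax(-1, cosb)))
    } else {
      bends$theta0 <- numeric(0)
    }

    # cross-link detection on sampled points along each segment
    n_samp <- 5L
    frac <- seq(0, 1, length.out = n_samp)
    p1 <- nodes[segments$i, , drop = FALSE]
    p2 <- nodes[segments$j, , drop = FALSE]
    m <- nrow(segments)
    pts <- matrix(0, m * n_samp, 3)
    for (s in seq_len(n_samp)) {
      pts[(s - 1L) * m + seq_len(m), ] <- p1 + frac[s] * (p2 - p1)
    }
    samp_fiber <- rep(segments$fiber, times = n_samp)
    samp_node <- ifelse(rep(frac, each = m) < 0.5,
                        rep(segments$i, times = n_samp),
                        rep(segments$j, times = n_samp))
    cand <- crosslink_candidates_cpp(pts, samp_fiber, samp_node - 1L,
                                     config$d_xl_um * 1e-6)
    if (nrow(cand) > 0L) {
      ii <- cand[, 1] + 1L
      jj <- cand[, 2] + 1L
      rest <- sqrt(rowSums((nodes[ii, , drop = FALSE] -
                              nodes[jj, , drop = FALSE])^2))
      crosslinks <- tibble(i = ii, j = jj, rest_m = rest, intact = TRUE)
    } else {
      crosslinks <- tibble(i = integer(), j = integer(),
                           rest_m = numeric(), intact = logical())
    }

    # boundary constraints: rigid frictionless walls freeze only their
    # normal coordinate; the moving (top) face prescribes z
    clamp <- config$clamp_depth_um * 1e-6
    frozen <- matrix(0L, nrow(nodes), 3)
    frozen[nodes[, 1] < clamp | nodes[, 1] > box - clamp, 1] <- 1L
    frozen[nodes[, 2] < clamp | nodes[, 2] > box - clamp, 2] <- 1L
    frozen[nodes[, 3] < clamp, 3] <- 1L
    moving <- nodes[, 3] > box - clamp
    frozen[moving, 3] <- 0L
    role <- integer(nrow(nodes))
    role[rowSums(frozen) > 0] <- 1L
    role[moving] <- 2L

    structure(
      list(
        nodes = nodes, segments = segments, bends = bends,
        crosslinks = crosslinks, node_role = role,
        frozen = frozen, moving = moving,
        n_fibers = fibers_n,
        total_length_um = sum(segments$l0_m) * 1e6,
        config = config
      ),
      class = "fiber_network"
    )
  })
}

#' @export
print.fiber_network <- function(x, ...) {
  cat("<fiber_network>\n")
  cat(sprintf("  %d fibers, %d nodes, %d segments, %d cross-links\n",
              x$n_fibers, nrow(x$nodes), nrow(x$segments),
              nrow(x$crosslinks)))
  cat(sprintf("  total fiber length %.4g um in a %g um box\n",
              x$total_length_um, x$config$box_um))
  cat(sprintf("  node roles: %d free / %d clamped / %d moving\n",
              sum(x$node_role == 0L), sum(x$node_role == 1L),
              sum(x$node_role == 2L)))
  invisible(x)
}

#' Geometric porosity of a network configuration
#'
#' One minus the fiber volume fraction `concentration / mass density`;
#' independent of the realized geometry.
#'
#' @param config A [network_config()].
#' @return Porosity in \[0, 1\].
#' @examples
#' network_porosity(network_config())  # ~0.997 at 4 mg/mL
#' @export
network_porosity <- function(config) {
  stopifnot(inherits(config, "network_config"))
  1 - config$concentration_mg_ml / (config$mass_density_g_cm3 * 1000)
}
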