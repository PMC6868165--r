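# Shared oracles and fixture builders. Everything here is independent of
# the implementation paths it is used to check.

# Closed-form boundary stress for LINEAR poroelastic consolidation under a
# ramp-and-hold displacement in confined compression: eigenfunction series
# for the diffusion equation u_t = D u_ZZ with a constant-flux boundary at
# the drained face (Z = 0) during the ramp and an impermeable far face.
# D = HA * k; stress at the drained face is HA * u(0, t).
linear_consolidation_stress <- function(times, H, HA, k, strain_rate,
                                        t_ramp, n_terms = 400) {
  D <- HA * k
  A <- H * strain_rate / D
  n <- seq_len(n_terms)
  mu <- n^2 * pi^2 * D / H^2
  vapply(times, function(t) {
    if (t <= t_ramp) {
      u0 <- -strain_rate * t - A * H / 3 +
        sum(2 * H * A / (n^2 * pi^2) * exp(-mu * t))
    } else {
      u0 <- -strain_rate * t_ramp +
        sum(2 * H * A / (n^2 * pi^2) *
              (exp(-mu * t) - exp(-mu * (t - t_ramp))))
    }
    HA * u0
  }, numeric(1))
}

# Reference biphasic parameters used across recovery tests: soft gel with
# a consolidation time of ~90 s at H = 3 mm (well resolved by 180 s holds)
ref_params <- function() biphasic_params(c1 = 250, c2 = -200, c3 = 2000,
                                         k = 1e-10)

# A small wavy three-node chain for analytic bending checks
toy_bent_chain <- function(theta, l0 = 1e-6) {
  rbind(
    c(-l0, 0, 0),
    c(0, 0, 0),
    c(l0 * cos(theta), l0 * sin(theta), 0)
  )
}

# Build a minimal hand-made fiber_network (bypassing the random generator)
# so two-node toys can be compared against pencil-and-paper formulas.
toy_network <- function(nodes, segments, bends = NULL, crosslinks = NULL,
                        config = network_config(box_um = 25, waviness = 0),
                        frozen = NULL, moving = NULL) {
  n <- nrow(nodes)
  if (is.null(bends)) {
    bends <- tibble::tibble(i = integer(), j = integer(), k = integer(),
                            theta0 = numeric())
  }
  if (is.null(crosslinks)) {
    crosslinks <- tibble::tibble(i = integer(), j = integer(),
                                 rest_m = numeric(), intact = logical())
  }
  if (is.null(frozen)) frozen <- matrix(0L, n, 3)
  if (is.null(moving)) moving <- rep(FALSE, n)
  role <- integer(n)
  role[rowSums(frozen) > 0] <- 1L
  role[moving] <- 2L
  structure(
    list(nodes = nodes, segments = segments, bends = bends,
         crosslinks = crosslinks, node_role = role, frozen = frozen,
         moving = moving, n_fibers = 1L,
         total_length_um = sum(segments$l0_m) * 1e6, config = config),
    class = "fiber_network"
  )
}
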