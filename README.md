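# collacomp

Compressive mechanics and remodeling of collagen networks.

Growing tumor spheroids compress the fibrous collagen around them. The
matrix responds by densifying into a tangentially aligned capsule — the
TACS-2 phenotype — and that densification changes how easily interstitial
fluid can move through the peri-tumoral stroma. `collacomp` implements the
computational toolchain for studying this process with confined-compression
rheometry, multiphoton imaging and discrete network simulation:

* **Biphasic (poroelastic) confined compression.** A gel column of
  unloaded thickness *H* is treated as an incompressible Yeoh solid matrix,

  *W* = c₁(I−3) + c₂(I−3)² + c₃(I−3)³,  with c₁, c₃ > 0 and c₂ < 0,

  plus interstitial fluid obeying Darcy's law with constant isotropic
  hydraulic permeability *k* (m⁴ N⁻¹ s⁻¹). Quasi-static equilibrium makes
  the total axial stress uniform in depth, and mass balance yields a
  nonlinear consolidation equation for the local stretch λ(Z,t),
  ∂λ/∂t = ∂/∂Z [k ∂σₑ(λ)/∂Z], solved by a conservative finite-volume
  method of lines (`solve_confined_compression()`). Parameters are
  estimated by the two-step procedure used in cartilage biomechanics:
  Yeoh coefficients from relaxed equilibrium stress–stretch points,
  then *k* from the pooled transient response (`two_step_fit()`).
* **Continuous relaxation-time spectra.** Stress decays
  σ(t) = σₑ + ∫ H(τ) e^(−t/τ) d ln τ are inverted on a log-spaced τ grid
  over [10⁻², 10⁴] s by non-negative least squares with a curvature
  penalty, L-curve-selected by default (`fit_spectrum()`,
  `per_step_spectra()`, `spectrum_area()`).
* **Discrete fiber networks.** Collagen fibers (diameter 155 nm, lognormal
  lengths) are laid down at 4 mg/mL in a cubic box, discretized into 1 µm
  segments with stretching stiffness k_s = EA/l₀ and bending stiffness
  k_b = EI/l₀, cross-linked where fibers pass close to one another, and
  evolved with overdamped athermal dynamics under boundary compression.
  Cross-links rupture irreversibly when their transmitted force exceeds
  f_break (`generate_network()`, `simulate_network()`,
  `parameter_sweep()`).
* **Image quantification.** Spheroid radius tracking by Mumford–Shah-type
  centre detection plus the radial-graininess 75 % rule
  (`spheroid_radius()`), SHG thresholding (mean + 2 SD of background
  maxima, largest group wins), areal porosity, masked TPF intensity,
  radial/axial intensity profiles, gel thickness and densified-layer
  detection.
* **Spheroid kinematics.** The expanding-spherical-inclusion solution maps
  a radius time course a(t) to matrix stretches: λ_θ = λ_φ = a/a₀ and
  λ_r = (a₀/a)² at the boundary (`boundary_stretches()`,
  `stretch_field()`, `track_to_stretches()`).
* **Synthetic data.** Seeded generators for every input class —
  multi-exponential decays, forward-simulated compression traces,
  fiber-rendered SHG stacks with depth attenuation and optional densified
  slabs, textured spheroid time-lapses — so the whole pipeline is testable
  without laboratory data.

All user-facing functions take data frames and return tibbles; fitted
objects support `tidy()`, `glance()` and `autoplot()`.

## Worked example

Simulate a six-step confined-compression experiment on a known gel, add
1 % force noise, and recover its parameters:

```r
library(collacomp)

truth <- biphasic_params(c1 = 250, c2 = -200, c3 = 2000, k = 1e-10)
prot  <- step_protocol()        # 6 x 3 % steps at 1 %/s, 180 s holds
geom  <- gel_geometry()         # H = 3 mm, D = 8 mm indenter

trace <- gen_biphasic_trace(truth, prot, geom,
                            noise_rel = 0.01, rate = 10, seed = 1)
fit <- two_step_fit(trace, geom, prot)
tidy(fit)
#> # A tibble: 4 x 3
#>   term   estimate stage
#>   <chr>     <dbl> <chr>
#> 1 c1     2.50e+ 2 equilibrium
#> 2 c2    -1.98e+ 2 equilibrium
#> 3 c3     2.00e+ 3 equilibrium
#> 4 k      1.00e-10 transient
```

The Yeoh coefficients come back within a fraction of a percent and the
permeability within half a percent of the generating values. The per-step
force decays can be inverted into relaxation spectra:

```r
spectra <- per_step_spectra(trace, prot, geom)
spectra[, c("step", "strain", "sigma_e", "area", "n_peaks")]
```

and a control-like fiber network shows the compressive-remodeling
signature after 15 % compression — a node-density peak at the compressed
face (about 1.8x the bulk density) and fiber realignment perpendicular to
the loading axis:

```r
net  <- generate_network(network_config(box_um = 25))
traj <- simulate_network(net, network_protocol(strain = 0.15,
                                               ramp_time = 1e-5,
                                               hold_time = 8e-5))
depth_profiles(traj)$density
```

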