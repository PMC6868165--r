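---
title: "Models and methods behind collacomp"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind collacomp}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(collacomp)
```

`collacomp` bundles the quantitative methods for studying how compression
remodels fibrous collagen: continuum poroelastic modeling of confined
compression, relaxation-spectrum analysis of stress decays, a discrete
fiber-network simulator with breakable cross-links, image quantification
for second-harmonic-generation (SHG) and time-lapse data, and the
kinematics of an expanding spheroid. This vignette explains each model,
its assumptions, the tunable parameters, the numerical choices, and what
the synthetic-data generators do and do not emulate.

## The biphasic confined-compression model

A collagen hydrogel is treated as a mixture of an intrinsically
incompressible solid skeleton and incompressible interstitial fluid. In
confined compression the gel column (unloaded thickness `H`, default
3 mm) deforms uniaxially: the deformation gradient is diag(1, 1, λ), so
the first invariant of the right Cauchy–Green tensor is I = λ² + 2. The
solid stress derives from the Yeoh strain energy

W(I) = c₁(I−3) + c₂(I−3)² + c₃(I−3)³,

with admissibility constraints c₁ > 0, c₃ > 0, c₂ < 0. The axial
effective stress is taken as

σₑ(λ) = (2/λ) W′(I) (λ² − 1),

which vanishes in the reference state, is compressive for λ < 1, and has
small-strain slope 4c₁ — the aggregate modulus of the linearized model.
The exact reduction of the Yeoh law to 1-D confined kinematics admits
equivalent algebraic forms; this one is isolated in `yeoh_stress()` so an
alternative can be swapped without touching the solver or the fits, and
every recovery test is self-consistent with whichever form is configured.
The strain-dependent shear modulus is reported as μ(λ) = 2W′(I), so
μ(1) = 2c₁, and the stored compressive energy as −W.

Fluid transport follows Darcy's law with a constant, isotropic hydraulic
permeability k (m⁴ N⁻¹ s⁻¹) — justified by the very high porosity
(≥ 99.7 % even at 4 mg/mL) and random fiber orientation. The constant
permeability is applied in the material frame (flux = k ∂σₑ/∂Z), which
keeps the governing equation parabolic and matches the strain-independent
assumption. Combining momentum balance (total stress uniform in depth),
Darcy's law and mass conservation gives a nonlinear diffusion equation
for the stretch field,

∂λ/∂t = ∂/∂Z [ k ∂σₑ(λ)/∂Z ],  Z ∈ [0, H],

with zero flux at the impermeable bottom (Z = H) and, at the
free-draining indenter face (Z = 0), a flux equal to the prescribed rate
of thickness change — the displacement-control statement that the column
must expel exactly the fluid volume the ramp displaces. Free drainage
(p = 0 at Z = 0) then reconstructs the pressure field,
p(Z,t) = σₑ(λ(Z,t)) − σₑ(λ(0,t)), and the measurable boundary stress
σ_ZZ(0,t) = σₑ(λ(0,t)).

### Discretization and verification

The PDE is solved by a conservative finite-volume method of lines on a
uniform material grid (60 cells by default) with the stiff LSODA
integrator (`rtol = 1e-8`, `atol = 1e-10`), restarted at every ramp/hold
transition so the piecewise-constant compression rate is represented
exactly. The discrete scheme conserves volume to round-off: the stretch
integral equals the prescribed thickness at every output time.

The solver is verified against an independently derived closed-form
eigenfunction series for *linear* ramp-and-hold consolidation (aggregate
modulus H_A = 4c₁, gel time constant H²/(H_A k)); at 0.5–1 % strain steps
the two agree to well under 2 % once the ramp-scale boundary layer has
passed. One caveat worth stating: in a biphasic model with incompressible
constituents an instantaneous displacement step is singular — the
boundary-layer stress and the far-face pressure grow without bound as the
ramp shortens — so "undrained limit" intuitions from compressible
poroelasticity do not transfer. The model's monotone contracts (faster
ramps give higher peak bottom pressure; halving k raises the peak and
slows the consolidation-stage decay) are tested instead.

### Two-step parameter estimation

Following standard practice in cartilage biomechanics, fitting proceeds
in two deterministic stages:

1. **Equilibrium.** The relaxed stress–stretch points (last 60 s of each
   hold) determine c₁, c₂, c₃. Because σₑ is linear in the coefficients,
   the sign-constrained problem is solved *exactly* by non-negative least
   squares with the signs absorbed into the design matrix — no starting
   values, no local minima. Coefficients pinned at a constraint are
   flagged.
2. **Transient.** With the material fixed, k is estimated from the pooled
   transient samples of all steps (equal weighting per sample), searched
   in log₁₀ k over [−14, −8]: a fixed 7-point bracketing grid followed by
   golden-section refinement. Determinism here is a feature: repeated fits
   of the same trace are bit-identical. A fit whose objective is
   essentially flat across the whole grid (no transient information)
   refuses with a classed error rather than returning an arbitrary k.

The transient stage thins traces to at most 1500 samples by uniform
stride; this preserves the equal-weight structure of the objective while
bounding the cost of each forward solve.

## Relaxation-time spectra

Stress decays are modeled as σ(t) = σₑ + ∫ H(τ) e^(−t/τ) d ln τ with
H ≥ 0 on a log-spaced grid of 10 points per decade over [10⁻², 10⁴] s
(61 nodes), the integral approximated by trapezoidal quadrature in ln τ.
This inversion is a classic ill-posed problem, so the fit minimizes the
residual plus a second-difference (curvature) penalty on H over ln τ,
subject to H ≥ 0 and σₑ ≥ 0, solved by non-negative least squares on the
stacked system. The penalty weight is chosen at the corner of the
L-curve (maximum discrete Menger curvature of log residual norm against
log seminorm over a fixed 17-point weight grid) unless supplied. Long
traces are thinned to 300 log-spaced time points: a decay carries
information per decade of time, not per sample.

Peak counting uses topographic prominence with a floor of 5 % of the
spectrum maximum; the area ∫ H d ln τ recovers the total decaying
amplitude for well-separated modes and serves as the dissipated-energy
proxy per compression step. Degenerate inputs (no measurable decay)
return a flagged zero spectrum rather than an error, because "this hold
did not relax" is a legitimate observation.

## The discrete fiber network

Fibers of diameter 155 nm are generated with uniform random positions
and orientations and lognormal lengths (median 8 µm, log-SD 0.5,
truncated to 2–25 µm — the scale reported by fiber-tracing tools on
reconstituted collagen; the measured distribution itself is not
available, so the family is fully configurable). Fibers are added until
the boxed fiber mass reaches the target concentration (default 4 mg/mL;
with collagen density 1.35 g/cm³ this is a fiber volume fraction of
0.296 %, i.e. geometric porosity 99.70 %). Each fiber is discretized into
segments of nominal length l₀ = 1 µm — below the persistence length, so
segments act as linear elastic rods with k_s = EA/l₀ and k_b = EI/l₀.

Five modeling choices deserve explanation:

* **Waviness.** Interior nodes are displaced transversally by a Gaussian
  of SD 0.05·l₀ and the perturbed geometry is adopted as the stress-free
  state (rest lengths and rest angles measured from it). Real collagen
  fibers are undulated, and the imperfection is load-bearing here: a
  perfectly straight rod under axial compression in deterministic
  athermal dynamics sits on an unstable symmetric equilibrium and can
  never buckle. Without waviness, compressed fibers freeze at high
  stretching energy; with it they buckle and the network relaxes by
  bending, which is the mechanism under study.
* **Cross-links.** Candidate pairs are found by sampling five points per
  segment on a uniform spatial grid; two fibers passing within d_xl
  (default 0.6 µm) are joined by a near-rigid coupling between their
  closest nodes. The default gives roughly two cross-links per fiber, a
  mechanically percolated network — with substantially sparser linking
  the network cannot transmit any equilibrium load and parameter
  contrasts between stiff and soft cells cannot exist. The coupling
  stiffness equals k_s: that is already two to three orders of magnitude
  stiffer than the bending modes that set network compliance, the
  transmitted force at mechanical balance does not depend on the coupling
  stiffness (rigid-link proxy), and stiffer couplings only shrink the
  stable explicit timestep. Nearly coincident nodes are handled by the
  same coupling with near-zero rest length.
* **Rupture.** Each step, the transmitted coupling force k_s·|Δl| of
  every intact cross-link is compared with f_break; exceeding it removes
  the bond irreversibly. The "total force at the cross-link" of the
  original description is ambiguous for a two-node coupling; the
  transmitted force is the measurable proxy.
* **Boundaries.** The chamber walls are rigid and frictionless: a wall
  constrains only its normal coordinate, so material can slide along the
  walls and the indenter, as in the physical experiment. The moving face
  (top 1 µm slab) has its axial coordinate prescribed. Freezing all three
  coordinates at the walls instead rigidly traps segments that connect a
  wall node to a moving-face node and buries the network response under
  boundary artifacts.
* **Dynamics and timestep.** Motion is overdamped and athermal
  (drag·dx/dt = −∇U; collagen fiber mechanics at these scales is
  athermal, so Brownian forces are omitted). The per-node drag defaults
  to the Stokes drag of one rod segment in water. The explicit-Euler
  timestep uses the worst-case Gershgorin stability bound from the total
  elastic stiffness attached to any single node, with a 3x safety
  factor; if the energies nevertheless diverge the run restarts at a
  four-fold smaller step (at most three times) before aborting.

Boundary stress is the net axial elastic force transmitted to the
moving-face nodes divided by the face area (reaction-force definition,
positive in compression). Depth profiles bin node counts against the
depth ζ below the current compressed surface; orientation is summarized
by the in-plane azimuth φ and the out-of-plane angle θ between a segment
and the plane perpendicular to compression, in degrees.

**Protocol timescales.** With stiffness-proportional forces and constant
drag, the only intrinsic timescales are drag/stiffness ratios: the
stretching time is ~10⁻⁸ s and the slowest fiber-scale bending modes
relax over ~10⁻⁴ s. Protocol defaults (2 µs ramps, 60 µs holds) resolve
the stress peak and most of its bending-mediated decay; the simulation
clock is physical but should be read as "a few bending relaxation
times", not laboratory seconds — hydrodynamic coupling to the fluid,
which sets laboratory timescales, is deliberately out of scope.

**The sweep compares cells at matched dimensionless time.** Overdamped
athermal dynamics is exactly self-similar under a modulus rescaling
(E → sE, t → t/s reproduces the identical trajectory with stresses
scaled by s). `parameter_sweep()` therefore interprets the protocol at
the reference modulus and scales each cell's durations by E_ref/E, so
every cell is loaded and observed at the same dimensionless time
t·k_s/drag. Without this, cells of different E are compared at different
stages of relaxation and the modulus effect is conflated with protocol
truncation. The absolute breaking force f_break is then the only
symmetry-breaking parameter besides the stress scale, which is exactly
the contrast of interest. Desk-scale default is a 25 µm box (~2500
segments); the 50 µm box is a `network_config(box_um = 50)` away.

## Image quantification

**Centre detection.** The spheroid centre minimizes a two-phase
piecewise-constant segmentation energy — the region-fidelity term of the
Mumford–Shah functional — over all pixel centres and a fixed family of
six candidate radii (10–45 % of the frame edge), the radius marginalized
by taking the best per centre. The within/outside sums of squares for
every centre are computed in closed form with FFT disk convolutions, so
the search is exhaustive, deterministic and fast; zero padding makes
partially overlapping disks (spheroids at the frame edge) score
correctly. A constant frame raises a degenerate-input error.

**Radius by graininess.** The graininess is the first-order
approximation to the squared image gradient (forward differences),
averaged in 1 px annuli. The radius is read where the profile, scanning
outward from its maximum, last falls below 75 % of the maximum and stays
below for at least two consecutive bins (single-bin noise immunity),
with linear interpolation of the crossing. Annuli with fewer than 30
pixels — the innermost rings and the clipped outermost ones — are
excluded because their means are dominated by counting noise. Detection
is declared unreliable (classed error, not a silent number) when the
binned profile has no contrast: 90th percentile below twice the 10th.
Volumetric time-lapses are flattened by minimum-intensity projection
before detection.

**SHG thresholding and porosity.** The intensity threshold is the mean
plus twice the sample standard deviation (n−1; background groups are
small) of the per-image *maxima* in fiber-free background regions,
computed per experimental group, with the largest group threshold applied
globally so one rule binarizes every image. Areal porosity is one minus
the fiber area fraction averaged over slices; for randomly oriented
fibers it equals the volumetric porosity. Whether the original rule used
per-image maxima or per-pixel statistics is not fully specified upstream;
the per-image-maximum reading is implemented and the statistic is a plain
function argument.

**Profiles, thickness, densified layers.** Radial and axial mean
intensity profiles conserve the count-weighted total under re-binning.
Gel thickness is the distance between the first and last sustained
crossings (≥ 2 slices) of a configurable fraction (default 0.5) of the
per-region profile maximum, averaged over three lateral sub-regions.
Densified layers are detected on a profile after removing a
single-exponential attenuation baseline fitted with a guard band
(±15 % of the coordinate range) around the candidate peak; a peak
qualifies if its topographic prominence exceeds both 10 % of the profile
range and five times the robust noise of the detrended baseline, ties
break by prominence then smaller depth, and the width is measured at half
prominence. "No layer" is a value, not an error.

## Spheroid kinematics

The growing spheroid is modeled as an expanding spherical inclusion in an
infinite, isotropic, incompressible matrix: a material point initially at
radius R moves to r = (R³ + a³ − a₀³)^(1/3), giving λ_θ = λ_φ = r/R and
λ_r = (R/r)², hence λ_r λ_θ λ_φ = 1 identically. At the boundary
(R = a₀) this reduces to λ_θ = a/a₀ and λ_r = (a₀/a)²: growth compresses
the matrix radially and stretches it tangentially, consistent with the
observed densification geometry. Whether the original analysis allowed
matrix compressibility is not recoverable; the incompressible
cavity-expansion solution is the default and the natural hook for a
compressible variant.

## What the synthetic data does and does not emulate

The generators reproduce the *statistical structure the analyses
assume*: multi-exponential or consolidation-shaped decays with additive
and/or multiplicative i.i.d. Gaussian noise; SHG stacks as rendered line
segments with per-slice Gaussian blur, exponential depth attenuation and
optional densified slabs (fiber centres are sampled in a margin-extended
volume so edge slices are not artificially depleted); time-lapse frames
as speckled disks whose mean offset and texture both scale with the
contrast parameter, so zero contrast is genuinely undetectable. They do
not attempt physical SHG/DIC image formation, detector physics, drift,
or spatially correlated noise, and the experimental noise magnitudes are
not known — defaults are plausible placeholders. Passing recovery tests
therefore demonstrates correctness of the estimators under the stated
noise model, not robustness to every artifact of real microscopy or
rheometry.

## Problem sizes and reproducibility

Tests and the acceptance script run at desk scale by design: 10 Hz
synthetic traces (the estimators are information- not rate-limited),
60/40-node solver grids, 25 µm network boxes, 96–128 px frames, and 50
Monte-Carlo seeds for the recovery study. Every stochastic step is
seeded through one mechanism (`with_seed()`), which restores the
caller's RNG state, so identical seeds give bit-identical outputs and
test runs do not perturb user code.

## Known limitations

* The continuum model has no intrinsic solid viscoelasticity or
  plasticity: everything transient is interstitial flow. The relaxation
  spectra of real gels contain modes this model cannot produce.
* Permeability is strain-independent by assumption; the fit will absorb
  mild strain dependence into a biased constant.
* The network model omits fiber–fluid coupling, thermal fluctuations,
  cross-link re-formation and intra-segment plasticity; rupture is the
  only irreversibility.
* The inclusion kinematics assume an infinite isotropic matrix and
  spherical symmetry; nearby stiff boundaries or non-spherical spheroids
  violate it.
* The Mumford–Shah centre search assumes one roughly disk-like object
  per frame.
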