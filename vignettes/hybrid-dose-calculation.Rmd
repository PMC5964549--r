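---
title: "Hybrid dose calculation for microbeam radiation therapy: models, parameters and numerics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Hybrid dose calculation for microbeam radiation therapy}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mrtdose)
```

## The model

Microbeam radiation therapy (MRT) delivers arrays of planar X-ray
beamlets, typically 50 µm wide at 400 µm centre-to-centre spacing, at
photon energies around 100 keV. The dose distribution has two very
different spatial scales: photons travel centimetres between
interactions, while the secondary electrons that actually deposit the
dose travel at most a few hundred micrometres. The microbeam *peak* dose
comes from electrons liberated by the primary, unscattered beam inside
the beamlet; the *valley* dose between beamlets is dominated by scattered
photons.

`mrtdose` exploits this separation:

* **Photon transport** is simulated by Monte Carlo on the coarse (CT)
  voxel grid. Only photon physics is modelled — photoelectric
  absorption, Compton scattering off free electrons (Klein–Nishina) and
  Rayleigh scattering; pair production is kinematically impossible below
  1.022 MeV and bremsstrahlung from low-energy electrons in light
  materials is negligible. Secondary electrons are killed at creation:
  their initial kinetic energy is deposited at the interaction point,
  justified because electron ranges (≤ a few hundred µm) are small
  against the voxel size (1–2 mm). Energy transferred at a history's
  first interaction is scored into a *primary* cube, everything later
  into a *scatter* cube. Dose is scored energy divided by the voxel mass
  ρ·V.
* **Electron transport** is analytic. Within one voxel the material,
  spectrum and beam intensity are taken as constant, so primary
  energy-transfer events are distributed laterally like the collimator
  fluence ν and uniformly along the beam. The fine dose in the voxel is

  $$D = D_\mathrm{Scatter} + D_\mathrm{Primary}\,(K_\mathrm{el} * \nu),$$

  a 1D convolution for planar beams and a 2D convolution for pencil-beam
  grids. The scatter dose is a homogeneous bath at the voxel scale.

### The electron kernel

Fitting measured electron stopping powers between 10 keV and a few
hundred keV with a power law $S = K E^{-\alpha/(1-\alpha)}$ gives
$\alpha \approx 0.415$ independent of material. Under isotropic emission
and straight CSDA slowing-down in a homogeneous medium the dose kernel
around a primary interaction is

$$K^{3D}_\mathrm{el}(r) = \frac{E_0 (1-\alpha)}{4\pi\sigma\rho r^2}
  \left(1-\frac{r}{\sigma}\right)^{-\alpha}, \qquad r \in [0, \sigma],$$

where $\sigma$ is the CSDA range. Integrating over the longitudinal
coordinate(s) yields the 2D and 1D kernels through the helper integrals

$$I^{\alpha}_{2D}(p) = \int_0^{\cos^{-1} p}
   \left(1-\frac{p}{\cos\varphi}\right)^{-\alpha} d\varphi,
  \qquad
  I^{\alpha}_{1D}(p) = \int_0^{p} \frac{x^{-\alpha}}{1-x}\,dx.$$

The range model is anchored at 43 µm for 50 keV electrons in water and
scales as $E^{1/(1-\alpha)}$ and inversely with density; the stopping
prefactor $K$ never needs to be materialised. Photoelectrons receive the
full photon energy (binding neglected); Compton electrons receive the
mean Klein–Nishina transfer fraction $p(E)\,E$. For a polychromatic beam
with fractional *power* $f(E_i)$ per line, the kernel is the weighted sum
with weights $f_i\,\mu_c/(p\mu_c+\mu_p)$ for the Compton component at
$E_0 = pE_i$ and $f_i\,\mu_p/(p\mu_c+\mu_p)$ for the photoelectron
component at $E_0 = E_i$; its mass integral is then exactly the mean
energy $\sum_i f_i E_i$. Using a single mean $p$ per line (rather than
the full Compton electron spectrum) is a deliberate approximation, shared
with the kernel derivation's neglect of range straggling.

## Tunable parameters

| parameter | default | units | rationale |
|---|---|---|---|
| `alpha` | 0.415 | – | stopping-power fit, material independent |
| range anchor | 43 µm @ 50 keV (water) | µm, keV | measured CSDA range |
| slit width / pitch | 50 / 400 | µm | standard MRT collimation |
| fine lateral bin | 5 | µm | resolves the 50 µm slit with 10 bins |
| fine longitudinal bin | 500 | µm | dose varies slowly along the beam |
| emission pixel | 100 (50 for small fields) | µm | source-plane rasterisation; not stated by the physics, configurable |
| photon cutoff | 2 | keV | residual range ≪ voxel; deposited locally |
| batches | 10 | – | 95% CIs from batch-to-batch variance |
| coarse voxel | 1–2 | mm | CT-scale grid; electron range must stay below it |

## Monte Carlo numerics

* **Woodcock (delta) tracking.** Free paths are drawn against a global
  majorant attenuation (the maximum over the materials and densities
  present, per energy); "null" collisions make the scheme exact in
  heterogeneous voxel arrays without ray–voxel marching, and it
  vectorises over photon batches.
* **Klein–Nishina sampling** is plain rejection on the scattering angle
  with majorant 2 in the normalised angular density (exact, and
  acceptably efficient below 500 keV). Rayleigh angles use the Thomson
  $(1+\cos^2\theta)$ distribution without an atomic form factor: the
  event is elastic and deposits nothing, so only small-angle detail is
  affected — a documented simplification.
* **Classification convention:** a Rayleigh event counts as the
  history's first interaction (primary class) while depositing nothing;
  the next interaction scores as scatter.
* **Bookkeeping.** Emitted = deposited(primary) + deposited(scatter) +
  escaped is enforced to 1e-6 relative each run (in practice it closes to
  machine precision).
* **Reproducibility** is guaranteed for a fixed (seed, batch count).

## Cross sections

Material coefficients live on an embedded 25-point log grid over
10–500 keV with log-log interpolation. Compton uses the closed-form
Klein–Nishina total cross section times the electron density (the
free-electron model is used consistently in sampling, kernels and
coefficients; binding and Doppler broadening are neglected).
Photoelectric and Rayleigh per-element coefficients are compact power-law
parameterisations calibrated against a standard compilation (water
anchors at 50 and 100 keV; approximate $Z^{4.5}$ and $Z^{2.3}$ scaling
across H, C, N, O, P, Ca), accurate at the few-percent level over the
range — sufficient for the fraction-level statements the package makes
(photoelectric share in water: ~11% of interactions at 50 keV, below 2%
at 100 keV). Mixtures follow mass-weighted additivity. The
Hounsfield-unit mapping is a simplified four-piece ramp
(air / lung-like / water / bone), not a full 24-bin tissue
decomposition: the fixtures only need air–water–bone discrimination.

## Kernel numerics

Both helper integrals have integrable endpoint singularities. $I_{2D}$
is evaluated after the substitution $u = 1 - p/\cos\varphi$, with the
$u^{-\alpha}$ head absorbed by $u = \tau^{1/(1-\alpha)}$ and the
inverse-square-root tail by $u = b - t^2$, leaving smooth integrands for
adaptive quadrature at 1e-9 relative tolerance. $I_{1D}$ sums the
$x^{-\alpha}$ head as an analytic series and integrates the remainder.
The 1D kernel diverges logarithmically at $y = 0$ and the 3D kernel as
$r^{-2}$, so point evaluation at the origin is refused; discretisation
goes through mass-conserving *cell integration*: in 1D an exact one-sided
cumulative (closed form up to $I_{1D}$) makes every bin the true bin
average, in 2D tensor Gauss–Legendre quadrature covers off-centre cells
and the central cell takes the conservation remainder. The discrete mass
sum equals the kernel's mean transferred energy to 1e-6 (exactly, in 1D).
A bin wider than the range collapses to a single delta bin.

The modulation $M = \hat K * \nu$ is computed as a circular convolution
over one collimator period (FFT), rescaled to an exact unit period mean.
Kernels wider than a period simply wrap, which is the correct periodic
limit.

## Design choices that were genuinely open

* **Field-edge voxels.** The Monte Carlo emits the *unmodulated* field
  envelope; the slit structure enters only through ν. For voxels at the
  lateral field edge the package convolves the finite, clipped comb and
  divides by the voxel's envelope coverage fraction. With the default
  geometry the pitch (400 µm) is incommensurate with the voxel (1 mm =
  2.5 periods), so exact per-voxel mean conservation and a uniform peak
  amplitude across voxels cannot both hold; we keep the peak amplitude
  physical (normalisation by envelope coverage, not by the modulated
  mean). Conservation tests therefore use commensurate geometry
  (0.8 mm voxels = 2 periods), where the identity is exact.
* **Power vs photon counts.** Spectrum fractions are *power* fractions;
  photon counts are sampled proportional to $f/E$.
* **Beam directions** are restricted to the grid axes; cross-firing
  composes axis-aligned fields with trilinear resampling onto a common
  grid. Oblique incidence is out of scope.
* **One kernel per (material, density, spectrum).** No per-depth
  spectral hardening: the within-voxel assumption is that spectrum and
  intensity do not change across a voxel; hardening across voxels is not
  modelled.
* **Pencil-beam fields** use the periodic 2D modulation everywhere
  (no finite-edge refinement); the planar path implements the
  edge-aware reconstruction.
* **PVDR estimator convention:** peak = mean over the central 10 µm of
  each interior slit, valley = mean over the central 100 µm of each
  interior gap; comb positions outside the irradiated field (the profile
  may extend beyond it) are dropped by a 10%-of-maximum slit-dose
  threshold. Any fixed convention works as long as both sides of a
  comparison share it.

## Validation strategy

Three independent routes guard the science:

1. The closed-form kernels are checked against their defining integrals:
   mass integrals equal $E_0$ (1e-6 to 1e-8), and the 2D/1D kernels equal
   numerical integrals of the 3D kernel (1e-5).
2. A CSDA *sampling* oracle re-derives the 3D kernel from the stopping
   model alone — electrons emitted isotropically, straight tracks,
   residual energy $E_0(1-r/\sigma)^{1-\alpha}$ — and matches the closed
   form pointwise. (On spherical shells this construction is
   deterministic: every radial track deposits identically, so the check
   is a discretisation identity rather than a statistical one. Direction
   randomness matters, and is exercised, on Cartesian grids.)
3. The full hybrid chain is compared against a direct-sampling Monte
   Carlo of the fine profile: primary interaction sites drawn from the
   collimator comb over the finite field, electron components drawn with
   the event weights, straight isotropic tracks binned at 5 µm. Both
   routes share the coarse Monte Carlo doses, so the comparison isolates
   the electron model. The PVDR of the two routes is compared at 10 and
   20 mm depth in the scaled-down benchmark below.

## What the fixtures emulate — and what they do not

The phantom generators reproduce the geometries the hybrid method is
meant for: a homogeneous 160 mm water cube, a layered "head" (4 mm water
skin, 6 mm bone shell, water interior, a 10 mm bone cube with one corner
at the phantom centre, extending into the +x/+y/+z octant — the octant is
our choice, the corner placement is the defining feature), and a
synthetic head CT (ellipsoidal soft-tissue interior with smooth HU noise,
a closed bone shell, air outside). The synthetic CT is a topological
stand-in, not anatomy: no sinuses, no density gradients in bone, no
table/couch. Passing tests on these fixtures demonstrates correct
physics coupling (attenuation contrast, range scaling, scatter tracking
at interfaces), not clinical accuracy on real CTs. Real-patient use would
additionally need a validated HU calibration and a measured beam
spectrum.

Problem sizes in the tests and the acceptance benchmark are deliberately
desk-scale: a 40 mm cube with 1 mm voxels, 2×2 mm fields, 10⁵–10⁶ photon
histories and 10⁶ oracle primaries. These sizes keep every statistical
tolerance honest (first-collision kerma to 2%, sampler means within 3
standard errors, PVDR comparison under its 5% band) while the whole suite
runs in minutes.

## Known limitations

* Free-electron Compton (no binding/Doppler), no fluorescence, no
  bremsstrahlung, no polarisation, parallel beams only.
* Mean-p Compton electrons and no range straggling in the kernels: the
  penumbra a few tens of µm outside a slit is the least accurate region.
* Sub-voxel anatomy (e.g. lung alveoli) is invisible to any method on a
  CT grid; the voxel-homogeneity assumption is structural.
* The parameterised photoelectric/Rayleigh tables are few-percent
  accurate; applications needing sub-percent cross sections should swap
  in compilation tables via the JSON material interface.
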