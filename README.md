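# mrtdose

Hybrid Monte Carlo–convolution dose calculation for microbeam radiation
therapy (MRT).

MRT irradiates tissue with arrays of ~50 µm wide planar X-ray beamlets
spaced a few hundred micrometres apart, producing extremely high peak
doses separated by low-dose valleys. Computing such dose distributions is
hard: the dose pattern lives on the micrometre scale, while photons
scatter over centimetres. Pure Monte Carlo simulation at micrometre
resolution needs enormous numbers of histories; pure kernel convolution
is fast but mishandles scattered-photon transport near material
interfaces — exactly where the clinically critical valley dose lives.

`mrtdose` implements the hybrid approach for researchers in medical
physics:

1. **Photon-only Monte Carlo on the CT voxel grid.** Photons undergo
   photoelectric absorption, Compton scattering (free-electron
   Klein–Nishina) and Rayleigh scattering; secondary electrons are killed
   at creation and their energy E₀ is deposited locally. The energy
   transferred at each history's *first* interaction is scored as primary
   dose `D_P`, all later interactions as scatter dose `D_S`. Free paths
   use Woodcock (delta) tracking, which is exact in heterogeneous voxel
   geometries.
2. **Per-voxel analytic electron transport.** Within a voxel the fine
   dose is reconstructed as

   ```
   D(r) = D_S(r) + D_P(r) · (K_el(r) ∗ ν(r))
   ```

   where ν is the collimator fluence comb (unit mean) and K_el the
   electron dose kernel. Under a power-law stopping approximation
   S ∝ E^(−α/(1−α)) with α = 0.415, the kernel has the closed form

   ```
   K_el^3D(r) = E₀(1−α) / (4π σ ρ r²) · (1 − r/σ)^(−α),   r ∈ [0, σ]
   ```

   with σ the electron CSDA range (43 µm at 50 keV in water, scaling as
   E^(1/(1−α)) and 1/ρ). Planar and pencil collimators use the 1D and 2D
   kernels obtained by integrating out the longitudinal coordinates.
   Polychromatic beams combine per-line kernels weighted by the
   photoelectric and Compton coefficients, with Compton electrons at the
   mean Klein–Nishina transfer energy p·E.

The scatter dose enters as a homogeneous bath per voxel, so material
interfaces are handled by the Monte Carlo stage, and the micrometre
pattern by the kernels — each method doing what it is good at.

The package also provides phantom generators (water cube, layered head
phantom with a bone insert, a synthetic head CT stand-in), Hounsfield-unit
conversion, PVDR (peak-to-valley dose ratio) and DVH analysis, cross-fired
field assembly, MetaImage I/O, and an independent direct-sampling
electron-track oracle used for validation.

## Worked example

A 100 keV planar microbeam field (50 µm slits, 400 µm pitch, 2×2 mm) on a
40 mm water cube with 1 mm voxels:

```r
library(mrtdose)

ph   <- water_cube(side_mm = 40, voxel_mm = 1)
beam <- beam_config("+z", square_field(2), collimator("planar", 50, 400),
                    mono_spectrum(100), emission_pixel_mm = 0.05)

cubes <- run_transport(ph, beam, n_histories = 2e5, seed = 1)
cubes
#> <dose_cube_pair> 40 x 40 x 40 voxels, 2e+05 histories
#>   energy: emitted 2e+07 keV = primary 1.48e+06 + scatter 5.42e+05 + escaped 1.8e+07 (closure 0.0e+00)

grid <- reconstruct_field(cubes, beam, ph,
                          roi_mm = list(lo = c(18, 19, 8), hi = c(22, 21, 22)))
grid
#> <micro_dose_grid> 800 x 2 x 28 bins, spacing 5/1000/500 um

profile <- extract_profile(grid, depth_mm = 10)
pvdr(profile, beam$collimator)
#> $peak
#> [1] 6.543626e-11
#> $valley
#> [1] 2.003307e-13
#> $pvdr
#> [1] 326.6412
#> $n_slits
#> [1] 3
```

Every voxel's energy books balance exactly (`closure 0`), and the
reconstructed peak dose of 6.5e-11 Gy/history against a valley of
2.0e-13 Gy/history gives a PVDR of ~330 at 10 mm depth — the scatter bath
plus a small primary electron tail is all that reaches the valley at this
field size. PVDR falls with depth as the scatter bath builds up.

A thin CLI over the same functions is installed at
`inst/scripts/mrthybrid` (subcommands `phantom`, `transport`, `kernel`,
`microdose`, `run`, `analyze`; one YAML config; provenance JSON per run).

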