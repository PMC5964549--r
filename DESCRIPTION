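Package: mrtdose
Title: Hybrid Monte Carlo-Convolution Dose Calculation for Microbeam
    Radiation Therapy
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Dose calculation for microbeam radiation therapy (MRT) using a
    hybrid algorithm: a coarse-grid photon-only Monte Carlo transport that
    scores primary and scattered photon energy transfer per CT voxel,
    followed by a per-voxel convolution of the primary dose with analytic
    electron scatter kernels to reconstruct the micrometre-scale peak and
    valley dose pattern.  Includes material and photon cross-section models
    (photoelectric, Klein-Nishina Compton, Rayleigh), a parallel-beam source
    with polygonal fields and microbeam collimators, analytic 1D/2D/3D
    electron dose kernels with polychromatic weighting, phantom generators,
    peak-to-valley dose ratio (PVDR) and dose-volume histogram analysis, and
    MetaImage volume input/output.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    pracma,
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
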