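Package: holophase
Title: Phase Retrieval for Propagation-Based X-ray Phase-Contrast Imaging
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation, pre-processing and phase retrieval for near-field
    (propagation-based) X-ray phase-contrast imaging and holo-tomography.
    Provides unit-less Fresnel propagation on pixel grids, a synthetic
    phantom and hologram generator, flat-/dark-field correction, outlier
    removal and subpixel registration of multi-distance hologram series,
    single-step phase retrieval in the direct-contrast regime (Paganin
    single-material, modified Bronnikov, Bronnikov-aided correction),
    linear and iterative phase retrieval in the holographic regime
    (contrast-transfer-function inversion with low/high frequency
    regularization and optional constraints, two-plane transport-of-intensity
    retrieval, alternating projections, relaxed averaged alternating
    reflections, modified hybrid input-output), spectral diagnostics
    (radial power spectra, Fresnel-number estimation from fringe spacing),
    sinogram ring removal and a minimal parallel-beam Radon/filtered
    back-projection pair, together with float32 TIFF/raw stack input/output
    and a small command-line front end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    tiff,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
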