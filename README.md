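# holophase

Phase retrieval for propagation-based (near-field) X-ray phase-contrast
imaging, in R.

In propagation-based imaging a (partially) coherent X-ray beam traverses a
weakly absorbing specimen, and free-space propagation over a distance `z`
converts the invisible phase shift into measurable intensity fringes — a
hologram. The phase image must then be reconstructed numerically. This
package implements the complete 2D workflow at desk scale: simulation of
holograms, pre-processing and alignment of multi-distance series, phase
retrieval in both imaging regimes, spectral diagnostics, and sinogram
post-processing for tomography.

All algorithms work in **pixel units**, parameterized by the unit-less
per-pixel Fresnel number

```
F = p_eff^2 / (lambda * z_eff),
```

with the cone-beam geometry of magnification `M = (z01 + z12)/z01` mapped to
its parallel-beam equivalent (`z_eff = z12/M`, `p_eff = pixel/M`) by the
Fresnel scaling theorem (`effective_geometry()`). Large `F` (~0.1) is the
direct-contrast regime (edge enhancement); small `F` (~0.005) is the
holographic regime (many fringes, strong low-frequency transfer).

## What is implemented

| Stage | Functions |
|---|---|
| Fresnel optics | `freq_grid`, `freq_normsq`, `chirp_phase`, `fresnel_propagate`, `effective_geometry` |
| Simulation | `make_phantom`, `make_wavefield`, `simulate_hologram`, `simulate_series` |
| Pre-processing | `flat_dark_correct`, `remove_outliers`, `pad_crop_window`, `register_translation`, `apply_shift`, `align_series` |
| Direct-contrast retrieval | `phaserec_smo` (Paganin single-material), `phaserec_mba` (modified Bronnikov), `phaserec_bac` (Bronnikov-aided correction) |
| Holographic retrieval | `phaserec_ctf` (+ `phaserec_ctf_constrained`), `phaserec_holotie`, iterative `iterate_ap` / `iterate_raar` / `iterate_mhio` with `project_data` / `project_object` |
| Diagnostics | `radial_psd`, `estimate_fresnel` |
| Tomography post-processing | `remove_stripes`, `radon_forward`, `radon_backproject`, `fbp` |
| I/O and CLI | `read_stack`, `write_stack` (float32 TIFF / raw), `resolve_config`, `cli_main` |

The forward model is the projection approximation: the object imprints
`psi = exp(-mu/2 + i*phi)` (phase `phi <= 0` for a refractive-index
decrement, absorption `mu >= 0`), and the detector records
`I = |D_F psi|^2` with `D_F` the Fresnel propagator, a Fourier multiplier
`exp(-i pi |xi|^2 / F)`. Weak objects obey the contrast-transfer-function
(CTF) linearization

```
FFT[I - 1](xi) = 2 sin(chi) FFT[phi] - cos(chi) FFT[mu],   chi = pi |xi|^2 / F,
```

which anchors the package's sign conventions and most of its single-step
inversions; the iterative solvers need no weak-object assumption and accept
support, phase-range, pure-phase and single-material constraints.

## Worked example

Simulate a drifting four-distance holographic series of a cell-like phantom
(0.5 rad peak phase, beta/delta = 0.05, 500 photons/pixel), align it, and
reconstruct the phase by regularized CTF inversion:

```r
library(holophase)

ph <- make_phantom(c(256, 256), kind = "cell_like", max_phase = 0.5,
                   beta_delta = 0.05, seed = 42)
stack <- simulate_series(ph$phi, ph$mu,
                         fresnel_numbers = c(5.0e-3, 4.6e-3, 4.2e-3, 3.9e-3),
                         photons = 500,
                         drifts = rbind(c(0, 0), c(1.4, -0.8),
                                        c(-0.6, 2.1), c(2.2, 0.5)),
                         seed = 43)
stack
#> Hologram stack: 4 image(s) of 256 x 256
#>   Fresnel numbers: 0.005, 0.0046, 0.0042, 0.0039

aligned <- align_series(stack, reference = 1, upsample = 100)
round(aligned$shifts, 2)        # recovered drifts, px (truth above)
#>       [,1]  [,2]
#> [1,]  0.00  0.00
#> [2,]  1.40 -0.84
#> [3,] -0.58  1.98
#> [4,]  2.16  0.40

phi_ctf <- phaserec_ctf(aligned$stack, lim1 = 5e-4, lim2 = 1e-2,
                        beta_delta = 0.05)
cor(as.vector(phi_ctf), as.vector(ph$phi))
#> 0.985
nrmse(phi_ctf, ph$phi, zero_mean = TRUE)
#> 0.171

estimate_fresnel(stack$images[[1]], f_range = c(1e-3, 5e-2))$fresnel
#> 0.00477    # true value 0.005
```

The recovered drifts match the injected ones to better than 0.15 px at this
photon budget; the phase map correlates at 0.985 with the ground truth (the
residual 17% RMS error is dominated by shot noise and the regularized
low-frequency band); and the Fresnel number is recovered from the fringe
spacing of a single noisy hologram to within 5%. On noiseless data the same
pipeline reaches sub-0.05 px alignment and <1% phase error (see
`tests/testthat/`).

A command-line front end wraps the same functions
(`simulate`, `preprocess`, `retrieve`, `diagnose`, `tomo`):

```sh
Rscript inst/scripts/holophase.R simulate --size 256 --fresnel 0.005 \
    --photons 50 --seed 1 --out stack.tif
Rscript inst/scripts/holophase.R retrieve --in stack.tif --method ctf \
    --fresnel 0.005 --lim1 5e-4 --lim2 1e-2 --out phase.tif
```

Every run writes a JSON sidecar with the fully resolved parameters and seed,
and fixed-seed runs are bit-reproducible.

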