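---
title: "Models, conventions and design choices in holophase"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models, conventions and design choices in holophase}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(holophase)
```

This vignette is the package's own account of the science it implements:
the forward model and its approximations, the exact conventions every
function relies on, what the synthetic-data generator does and does not
emulate, and the numerical design choices that were genuinely open.

## Forward model and conventions

A thin specimen illuminated by a coherent plane wave imprints, under the
projection approximation, the complex transmission

$$\psi(\mathbf r) = \exp\!\big(-\mu(\mathbf r)/2 + i\,\varphi(\mathbf r)\big),$$

where $\varphi \le 0$ is the projected phase shift (the refractive index is
$n = 1-\delta+i\beta$ with $\delta > 0$, so the phase is *advanced*;
$\varphi = -k\int\delta\,dz$) and $\mu = 2k\int\beta\,dz \ge 0$ the
projected absorption. After free-space propagation the detector records
$I = |D_F\,\psi|^2$.

Everything is computed in pixel units. The single geometry parameter is the
unit-less per-pixel Fresnel number $F = p_{\mathrm{eff}}^2/(\lambda
z_{\mathrm{eff}})$; cone-beam recordings are first mapped to parallel beam
by the Fresnel scaling theorem (`effective_geometry()`), and all physical
units stop at that boundary. The propagator is the Fourier multiplier

$$\hat D_F(\xi) = e^{-i\chi(\xi)}, \qquad \chi = \pi |\xi|^2 / F,$$

with frequencies $\xi$ in cycles/pixel on the unshifted FFT grid
(`freq_grid()`, `freq_normsq()`). The sign of the exponent together with
the sign of $\varphi$ is *the* global convention: it is fixed by requiring
that a weak object reproduce the contrast-transfer-function linearization

$$\widehat{I-1}(\xi) = 2\sin\chi\;\hat\varphi(\xi) - \cos\chi\;\hat\mu(\xi),$$

which a dedicated test verifies against the full nonlinear simulation
(0.3% relative $L^2$ at 0.01 rad). Any other combination of signs breaks
that identity, so the convention is pinned by an oracle rather than by
documentation alone.

Propagation uses replicate padding to twice the field of view by default
(suppressing periodic wrap-around of fringes) and offers `pad = "none"`,
which makes the operator exactly unitary — energy conservation and the
round trip then hold to $10^{-12}$, and a direct $O(N^4)$ discrete
convolution sum reproduces the FFT path to $10^{-8}$ on a $32^2$ field.

## The synthetic-data generator

`make_phantom()` builds compact objects — smoothed random discs
(`"balls"`), band-limited blobs (`"smooth_blobs"`), or a cell-like body
with nucleus and inclusions (`"cell_like"`) — with an exact peak phase
`max_phase`, single-material absorption `mu = 2 c |phi|` with
`c = beta_delta`, Gaussian edge width `smoothness` (default 2 px; tests of
the direct-contrast regime use 1 px so that spectral content survives out
to the first CTF zero at $|\xi| = \sqrt F \approx 0.32$), and a taper to
exactly zero at the border. Shot noise is Poisson on the flat-normalized
intensity at a mean of `photons` counts per pixel, applied after
propagation. Per-image lateral drifts are applied by Fourier subpixel
shift.

What the generator does **not** emulate: detector point-spread functions,
source blur and partial coherence, polychromaticity, flat-field structure
beyond the low-order fields used in the pre-processing tests, and
non-circulant boundaries (real detectors truncate the wavefield; the
simulator's periodic/padded boundaries are close but not identical).
Passing round-trip tests therefore demonstrate correctness of the inverse
operators under their own forward model, not robustness to every
real-beamline imperfection — the latter is what the regularization
parameters are for.

## Direct-contrast methods

* `phaserec_smo()` — the Paganin single-material filter
  $M = \mathrm{IFFT}[\widehat I/(1+\chi/c)]$, $\mu = -\log M$,
  $\varphi = -\mu/2c$. Exact in the transport-of-intensity limit for
  single-material objects; behaves as a low pass.
* `phaserec_mba()` — pure-phase transport-of-intensity inversion
  $\hat\varphi = \widehat{I-1}/(2\chi+\alpha)$, zero-mean phase (the DC
  component is unconstrained by the data). **Convention:** our $\alpha$
  regularizes against $2\chi(\xi)$, not against $|\xi|^2$ as in some
  historic codes — the same nominal value means different strengths in the
  two conventions. With the single-material coupling enforced, the
  absorption term acts exactly like $\alpha = 2c$, which is the basis of
  the SMO/MBA agreement test.
* `phaserec_bac()` — divides the hologram by $1-\gamma\nabla^2\varphi_B$
  with $\varphi_B$ from MBA, returning a corrected object-plane intensity.
  The Laplacian is the Fourier multiplier $-4\pi^2|\xi|^2$, deliberately
  the same discretization as $\chi$. The physically matched strength is
  $\gamma \approx 1/(2\pi F)$; the conservative default $2\times10^{-3}$
  under-corrects and should be tuned. In the tests, "sharpness" is the
  contrast-normalized edge slope (max profile derivative divided by the
  local step amplitude): BAC reduces the overshoot by >95% while keeping
  that slope within 3% of the raw hologram's, whereas SMO blurs it to
  ~70%.

## Holographic methods

`phaserec_ctf()` inverts the single-material CTF model over $J$ distances
with kernel $K_j = 2(\sin\chi_j + c\cos\chi_j)$ and a **two-limit
Tikhonov** term $\alpha(\xi)$ that interpolates from $2\,\mathrm{lim1}$
below the first CTF maximum to $2\,\mathrm{lim2}$ above it. The transition
is a Gaussian-CDF step in $\log_{10}|\xi|$ centered at
$|\xi| = \sqrt{\max_j F_j/2}$ with a width of 0.4 decades — a smooth,
$C^\infty$ filter; the exact functional form is this package's choice.
With `lim1 = lim2 = 0` the inversion is the exact pseudo-inverse on
frequencies where $\sum_j K_j^2 > 0$ (machine-precision test). The
constrained variant alternates Tikhonov solves of the data residual with
projections onto support/phase-range constraints and reduces to the plain
inversion for all-pass constraints and one sweep.

`phaserec_holotie()` solves the transport-of-intensity equation from two
closely spaced distances: finite-difference axial derivative in the
unit-less coordinate $\tilde z = 1/F$, then
$\varphi = -P_\alpha[\nabla\!\cdot\!((1/I_{\mathrm{mid}})\nabla
P_\alpha[2\pi\,\partial_{\tilde z} I])]$ with the regularized inverse
Laplacian $P_\alpha = 1/(4\pi^2|\xi|^2+\alpha)$. The prefactor $2\pi$ is
*derived* from the small-$\chi$ CTF limit in these units (not calibrated):
$\partial_{\tilde z}\widehat I = 2\pi|\xi|^2\hat\varphi\cos\chi$, so the
chain of two Poisson solves returns $\varphi$ exactly as $\alpha\to 0$,
$\chi\to 0$. No object constraints are required, which is the method's
niche (extended objects, neither pure-phase nor single-material).

The iterative solvers act on the object-plane field with the **magnitude
projector** $P_M$ (propagate, impose $\sqrt I$, propagate back; averaged
over distances — exact and idempotent for $J = 1$, averaged and slightly
non-idempotent for $J > 1$) and the **object projector** $P_O$ (amplitude
rule, phase clamp, empty beam outside the support; exactly idempotent):

* `iterate_ap()` — $\psi \leftarrow P_O P_M \psi$;
* `iterate_raar()` — $\psi \leftarrow \tfrac{\beta_n}{2}(R_O R_M +
  \mathrm{Id})\psi + (1-\beta_n) P_M\psi$ with reflectors $R = 2P -
  \mathrm{Id}$ and $\beta_n$ ramping smoothly from `beta_start = 1` to
  `beta_max = 0.5` around `beta_switch = n_iter/2`
  ($\beta_n = \beta_{\max} + (\beta_0-\beta_{\max})
  e^{-(n/n_s)^3}$) — defaults found stable on the synthetic suite, always
  overridable;
* `iterate_mhio()` — the near-field hybrid input–output: the constrained
  magnitude projection is accepted inside the support, while outside the
  feedback $\psi \leftarrow \psi - \beta_{\mathrm{HIO}}(P_M\psi - 1)$
  relaxes the field towards the *empty beam* $\psi = 1$ (the natural
  background of flat-normalized holography, in contrast to the far-field
  variant's zero). The exterior relaxation is diffusive — deviations decay
  monotonically at a rate set by the feedback and the spectral mixing of
  the propagator, not geometrically per iteration.

Phases are returned as principal values of $\arg\psi$; there is no phase
unwrapping, so objects beyond $\pi$ rad need range constraints. All
solvers record a normalized RMS amplitude residual per iteration and abort
when it exceeds ten times its initial value.

On the reference task (0.5 rad supported pure-phase phantom, $F = 5\times
10^{-3}$, $128^2$, 150 iterations) all three reach correlation $\ge 0.999$
with the truth, noiselessly. At 50 photons/pixel the same task has a
*physical* per-pixel phase-noise floor of $\sigma_\varphi \approx
1/\sqrt{2N_{\mathrm{ph}}} \approx 0.07$ rad — about half of the truth's
RMS inside the support — so pixelwise relative errors of order tens of
percent are the attainable optimum for any unbiased solver at these
settings; the measured values (~0.3–0.5) are reported as-is by the
acceptance script.

## Diagnostics

`radial_psd()` averages $|\mathrm{FFT}[I-\bar I]|^2$ over linear $|\xi|$
annuli (DC excluded; Parseval holds per test). `estimate_fresnel()`
exploits the phase-CTF zeros at $|\xi| = \sqrt{mF}$: dips are measured as
log-PSD depth below a smoothed spectral envelope (making the score
invariant to the envelope and to affine intensity rescaling), the band is
limited to frequencies above the high-frequency noise floor, and each
candidate $F$ is scored by the $1/m$-weighted mean depth at its first four
predicted zeros combined with the *weakest* of those dips — a single deep
speckle dip cannot carry a wrong candidate. A log-spaced grid search is
refined locally; estimates clamped to the search boundary carry a warning.
Strong shot noise fills the dips with the flat noise floor, so reliable
estimation needs clean (or averaged) holograms; on noiseless data the
estimator is within 2% in the holographic regime and 5% in the
direct-contrast regime, where only one or two zeros are available.

## Pre-processing

Registration follows the upsampled cross-correlation approach: FFT
correlation for the integer peak, then a localized matrix-multiply DFT at
spacing $1/\mathrm{upsample}$ — 0.02 px accuracy at upsample 100 on clean
data. `align_series()` prepares each pair by mean subtraction (otherwise
the common window pattern dominates the correlation), Tukey windowing
($\alpha = 0.2$), and a *CTF-consistency filter*: only frequencies where
the two distances' phase CTFs have a positive product are correlated,
low-passed at $\sigma_\xi = 0.1$ cycles/px against shot noise. Without
this filter, cross-distance correlation is biased by the differing
contrast transfer (up to several px for widely spaced distances).
Magnification differences between distances are assumed already removed
via known geometry; rotation search is out of scope.

Outlier removal replaces pixels deviating from their window median by more
than `nsigma` robust standard deviations (MAD $\times$ 1.4826, with a
small floor for locally constant data). Fractional shifts put the
unpaired Nyquist bin of even axes at its nearest-integer phase so that
`apply_shift()` stays real and exactly invertible.

## Tomography post-processing

The internal parallel-beam pair is deliberately minimal: pixel-driven
splatting with linear weights (mass-conserving for objects inside the
inscribed circle) and its *exact* adjoint as back-projector. FBP uses the
band-limited spatial-domain ramp kernel ($h_0 = 1/4$, $h_k =
-1/(\pi k)^2$ odd $k$) — frequency-sampling $|f|$ loses the DC response
and biased reconstructions by several percent — with Shepp-Logan and Hann
apodizations, rows zero-padded to twice the detector. A smooth-edged disc
reconstructs with 4% NRMSE from 180 angles.

Ring removal addresses the sinogram signature of detector-gain defects:
stripes constant along angle. `"mean-subtraction"` fits the angular
column-mean profile with a robust loess (symmetric family, span =
`strength`/width, default a tenth of the detector), flags columns whose
deviation is significant (3 robust SD, and at least 2% of the typical
signal — so a stripe-free sinogram is returned bit-identical up to that
threshold and the operation is idempotent in practice), and measures each
flagged column's offset against a spline through the exact clean-column
means. On the reference workflow (10 isolated defective columns, 10%
offsets) this removes >96% of the stripe RMS and >92% of the ring-band RMS
in the reconstruction. The assumptions are explicit: defects sharp and
(mostly) isolated in the detector coordinate, object profile smooth on the
loess span — heavily clustered defects or near-singular projection
shoulders degrade the separation, as does any perfectly
rotationally-symmetric object component, which is mathematically
indistinguishable from detector gain. `"fourier-damping"` approximates the
wavelet-Fourier family by a Gaussian notch at near-zero angular frequency,
applied only above $\sigma_{f_t} = 0.12$ cycles/px in the detector
direction; it is gentler, parameter-light, and preferred when defects are
dense rather than isolated.

## Numerical choices and degenerate inputs

* Intensity floors before logarithms/divisions: $10^{-6}$, with clamped
  pixels counted on the result (`n_clamped`).
* MBA/HoloTIE set the unconstrained DC phase to zero; comparisons against
  truth should be zero-mean (`nrmse(..., zero_mean = TRUE)`).
* `phaserec_ctf` with zero regularization zeroes frequencies where all
  kernels vanish instead of dividing by zero; an all-zero kernel set with
  zero regularization is an error.
* Constant images are rejected where an operation is undefined on them
  (registration, PSD).
* Contact-plane geometry ($z_{12} = 0$) yields `fresnel = NA` with a
  warning rather than infinity.
* All randomness (phantoms, noise) is seeded; identical seeds give
  bit-identical outputs, including through the command line.

## Problem sizes

The test suite and the acceptance script run on $32^2$–$512^2$ images,
$J \le 4$ distances and 150 iterations for the iterative solvers — sizes
chosen so the full suite completes in about a minute while every algorithm
operates in its intended regime (fringe counts, CTF-zero counts and noise
levels match the regimes discussed above). All figures quoted in this
vignette are computed by the tests or by `scripts/acceptance.R`, not
transcribed from elsewhere.

## Known limitations

Paraxial, fully coherent, monochromatic model only; no partial-coherence
or detector PSF forward models. No phase unwrapping. No rotation or
magnification registration. Translation alignment across widely spaced
distances degrades with strong noise (the CTF-consistency filter mitigates
but cannot remove this). Fresnel-number estimation needs visible CTF
zeros: very smooth objects or strong noise defeat it. The tomography pair
is a testing-scale reference implementation, not a competitor to dedicated
tomography engines.
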