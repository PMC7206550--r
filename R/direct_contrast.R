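# Single-step phase retrieval in the direct-contrast regime.
#
# All filters are built from the chirp chi(xi) = pi |xi|^2 / F so that the
# spectral discretization is identical across methods (including the BAC
# Laplacian, a Fourier multiplier rather than a finite-difference stencil).

#' Paganin single-material phase retrieval (SMO)
#'
#' Inverts the single-material transport-of-intensity model by the Paganin
#' low-pass filter: `M = IFFT[ FFT[I] / (1 + chi(xi)/beta_delta) ]` is
#' interpreted as the object-plane attenuation `exp(-mu)`, from which
#' `mu = -log(M)` and `phi = -mu / (2 beta_delta)` (non-positive phase under
#' the package sign convention). Filtered intensities below `floor` are
#' clamped before the logarithm and counted in `attr(, "n_clamped")`.
#'
#' @param hologram flat-normalized intensity image.
#' @param fresnel per-pixel Fresnel number (> 0).
#' @param beta_delta single-material ratio `beta/delta` (> 0).
#' @param floor positive clamp applied before taking the logarithm.
#' @return phase map in radians (attribute `n_clamped` counts guarded
#'   pixels).
#' @export
phaserec_smo <- function(hologram, fresnel, beta_delta, floor = 1e-6) {
  assert_image(hologram)
  assert_fresnel(fresnel)
  if (!(beta_delta > 0)) stop("SMO requires beta_delta > 0")
  filt <- 1 + chirp_phase(dim(hologram), fresnel) / beta_delta
  m <- Re(ifft2(fft2(hologram) / filt))
  nclamp <- sum(m < floor)
  if (nclamp > 0) warning(sprintf("%d filtered pixels clamped at %g", nclamp, floor))
  mu <- -log(pmax(m, floor))
  out <- -mu / (2 * beta_delta)
  attr(out, "n_clamped") <- nclamp
  out
}

#' Modified Bronnikov phase retrieval (MBA)
#'
#' Pure-phase transport-of-intensity inversion with Tikhonov
#' regularization: `phi_hat(xi) = FFT[I - 1] / (2 chi(xi) + alpha)` and
#' `phi_hat(0) = 0` (zero-mean phase; the DC component is unconstrained by
#' the transport-of-intensity equation). Consistent with the small-`chi`
#' limit of the contrast transfer function, `sin(chi) ~ chi`. The
#' regularization `alpha` is defined against `2 chi(xi)`; it dominates the
#' filter at low spatial frequencies `|xi|^2 < alpha F / (2 pi)`.
#'
#' @param hologram flat-normalized intensity image.
#' @param fresnel per-pixel Fresnel number (> 0).
#' @param alpha Tikhonov regularization parameter (> 0).
#' @return zero-mean phase map in radians.
#' @export
phaserec_mba <- function(hologram, fresnel, alpha) {
  assert_image(hologram)
  assert_fresnel(fresnel)
  if (!(alpha > 0)) stop("MBA requires alpha > 0 (the DC term is otherwise divided by zero)")
  den <- 2 * chirp_phase(dim(hologram), fresnel) + alpha
  phihat <- fft2(hologram - 1) / den
  phihat[1, 1] <- 0
  Re(ifft2(phihat))
}

#' Bronnikov-aided correction (BAC)
#'
#' Uses a modified-Bronnikov phase estimate `phi_B` to undo the
#' edge-enhancement modulation of a direct-contrast hologram:
#' `I_corr = I / (1 - gamma * Laplacian(phi_B))`, returning the corrected
#' object-plane intensity (not a phase). The Laplacian is the Fourier
#' multiplier `-4 pi^2 |xi|^2`, matching the spectral discretization of
#' `chi`. The physically matched correction strength is
#' `gamma ~ 1 / (2 pi F)`; smaller values under-correct. Non-positive
#' denominators are clamped at `floor` and counted in `attr(, "n_clamped")`.
#'
#' @param hologram flat-normalized intensity image.
#' @param fresnel per-pixel Fresnel number (> 0).
#' @param alpha regularization for the internal MBA step.
#' @param gamma correction strength (>= 0; 0 returns the input).
#' @param floor positive clamp for the correction denominator.
#' @return corrected intensity image (>= 0), attribute `n_clamped`.
#' @export
phaserec_bac <- function(hologram, fresnel, alpha, gamma = 2e-3, floor = 1e-6) {
  assert_image(hologram)
  if (gamma < 0) stop("gamma must be >= 0")
  if (gamma == 0) {
    out <- hologram
    attr(out, "n_clamped") <- 0L
    return(out)
  }
  phib <- phaserec_mba(hologram, fresnel, alpha)
  lap <- Re(ifft2(fft2(phib) * (-4 * pi^2 * freq_normsq(dim(hologram)))))
  den <- 1 - gamma * lap
  nclamp <- sum(den <= floor)
  if (nclamp > 0) warning(sprintf("%d correction denominators clamped at %g", nclamp, floor))
  out <- pmax(hologram / pmax(den, floor), 0)
  attr(out, "n_clamped") <- nclamp
  out
}
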