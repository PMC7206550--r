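# Linear (single-step) phase retrieval in the holographic regime.

# Two-limit regularization alpha(xi): interpolates from 2*lim1 at low
# spatial frequencies to 2*lim2 at high ones with a smooth (Gaussian-CDF)
# step in log10 |xi|, centered where the chirp of the largest Fresnel
# number (the smallest chi at fixed xi) reaches its first CTF maximum
# chi = pi/2, i.e. at |xi| = sqrt(max(F)/2). Width ~ one decade.
ctf_alpha <- function(shape, fresnel_numbers, lim1, lim2, width = 0.4) {
  xi <- sqrt(freq_normsq(shape))
  xc <- sqrt(max(fresnel_numbers) / 2)
  w <- matrix(0, shape[1], shape[2])
  nz <- xi > 0
  w[nz] <- stats::pnorm((log10(xi[nz]) - log10(xc)) / width)
  2 * (lim1 + (lim2 - lim1) * w)
}

#' Linearized contrast-transfer-function forward model
#'
#' Predicts the hologram spectra of a weak object under the CTF model:
#' `I_hat_j(xi) = delta_DC + 2 sin(chi_j) phi_hat(xi) - cos(chi_j) mu_hat(xi)`
#' with `chi_j = pi |xi|^2 / F_j`. Spectra are returned in FFT order and in
#' the unnormalized-FFT scale of [stats::fft()] (the DC spike of the unit
#' background equals the pixel count).
#'
#' @param phi,mu weak-object phase/absorption images.
#' @param fresnel_numbers vector of per-distance Fresnel numbers.
#' @return list of complex spectrum matrices, one per distance. The
#'   corresponding real-space intensities are `Re(ifft2(spectrum))`.
#' @export
ctf_forward <- function(phi, mu = 0 * phi, fresnel_numbers) {
  assert_image(phi); assert_image(mu)
  if (!all(dim(phi) == dim(mu))) stop("phi and mu must share one shape")
  assert_fresnel(fresnel_numbers)
  phih <- fft2(phi)
  muh <- fft2(mu)
  dc <- length(phi)   # FFT of the unit background
  lapply(fresnel_numbers, function(f) {
    chi <- chirp_phase(dim(phi), f)
    s <- 2 * sin(chi) * phih - cos(chi) * muh
    s[1, 1] <- s[1, 1] + dc
    s
  })
}

#' CTF phase retrieval (multi-distance Tikhonov inversion)
#'
#' Least-squares inversion of the single-material CTF model over J
#' distances. With kernel `K_j(xi) = 2 (sin chi_j + beta_delta * cos chi_j)`
#' the phase spectrum is
#' `phi_hat = sum_j K_j FFT[I_j - 1] / (sum_j K_j^2 + alpha(xi))`,
#' where `alpha(xi)` interpolates smoothly from `2*lim1` below the first CTF
#' maximum to `2*lim2` above it (see Details). This keeps the filter finite
#' at CTF zeros while leaving low, well-transferred frequencies nearly
#' untouched. With `lim1 = lim2 = 0` frequencies where the kernel vanishes
#' are set to zero (exact pseudo-inverse on the rest).
#'
#' @param stack an aligned [hologram_stack()].
#' @param lim1 low-frequency regularization (>= 0).
#' @param lim2 high-frequency regularization (>= 0).
#' @param beta_delta single-material ratio `beta/delta` (0 = pure phase).
#' @return phase map in radians.
#' @export
phaserec_ctf <- function(stack, lim1 = 5e-4, lim2 = 1e-2, beta_delta = 0) {
  stopifnot(inherits(stack, "hologram_stack"))
  if (lim1 < 0 || lim2 < 0) stop("lim1 and lim2 must be >= 0")
  if (beta_delta < 0) stop("beta_delta must be >= 0")
  sh <- dim(stack$images[[1]])
  num <- matrix(0i, sh[1], sh[2])
  den <- matrix(0, sh[1], sh[2])
  for (j in seq_along(stack$images)) {
    chi <- chirp_phase(sh, stack$fresnel_numbers[j])
    k <- 2 * (sin(chi) + beta_delta * cos(chi))
    num <- num + k * fft2(stack$images[[j]] - 1)
    den <- den + k^2
  }
  if (lim1 == 0 && lim2 == 0) {
    if (all(den == 0)) stop("all-zero CTF kernels with zero regularization")
    phihat <- matrix(0i, sh[1], sh[2])
    nz <- den > 0
    phihat[nz] <- num[nz] / den[nz]
  } else {
    phihat <- num / (den + ctf_alpha(sh, stack$fresnel_numbers, lim1, lim2))
  }
  Re(ifft2(phihat))
}

# Project a real phase map onto support / range constraints (real-space
# counterpart of project_object for linear methods).
project_phase <- function(phi, constraints) {
  if (is.null(constraints)) return(phi)
  stopifnot(inherits(constraints, "constraint_set"))
  out <- pmin(pmax(phi, constraints$phase_min), constraints$phase_max)
  if (!is.null(constraints$support)) out[!constraints$support] <- 0
  out
}

#' Constrained (iteratively refined) CTF phase retrieval
#'
#' Alternates the Tikhonov CTF inversion of the current data residual with
#' projection of the phase onto the object constraints (support and/or
#' phase range): starting from `phi = 0`, each sweep sets
#' `phi <- P[phi] + CTF^-1( data - CTF(P[phi]) )`. With all-pass
#' constraints and one iteration this reproduces [phaserec_ctf()] exactly.
#' Iteration stops after `n_iter` sweeps or when the update norm falls
#' below `tol` times the phase norm.
#'
#' @inheritParams phaserec_ctf
#' @param constraints a [constraint_set()] (support mask and/or phase
#'   range); amplitude rules are ignored here (the model is single-material
#'   by construction).
#' @param n_iter maximum number of refinement sweeps.
#' @param tol relative update-norm stopping tolerance.
#' @return phase map in radians with attribute `n_sweeps`.
#' @export
phaserec_ctf_constrained <- function(stack, lim1 = 5e-4, lim2 = 1e-2,
                                     beta_delta = 0, constraints = NULL,
                                     n_iter = 20L, tol = 1e-6) {
  stopifnot(inherits(stack, "hologram_stack"))
  if (!is.null(constraints) && !is.null(constraints$support) &&
      !any(constraints$support)) stop("empty support")
  sh <- dim(stack$images[[1]])
  j <- length(stack$images)
  chis <- lapply(stack$fresnel_numbers, function(f) chirp_phase(sh, f))
  ks <- lapply(chis, function(chi) 2 * (sin(chi) + beta_delta * cos(chi)))
  data_h <- lapply(stack$images, function(im) fft2(im - 1))
  den <- Reduce(`+`, lapply(ks, function(k) k^2)) +
    ctf_alpha(sh, stack$fresnel_numbers, lim1, lim2)
  phi <- matrix(0, sh[1], sh[2])
  sweeps <- 0L
  for (it in seq_len(n_iter)) {
    phi_p <- project_phase(phi, constraints)
    phip_h <- fft2(phi_p)
    num <- matrix(0i, sh[1], sh[2])
    for (jj in seq_len(j)) num <- num + ks[[jj]] * (data_h[[jj]] - ks[[jj]] * phip_h)
    upd <- Re(ifft2(num / den))
    phi <- phi_p + upd
    sweeps <- it
    if (sqrt(sum(upd^2)) < tol * max(sqrt(sum(phi^2)), 1e-30)) break
  }
  if (!is.null(constraints)) phi <- project_phase(phi, constraints)
  attr(phi, "n_sweeps") <- sweeps
  phi
}

#' Two-plane transport-of-intensity phase retrieval (HoloTIE)
#'
#' Recovers the phase at the mid-plane between two closely spaced
#' measurement planes from the finite-difference axial intensity derivative,
#' by two regularized Fourier Poisson inversions with an intermediate
#' division by the mid-plane intensity:
#' `phi = -P_a[ div( (1/I_mid) grad P_a[ 2*pi * dI/dz ] ) ]`,
#' where `P_a` is the Fourier multiplier `1 / (4 pi^2 |xi|^2 + alpha)`, the
#' unit-less propagation coordinate is `z = 1/F`, and the prefactor `2*pi`
#' is fixed by agreement with the small-`chi` limit of the CTF model. No
#' object constraints are required, which makes the method suitable for
#' extended objects that are neither pure-phase nor single-material.
#'
#' @param i_a,i_b intensity images at Fresnel numbers `f_a`, `f_b`.
#' @param f_a,f_b the two (distinct, closely spaced) Fresnel numbers.
#' @param alpha Poisson-solver regularization (> 0).
#' @return zero-mean mid-plane phase map in radians.
#' @export
phaserec_holotie <- function(i_a, i_b, f_a, f_b, alpha = 1e-3) {
  assert_image(i_a); assert_image(i_b)
  if (!all(dim(i_a) == dim(i_b))) stop("images must share one shape")
  assert_fresnel(c(f_a, f_b))
  if (f_a == f_b) stop("the two Fresnel numbers must differ")
  if (max(f_a, f_b) / min(f_a, f_b) > 1.5)
    warning("planes are far apart (unit-less distance ratio > 1.5); the finite-difference derivative degrades")
  if (any(i_a <= 0) || any(i_b <= 0)) stop("intensities must be > 0")
  if (!(alpha > 0)) stop("alpha must be > 0")
  sh <- dim(i_a)
  g <- freq_grid(sh)
  dy <- 2i * pi * matrix(g[[1]], sh[1], sh[2])          # d/dy multiplier
  dx <- 2i * pi * matrix(g[[2]], sh[1], sh[2], byrow = TRUE)  # d/dx
  pa <- 1 / (4 * pi^2 * freq_normsq(sh) + alpha)
  didz <- (i_b - i_a) / (1 / f_b - 1 / f_a)
  i_mid <- (i_a + i_b) / 2
  u_h <- 2 * pi * fft2(didz) * pa
  gy <- Re(ifft2(u_h * dy)) / i_mid
  gx <- Re(ifft2(u_h * dx)) / i_mid
  div_h <- fft2(gy) * dy + fft2(gx) * dx
  phih <- -div_h * pa
  phih[1, 1] <- 0
  Re(ifft2(phih))
}
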