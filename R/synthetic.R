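# Synthetic phantoms, wavefields and multi-distance hologram stacks.
#
# Sign convention (fixed globally): the object wavefield is
#   psi = exp(-mu/2 + 1i * phi)
# with phase phi <= 0 for a phase-advancing object (phi = -k integral of
# delta) and absorption mu >= 0. Under the forward transfer function
# exp(-1i * chi) this yields the linearized hologram spectrum
#   I_hat = delta_DC + 2 sin(chi) phi_hat - cos(chi) mu_hat,
# which is verified against the full nonlinear simulation by a weak-object
# test (the package's sign-convention oracle).

#' Generate a synthetic phase/absorption phantom
#'
#' Builds a compact 2D object with controllable maximum phase shift and a
#' single-material absorption channel. Three geometries are available:
#' `"balls"` (a few smoothed random discs/ellipses), `"smooth_blobs"`
#' (band-limited random field, tapered to zero at the border) and
#' `"cell_like"` (an elliptical body with a denser nucleus and small
#' organelle-scale inclusions). All are smoothed with a Gaussian edge of
#' width `smoothness` pixels and vanish at the image border.
#'
#' The returned phase is non-positive (`phi = -max_phase * g`, `g` in
#' `[0, 1]`, following the convention `phi = -k` times the projected
#' refractive-index decrement), with `max(|phi|) = max_phase` exactly, and
#' the absorption obeys the single-material coupling
#' `mu = 2 * beta_delta * |phi|`.
#'
#' @param shape image shape, e.g. `c(256, 256)`.
#' @param kind phantom geometry, one of `"balls"`, `"smooth_blobs"`,
#'   `"cell_like"`.
#' @param max_phase maximum absolute phase shift in radians.
#' @param beta_delta ratio `beta/delta` >= 0 coupling absorption to phase
#'   (0 for a pure-phase object).
#' @param smoothness Gaussian edge width in pixels.
#' @param seed integer seed; the same seed reproduces the phantom
#'   bit-identically.
#' @return list with matrices `phi` (radians, <= 0) and `mu` (>= 0).
#' @examples
#' ph <- make_phantom(c(128, 128), max_phase = 0.5, beta_delta = 0.05,
#'                    seed = 1)
#' max(abs(ph$phi))   # 0.5
#' max(ph$mu)         # 0.05
#' @export
make_phantom <- function(shape, kind = c("balls", "smooth_blobs", "cell_like"),
                         max_phase = 0.5, beta_delta = 0.05,
                         smoothness = 2, seed = 1) {
  kind <- match.arg(kind)
  if (!is.finite(max_phase) || max_phase < 0) stop("max_phase must be finite and >= 0")
  if (beta_delta < 0) stop("beta_delta must be >= 0")
  shape <- as.integer(shape)
  nr <- shape[1]; nc <- shape[2]
  g <- with_seed(seed, {
    yy <- matrix(seq_len(nr), nr, nc)
    xx <- matrix(seq_len(nc), nr, nc, byrow = TRUE)
    base <- switch(kind,
      balls = {
        k <- sample(3:6, 1)
        acc <- matrix(0, nr, nc)
        for (i in seq_len(k)) {
          cy <- stats::runif(1, 0.25 * nr, 0.75 * nr)
          cx <- stats::runif(1, 0.25 * nc, 0.75 * nc)
          ry <- stats::runif(1, 0.06, 0.16) * min(nr, nc)
          rx <- ry * stats::runif(1, 0.7, 1.4)
          amp <- stats::runif(1, 0.5, 1)
          acc <- acc + amp * (((yy - cy) / ry)^2 + ((xx - cx) / rx)^2 < 1)
        }
        acc
      },
      smooth_blobs = {
        z <- matrix(stats::rnorm(nr * nc), nr, nc)
        z <- gauss_blur(z, max(smoothness * 4, min(nr, nc) / 16))
        pmax(z - stats::quantile(z, 0.6), 0)
      },
      cell_like = {
        cy <- nr / 2 + stats::runif(1, -0.05, 0.05) * nr
        cx <- nc / 2 + stats::runif(1, -0.05, 0.05) * nc
        ry <- 0.3 * nr; rx <- 0.35 * nc
        body <- 0.5 * (((yy - cy) / ry)^2 + ((xx - cx) / rx)^2 < 1)
        nuc <- 0.8 * (((yy - cy - 0.08 * nr) / (0.12 * nr))^2 +
                        ((xx - cx + 0.05 * nc) / (0.12 * nc))^2 < 1)
        org <- matrix(0, nr, nc)
        for (i in 1:4) {
          oy <- cy + stats::runif(1, -0.18, 0.18) * nr
          ox <- cx + stats::runif(1, -0.2, 0.2) * nc
          r <- stats::runif(1, 0.02, 0.05) * min(nr, nc)
          org <- org + 0.4 * (((yy - oy)^2 + (xx - ox)^2) < r^2)
        }
        body + nuc + org
      })
    base
  })
  g <- gauss_blur(g, smoothness)
  # compact support: taper to exactly zero in the outer 10% margin
  g <- g * tukey2(shape, alpha = 0.2)
  g[g < 0] <- 0
  g[c(1, nr), ] <- 0
  g[, c(1, nc)] <- 0
  mx <- max(g)
  if (mx > 0) g <- g / mx
  phi <- -max_phase * g
  list(phi = phi, mu = 2 * beta_delta * abs(phi))
}

#' Object-plane wavefield from phase and absorption images
#'
#' Forms the complex transmission `psi = exp(-mu/2 + 1i * phi)` behind the
#' sample under the projection approximation. Unit amplitude is the empty
#' beam, so `|psi| <= 1` for non-negative absorption.
#'
#' @param phi phase image in radians.
#' @param mu absorption image (>= 0), `mu = 2 k` times the projected
#'   imaginary refractive index.
#' @return complex matrix of the same shape.
#' @export
make_wavefield <- function(phi, mu = 0 * phi) {
  assert_image(phi); assert_image(mu)
  if (!all(dim(phi) == dim(mu))) stop("phi and mu must have the same shape")
  if (any(mu < 0)) stop("mu must be >= 0")
  exp(-mu / 2 + 1i * phi)
}

#' Simulate a near-field hologram
#'
#' Propagates an object-plane wavefield to the detector at per-pixel Fresnel
#' number `fresnel` and records the intensity `I = |D_F psi|^2`. With finite
#' `photons`, Poisson shot noise at a mean of `photons` counts per pixel in
#' the empty beam is applied to the flat-normalized intensity
#' (`I <- rpois(photons * I) / photons`).
#'
#' @param field complex object-plane wavefield (see [make_wavefield()]).
#' @param fresnel per-pixel Fresnel number (> 0).
#' @param photons mean photon count per pixel, or `Inf` for noiseless data.
#' @param seed integer seed for the shot noise (ignored when noiseless).
#' @param pad padding policy passed to [fresnel_propagate()].
#' @return non-negative intensity matrix with empty-beam mean ~ 1.
#' @export
simulate_hologram <- function(field, fresnel, photons = Inf, seed = NULL,
                              pad = c("replicate", "none")) {
  pad <- match.arg(pad)
  if (!(is.infinite(photons) || photons > 0)) stop("photons must be > 0 or Inf")
  holo <- Mod(fresnel_propagate(field, fresnel, "forward", pad))^2
  if (is.finite(photons)) {
    holo <- with_seed(seed,
      matrix(stats::rpois(length(holo), photons * holo), nrow(holo)) / photons)
  }
  holo
}

#' Multi-distance hologram stack
#'
#' `hologram_stack()` bundles J flat-normalized holograms with their J
#' per-pixel Fresnel numbers, the common input of all multi-distance
#' retrieval algorithms. `simulate_series()` generates such a stack from a
#' phantom: one hologram per Fresnel number, optionally with per-image
#' lateral drifts (applied by Fourier subpixel shift after simulation, as in
#' a defocus series whose sample drifts between distances) and shot noise.
#' The true drifts are attached for testing alignment routines.
#'
#' @param images list of intensity matrices (same shape, non-negative).
#' @param fresnel_numbers numeric vector of per-image Fresnel numbers.
#' @return an object of class `"hologram_stack"`: a list with elements
#'   `images` and `fresnel_numbers`. For `simulate_series` the true applied
#'   drifts are stored in `attr(, "true_drifts")` (J x 2 matrix, dy/dx).
#' @export
hologram_stack <- function(images, fresnel_numbers) {
  if (is.matrix(images)) images <- list(images)
  if (!is.list(images) || length(images) < 1L)
    stop("images must be a non-empty list of matrices")
  sh <- dim(images[[1]])
  for (im in images) {
    assert_image(im)
    if (!all(dim(im) == sh)) stop("all images must share one shape")
  }
  assert_fresnel(fresnel_numbers)
  if (length(fresnel_numbers) != length(images))
    stop("need one Fresnel number per image")
  structure(list(images = images, fresnel_numbers = as.numeric(fresnel_numbers)),
            class = "hologram_stack")
}

#' @export
print.hologram_stack <- function(x, ...) {
  cat(sprintf("Hologram stack: %d image(s) of %d x %d\n",
              length(x$images), nrow(x$images[[1]]), ncol(x$images[[1]])))
  cat("  Fresnel numbers:", paste(signif(x$fresnel_numbers, 4), collapse = ", "),
      "\n")
  invisible(x)
}

#' @rdname hologram_stack
#' @param phi,mu phantom phase/absorption images (see [make_phantom()]).
#' @param fresnel_numbers numeric vector of per-image Fresnel numbers.
#' @param photons mean photon count per pixel or `Inf`.
#' @param drifts J x 2 matrix of (dy, dx) drifts in pixels, or `NULL` for a
#'   perfectly aligned series.
#' @param seed integer seed controlling the shot noise of the whole series.
#' @param pad padding policy for the propagation.
#' @export
simulate_series <- function(phi, mu, fresnel_numbers, photons = Inf,
                            drifts = NULL, seed = NULL,
                            pad = c("replicate", "none")) {
  pad <- match.arg(pad)
  j <- length(fresnel_numbers)
  if (is.null(drifts)) drifts <- matrix(0, j, 2)
  drifts <- as.matrix(drifts)
  if (nrow(drifts) != j || ncol(drifts) != 2)
    stop("drifts must be a J x 2 matrix matching fresnel_numbers")
  if (any(!is.finite(drifts))) stop("drifts must be finite")
  field <- make_wavefield(phi, mu)
  images <- with_seed(seed, lapply(seq_len(j), function(i) {
    holo <- simulate_hologram(field, fresnel_numbers[i], photons,
                              seed = NULL, pad = pad)
    if (any(drifts[i, ] != 0)) holo <- apply_shift(holo, drifts[i, 1], drifts[i, 2])
    holo
  }))
  out <- hologram_stack(images, fresnel_numbers)
  attr(out, "true_drifts") <- drifts
  out
}
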