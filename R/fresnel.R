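#' Fourier frequency grids for image-shaped arrays
#'
#' `freq_grid()` returns, for every axis of `shape`, the sample frequencies of
#' the discrete Fourier transform in cycles/pixel and in FFT (unshifted)
#' order: `0, 1/n, ..., -2/n, -1/n`, with the Nyquist frequency `-1/2` for
#' even `n`. `freq_normsq()` returns the 2D array of squared Euclidean
#' frequency norms `|xi|^2`, the workhorse of every Fourier-space filter in
#' the package.
#'
#' All algorithms in this package operate in pixel units: lengths are in
#' detector pixels and the geometry enters only through the unit-less
#' per-pixel Fresnel number (see [effective_geometry()]).
#'
#' @param shape integer vector of array dimensions (length 1 or 2 for
#'   `freq_grid`; exactly 2 for `freq_normsq`).
#' @return `freq_grid`: a list of numeric vectors, one per axis.
#'   `freq_normsq`: a matrix of dimension `shape` with `|xi|^2` per element;
#'   zero exactly at the DC element `[1, 1]`.
#' @examples
#' freq_grid(4)[[1]]              # 0 0.25 -0.5 -0.25
#' freq_normsq(c(4, 4))[1, 1]     # 0
#' @export
freq_grid <- function(shape) {
  if (any(shape < 1)) stop("all dimensions must be >= 1")
  lapply(as.integer(shape), fftfreq)
}

#' @rdname freq_grid
#' @export
freq_normsq <- function(shape) {
  if (length(shape) != 2L) stop("freq_normsq expects a 2D shape")
  g <- freq_grid(shape)
  outer(g[[1]]^2, g[[2]]^2, `+`)
}

#' Fresnel chirp phase
#'
#' The quadratic phase `chi(xi) = pi |xi|^2 / fresnel` that the Fresnel
#' propagator applies in Fourier space at per-pixel Fresnel number
#' `fresnel`. `chi` is also the argument of the contrast transfer functions:
#' the phase CTF is `sin(chi)` and the absorption CTF is `cos(chi)`, so the
#' first zero of the phase CTF sits at `|xi| = sqrt(fresnel)`.
#'
#' @param shape 2D image shape.
#' @param fresnel per-pixel Fresnel number (> 0).
#' @return matrix of `chi` values, zero at DC, in FFT order.
#' @export
chirp_phase <- function(shape, fresnel) {
  assert_fresnel(fresnel)
  if (length(fresnel) != 1L) stop("'fresnel' must be a single number")
  pi * freq_normsq(shape) / fresnel
}

#' Fresnel propagation of a complex wavefield
#'
#' Propagates a pixel-sampled complex wavefield by multiplication with the
#' Fresnel transfer function `exp(-1i * chi(xi))` in Fourier space (the
#' conjugate kernel for `direction = "backward"`). The global piston phase is
#' dropped (`chi(0) = 0`), so an empty beam propagates to itself.
#'
#' With `pad = "replicate"` (default) the field is replicate-padded to twice
#' its size before the FFT and cropped back afterwards, which suppresses
#' periodic wrap-around of fringes from compact objects. With `pad = "none"`
#' the operator is exactly unitary: total intensity `sum(|psi|^2)` is
#' conserved to numerical precision and
#' `fresnel_propagate(fresnel_propagate(psi, F), F, "backward")`
#' returns `psi` exactly.
#'
#' @param field complex (or numeric) matrix; unit amplitude is the empty beam.
#' @param fresnel per-pixel Fresnel number (> 0).
#' @param direction `"forward"` (towards the detector) or `"backward"`.
#' @param pad `"replicate"` or `"none"`.
#' @return complex matrix of the same shape as `field`.
#' @export
fresnel_propagate <- function(field, fresnel,
                              direction = c("forward", "backward"),
                              pad = c("replicate", "none")) {
  direction <- match.arg(direction)
  pad <- match.arg(pad)
  assert_image(field)
  assert_fresnel(fresnel)
  sh <- dim(field)
  if (any(sh < 2)) stop("field must be at least 2x2")
  if (pad == "replicate") {
    target <- 2L * sh
    fp <- pad_center(Re(field), target, "replicate") +
      1i * pad_center(Im(field), target, "replicate")
  } else {
    target <- sh
    fp <- field
  }
  h <- exp(-1i * chirp_phase(target, fresnel))
  if (direction == "backward") h <- Conj(h)
  out <- ifft2(fft2(fp) * h)
  if (pad == "replicate") out <- crop_center(out, sh)
  out
}

#' Imaging geometry and the Fresnel scaling theorem
#'
#' `fresnel_geometry()` records a cone-beam (point-source) geometry in SI
#' units: source-to-sample distance `z01`, sample-to-detector distance `z12`,
#' detector pixel size and wavelength, all in metres. `effective_geometry()`
#' converts it to the equivalent parallel-beam quantities via the Fresnel
#' scaling theorem: magnification `M = (z01 + z12)/z01`, effective
#' propagation distance `z_eff = z12 / M`, effective (demagnified) pixel
#' `p_eff = pixel_size / M`, and the unit-less per-pixel Fresnel number
#' `F = p_eff^2 / (lambda * z_eff)` that every algorithm in the package
#' consumes.
#'
#' @param z01 source-to-sample distance in metres (> 0; `Inf` for a parallel
#'   beam).
#' @param z12 sample-to-detector distance in metres (>= 0).
#' @param pixel_size detector pixel size in metres (> 0).
#' @param wavelength photon wavelength in metres (> 0).
#' @return `fresnel_geometry`: an object of class `"fresnel_geometry"`.
#'   `effective_geometry`: a list with elements `magnification`, `z_eff`,
#'   `p_eff` and `fresnel`; at `z12 = 0` the Fresnel number is undefined
#'   (contact plane) and returned as `NA` with a warning.
#' @examples
#' g <- fresnel_geometry(z01 = 0.1, z12 = 5, pixel_size = 6.5e-6,
#'                       wavelength = 1e-10)
#' effective_geometry(g)
#' @export
fresnel_geometry <- function(z01, z12, pixel_size, wavelength) {
  if (!(z01 > 0)) stop("z01 must be > 0 (use Inf for a parallel beam)")
  if (!(z12 >= 0) || !is.finite(z12)) stop("z12 must be finite and >= 0")
  if (!(pixel_size > 0) || !(wavelength > 0))
    stop("pixel_size and wavelength must be > 0")
  structure(list(z01 = z01, z12 = z12, pixel_size = pixel_size,
                 wavelength = wavelength),
            class = "fresnel_geometry")
}

#' @rdname fresnel_geometry
#' @param geom a `"fresnel_geometry"` object.
#' @export
effective_geometry <- function(geom) {
  stopifnot(inherits(geom, "fresnel_geometry"))
  m <- if (is.infinite(geom$z01)) 1 else (geom$z01 + geom$z12) / geom$z01
  z_eff <- geom$z12 / m
  p_eff <- geom$pixel_size / m
  if (geom$z12 == 0) {
    warning("z12 = 0: contact plane, Fresnel number undefined")
    fresnel <- NA_real_
  } else {
    fresnel <- p_eff^2 / (geom$wavelength * z_eff)
  }
  list(magnification = m, z_eff = z_eff, p_eff = p_eff, fresnel = fresnel)
}

#' @export
print.fresnel_geometry <- function(x, ...) {
  cat("Fresnel geometry (SI units):\n")
  cat(sprintf("  z01 = %g m, z12 = %g m, pixel = %g m, lambda = %g m\n",
              x$z01, x$z12, x$pixel_size, x$wavelength))
  if (x$z12 > 0) {
    e <- effective_geometry(x)
    cat(sprintf("  M = %.4g, z_eff = %.4g m, p_eff = %.4g m, F = %.4g\n",
                e$magnification, e$z_eff, e$p_eff, e$fresnel))
  }
  invisible(x)
}
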