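# Pre-processing: raw frames -> clean, aligned, flat-normalized holograms.

#' Flat-field and dark-frame correction
#'
#' Computes the flat-normalized hologram `(raw - dark) / (flat - dark)`.
#' Pixels where the denominator is not usefully positive (<= `eps` times the
#' median positive denominator) are set to 1 (empty beam) and counted in
#' `attr(, "n_flagged")`.
#'
#' @param raw raw detector frame.
#' @param flat flat-field frame (illumination without sample).
#' @param dark dark frame (detector offset without beam); scalar 0 allowed.
#' @param eps relative threshold declaring a denominator pixel unusable.
#' @return normalized hologram with attribute `n_flagged`.
#' @export
flat_dark_correct <- function(raw, flat, dark = 0, eps = 1e-6) {
  assert_image(raw); assert_image(flat)
  if (length(dark) == 1L) dark <- matrix(dark, nrow(raw), ncol(raw))
  assert_image(dark)
  if (!all(dim(raw) == dim(flat)) || !all(dim(raw) == dim(dark)))
    stop("raw, flat and dark must share one shape")
  den <- flat - dark
  pos <- den > 0
  if (!any(pos)) stop("flat - dark is nowhere positive")
  bad <- den <= eps * stats::median(den[pos])
  den[bad] <- 1
  out <- (raw - dark) / den
  out[bad] <- 1
  attr(out, "n_flagged") <- sum(bad)
  out
}

# Median (and optionally MAD) over a sliding window, computed from a stack
# of replicate-padded shifted copies. Windows stay small (3..7), so the
# apply() over w^2 values per pixel is affordable.
window_stats <- function(img, window) {
  r <- (window - 1L) %/% 2L
  nr <- nrow(img); nc <- ncol(img)
  ri <- function(k) pmin(pmax(seq_len(nr) + k, 1L), nr)
  ci <- function(k) pmin(pmax(seq_len(nc) + k, 1L), nc)
  stack <- matrix(0, nr * nc, window^2)
  m <- 1L
  for (dy in -r:r) for (dx in -r:r) {
    stack[, m] <- img[ri(dy), ci(dx)]
    m <- m + 1L
  }
  med <- apply(stack, 1L, stats::median)
  mad <- apply(abs(stack - med), 1L, stats::median)
  list(median = matrix(med, nr, nc), mad = matrix(mad, nr, nc))
}

#' Remove hot pixels and outliers by a robust median test
#'
#' Pixels deviating from their `window x window` neighborhood median by more
#' than `nsigma` robust standard deviations (median absolute deviation
#' scaled by 1.4826) are replaced by that median; all other pixels are
#' returned bit-identical. The number of replacements is attached as
#' `attr(, "n_replaced")`.
#'
#' @param img image matrix.
#' @param window odd window size >= 3.
#' @param nsigma detection threshold in robust standard deviations.
#' @return corrected image with attribute `n_replaced`.
#' @export
remove_outliers <- function(img, window = 3L, nsigma = 8) {
  assert_image(img)
  window <- as.integer(window)
  if (window < 3L || window %% 2L == 0L) stop("window must be odd and >= 3")
  ws <- window_stats(img, window)
  sigma <- 1.4826 * ws$mad
  # guard against zero MAD on locally constant data
  floor_ <- 1e-12 + 1e-9 * stats::median(abs(img))
  bad <- abs(img - ws$median) > nsigma * pmax(sigma, floor_)
  out <- img
  out[bad] <- ws$median[bad]
  attr(out, "n_replaced") <- sum(bad)
  out
}

#' Centered padding, cropping and windowing
#'
#' Pads or crops an image to `target` (per axis, centered placement) with
#' boundary handling `"replicate"`, `"symmetric"` or `"constant"`, and
#' optionally multiplies the result by a separable Tukey window whose taper
#' acts only on the outer `alpha/2` transition band of each axis.
#'
#' @param img image matrix.
#' @param target integer target shape (length 2). Defaults to the input
#'   shape (no resizing).
#' @param mode boundary fill for padding.
#' @param value fill value for `mode = "constant"`.
#' @param window `"none"` or `"tukey"`.
#' @param alpha Tukey taper fraction in (0, 1].
#' @return resized (and windowed) image.
#' @export
pad_crop_window <- function(img, target = dim(img),
                            mode = c("replicate", "symmetric", "constant"),
                            value = 0, window = c("none", "tukey"),
                            alpha = 0.2) {
  mode <- match.arg(mode)
  window <- match.arg(window)
  assert_image(img)
  target <- as.integer(target)
  if (length(target) != 2L || any(target < 1L)) stop("invalid target shape")
  out <- img
  if (any(target > dim(img)))
    out <- pad_center(out, pmax(target, dim(img)), mode, value)
  if (any(target < dim(out)))
    out <- crop_center(out, pmin(target, dim(out)))
  if (window == "tukey") out <- out * tukey2(dim(out), alpha)
  out
}

#' Subpixel translation registration by upsampled cross-correlation
#'
#' Estimates the translation that maps image `a` onto image `b` (i.e. `b` is
#' `a` shifted by the returned `(dy, dx)`), using FFT cross-correlation for
#' the integer-pixel estimate and a localized matrix-multiply discrete
#' Fourier transform around the coarse peak to refine it to `1/upsample`
#' pixels. Applying the negated shift to `b` (see [apply_shift()]) best
#' aligns it to `a`.
#'
#' @param a,b image matrices of identical shape, non-constant.
#' @param upsample integer precision factor (1 = integer-pixel).
#' @return list with elements `shift` (numeric `(dy, dx)` in pixels),
#'   `error` (normalized RMS residual in `[0, 1]`) and `upsample`.
#' @export
register_translation <- function(a, b, upsample = 1L) {
  assert_image(a); assert_image(b)
  if (!all(dim(a) == dim(b))) stop("images must share one shape")
  if (stats::sd(a) == 0 || stats::sd(b) == 0)
    stop("constant image: no correlation peak")
  upsample <- max(1L, as.integer(upsample))
  nr <- nrow(a); nc <- ncol(a)
  fa <- fft2(a); fb <- fft2(b)
  cross <- fb * Conj(fa)
  cc <- ifft2(cross)           # cc(s) = sum_x b(x) conj(a(x - s))
  pk <- which.max(Mod(cc))
  py <- (pk - 1L) %% nr
  px <- (pk - 1L) %/% nr
  if (py > nr / 2) py <- py - nr
  if (px > nc / 2) px <- px - nc
  shift <- c(py, px)
  peak <- cc[pk]
  if (upsample > 1L) {
    # refine on a (1.5 px)^2 neighborhood sampled at 1/upsample
    half <- ceiling(1.5 * upsample) / upsample
    uy <- shift[1] + seq(-half, half, by = 1 / upsample)
    ux <- shift[2] + seq(-half, half, by = 1 / upsample)
    fy <- fftfreq(nr); fx <- fftfreq(nc)
    er <- exp(2i * pi * outer(uy, fy))          # |uy| x nr
    ec <- exp(2i * pi * outer(ux, fx))          # |ux| x nc
    ccu <- (er %*% cross %*% t(ec)) / length(a)
    pk2 <- which.max(Mod(ccu))
    iy <- (pk2 - 1L) %% length(uy) + 1L
    ix <- (pk2 - 1L) %/% length(uy) + 1L
    shift <- c(uy[iy], ux[ix])
    peak <- ccu[pk2]
  }
  rho2 <- min(1, Mod(peak)^2 / (sum(a^2) * sum(b^2)))
  list(shift = shift, error = sqrt(1 - rho2), upsample = upsample)
}

#' Fourier subpixel shift
#'
#' Circularly shifts image content by `(dy, dx)` pixels (possibly
#' fractional) via a linear phase ramp in Fourier space. Exact inverse pair:
#' `apply_shift(apply_shift(x, dy, dx), -dy, -dx)` returns `x` up to
#' round-off.
#'
#' @param img image matrix.
#' @param dy,dx shift in pixels along rows/columns (content moves towards
#'   larger indices for positive values).
#' @return shifted image.
#' @export
apply_shift <- function(img, dy, dx) {
  assert_image(img)
  if (!is.finite(dy) || !is.finite(dx)) stop("shift must be finite")
  phase_vec <- function(n, s) {
    p <- exp(-2i * pi * fftfreq(n) * s)
    # the unpaired Nyquist bin of even-sized axes gets the nearest integer
    # part of the shift, keeping the output real and the operator an exact
    # inverse pair
    if (n %% 2L == 0L) p[n / 2L + 1L] <- (-1)^round(s)
    p
  }
  ramp <- outer(phase_vec(nrow(img), dy), phase_vec(ncol(img), dx))
  Re(ifft2(fft2(img) * ramp))
}

#' Align a multi-distance hologram series
#'
#' Registers every image of a stack to a reference image by
#' [register_translation()] and shifts it into alignment. Before
#' correlation each pair is mean-subtracted, windowed (Tukey,
#' `alpha = 0.2`) to suppress edge ringing, and band-filtered to the
#' frequencies both distances transfer with consistent contrast sign (the
#' positive part of the product of their phase CTFs, low-passed against
#' shot noise); this removes the bias that differing contrast transfer
#' otherwise imprints on cross-distance correlation. The shifts reported
#' (and undone) refer to the original frames.
#'
#' @param stack a [hologram_stack()].
#' @param reference index of the reference image.
#' @param upsample registration precision factor.
#' @return list with elements `stack` (aligned [hologram_stack()]), `shifts`
#'   (J x 2 matrix of detected (dy, dx)) and `errors` (registration
#'   residuals).
#' @export
align_series <- function(stack, reference = 1L, upsample = 100L) {
  stopifnot(inherits(stack, "hologram_stack"))
  j <- length(stack$images)
  if (j < 2L) stop("alignment needs at least 2 images")
  reference <- as.integer(reference)
  if (reference < 1L || reference > j) stop("invalid reference index")
  sh <- dim(stack$images[[1]])
  win <- tukey2(sh, 0.2)
  # subtract the flat background before windowing: otherwise the common
  # window pattern itself dominates the correlation
  prep <- function(x) (x - mean(x)) * win
  # correlate only co-transferred content: weight by the product of the two
  # phase CTFs where it is positive (consistent contrast sign), with a
  # Gaussian low-pass against the noise-dominated band
  pair_filter <- function(fa, fb) {
    sqrt(pmax(sin(chirp_phase(sh, fa)) * sin(chirp_phase(sh, fb)), 0)) *
      exp(-freq_normsq(sh) / (2 * 0.1^2))
  }
  shifts <- matrix(0, j, 2)
  errors <- numeric(j)
  aligned <- stack$images
  for (i in seq_len(j)) {
    if (i == reference) next
    flt <- pair_filter(stack$fresnel_numbers[reference],
                       stack$fresnel_numbers[i])
    a <- Re(ifft2(fft2(prep(stack$images[[reference]])) * flt))
    b <- Re(ifft2(fft2(prep(stack$images[[i]])) * flt))
    reg <- tryCatch(
      register_translation(a, b, upsample),
      error = function(e) stop(sprintf("registration failed for image %d: %s",
                                       i, conditionMessage(e))))
    shifts[i, ] <- reg$shift
    errors[i] <- reg$error
    aligned[[i]] <- apply_shift(stack$images[[i]], -reg$shift[1], -reg$shift[2])
  }
  list(stack = hologram_stack(aligned, stack$fresnel_numbers),
       shifts = shifts, errors = errors)
}
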