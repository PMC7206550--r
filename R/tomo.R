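# Sinogram post-processing and a minimal parallel-beam Radon/FBP pair.
#
# The forward projector is pixel-driven (each pixel splits its value
# linearly between the two nearest detector bins), so mass is conserved
# exactly for objects inside the inscribed circle and the unfiltered
# back-projector is the exact adjoint (gather with the same weights).

#' Sinogram container
#'
#' Rows are projection angles (strictly increasing, in `[0, pi)`), columns
#' are detector pixels.
#'
#' @param values matrix of projection values (rows = angles).
#' @param angles numeric vector of projection angles in radians.
#' @return an object of class `"sinogram"`.
#' @export
sinogram <- function(values, angles) {
  assert_image(values)
  if (nrow(values) != length(angles)) stop("rows must equal length(angles)")
  if (any(diff(angles) <= 0)) stop("angles must be strictly increasing")
  if (any(angles < 0) || any(angles >= pi)) stop("angles must lie in [0, pi)")
  structure(list(values = values, angles = as.numeric(angles)),
            class = "sinogram")
}

#' @export
print.sinogram <- function(x, ...) {
  cat(sprintf("Sinogram: %d angles x %d detector pixels, theta in [%.3f, %.3f]\n",
              nrow(x$values), ncol(x$values), min(x$angles), max(x$angles)))
  invisible(x)
}

# Linear pixel->bin splitting for one angle; returns indices and weights.
proj_geometry <- function(n, theta) {
  ctr <- (n + 1) / 2
  y <- matrix(seq_len(n) - ctr, n, n)
  x <- t(y)
  t <- x * cos(theta) + y * sin(theta) + ctr
  i0 <- floor(t)
  w <- t - i0
  list(i0 = as.vector(i0), w = as.vector(w))
}

#' Parallel-beam Radon transform
#'
#' Line-integral projections of a square image by pixel-driven splatting
#' with linear interpolation: each pixel adds its value to the two detector
#' bins nearest to `t = x cos(theta) + y sin(theta)`. Every projection row
#' sums to the total image mass (exactly, for objects inside the inscribed
#' circle of the detector).
#'
#' @param image square numeric matrix.
#' @param angles projection angles in radians, in `[0, pi)`.
#' @return a [sinogram()] with `length(angles)` rows and `ncol(image)`
#'   detector pixels.
#' @export
radon_forward <- function(image, angles) {
  assert_image(image)
  if (nrow(image) != ncol(image)) stop("image must be square")
  if (length(angles) < 1L) stop("empty angle list")
  n <- nrow(image)
  v <- as.vector(image)
  lv <- factor(integer(0), levels = seq_len(n))
  sino <- matrix(0, length(angles), n)
  for (a in seq_along(angles)) {
    pg <- proj_geometry(n, angles[a])
    idx <- c(pg$i0, pg$i0 + 1L)
    wts <- c((1 - pg$w) * v, pg$w * v)
    keep <- idx >= 1L & idx <= n
    s <- rowsum(wts[keep], factor(idx[keep], levels = seq_len(n)))
    sino[a, ] <- s[, 1]
  }
  sinogram(sino, angles)
}

#' Unfiltered back-projection (adjoint of the Radon transform)
#'
#' Gathers sinogram values back into image space with the same linear
#' weights as [radon_forward()], making the pair exactly adjoint:
#' `sum(radon(x) * y) == sum(x * backproject(y))`.
#'
#' @param sino a [sinogram()].
#' @return square image matrix (`n = ncol(sino$values)`).
#' @export
radon_backproject <- function(sino) {
  stopifnot(inherits(sino, "sinogram"))
  n <- ncol(sino$values)
  acc <- numeric(n * n)
  for (a in seq_along(sino$angles)) {
    pg <- proj_geometry(n, sino$angles[a])
    row <- sino$values[a, ]
    v0 <- ifelse(pg$i0 >= 1L & pg$i0 <= n, row[pmin(pmax(pg$i0, 1L), n)], 0)
    v1 <- ifelse(pg$i0 + 1L >= 1L & pg$i0 + 1L <= n,
                 row[pmin(pmax(pg$i0 + 1L, 1L), n)], 0)
    acc <- acc + (1 - pg$w) * v0 + pg$w * v1
  }
  matrix(acc, n, n)
}

#' Filtered back-projection
#'
#' Standard frequency-domain ramp filtering of each projection row
#' (zero-padded to twice the detector length) followed by unfiltered
#' back-projection scaled by the angular step `pi / n_angles`. Filters:
#' `"ram-lak"` (`|f|`), `"shepp-logan"` (`|f| sinc(f)`), `"hann"`
#' (`|f| (1 + cos(2 pi f)) / 2`), with `f` in cycles/pixel up to the
#' Nyquist 0.5. Linear in the sinogram.
#'
#' @param sino a [sinogram()] with at least 8 angles for meaningful output.
#' @param filter filter name.
#' @return reconstructed square image.
#' @export
fbp <- function(sino, filter = c("ram-lak", "shepp-logan", "hann")) {
  filter <- match.arg(filter)
  stopifnot(inherits(sino, "sinogram"))
  n <- ncol(sino$values)
  np <- 2L * n
  # band-limited ramp from its spatial kernel (h[0] = 1/4, h[odd k] =
  # -1/(pi k)^2), which keeps the correct DC response that plain
  # frequency sampling of |f| loses
  k <- c(0:(np / 2), -(np / 2 - 1):-1)
  hk <- ifelse(k == 0, 0.25, ifelse(k %% 2L != 0L, -1 / (pi * k)^2, 0))
  h <- Re(stats::fft(hk))
  f <- fftfreq(np)
  h <- switch(filter,
    "ram-lak" = h,
    "shepp-logan" = h * ifelse(f == 0, 1, sin(pi * f) / (pi * f)),
    "hann" = h * (1 + cos(2 * pi * f)) / 2)
  filtered <- matrix(0, nrow(sino$values), n)
  for (a in seq_len(nrow(sino$values))) {
    p <- c(sino$values[a, ], rep(0, np - n))
    q <- Re(stats::fft(stats::fft(p) * h, inverse = TRUE)) / np
    filtered[a, ] <- q[seq_len(n)]
  }
  dtheta <- pi / length(sino$angles)
  dtheta * radon_backproject(sinogram(filtered, sino$angles))
}

# 1D Gaussian smoothing with reflected boundaries.
smooth1 <- function(x, sigma) {
  if (sigma <= 0) return(x)
  r <- ceiling(3 * sigma)
  k <- stats::dnorm(-r:r, sd = sigma)
  k <- k / sum(k)
  xp <- c(rev(x[seq_len(r)]), x, rev(x[length(x) - seq_len(r) + 1L]))
  as.numeric(stats::filter(xp, k, sides = 2))[r + seq_along(x)]
}

#' Remove stripe (ring) artifacts from a sinogram
#'
#' Stripes constant along the angular axis of a sinogram reconstruct to
#' concentric rings; both methods suppress exactly that component.
#'
#' `"mean-subtraction"`: the angular mean of each detector column is
#' compared with its neighborhood-smoothed version, a robust local
#' regression (`loess`, symmetric family) over windows of `strength`
#' columns that follows the smooth object profile while ignoring the
#' outlying columns; the deviation - the detector-gain signature - is
#' subtracted from the column. Assumes gain defects are sharp in the
#' detector coordinate while the object's angular-mean profile is smooth
#' on the `strength` scale.
#'
#' `"fourier-damping"`: the 2D spectrum of the sinogram is attenuated by a
#' Gaussian notch at near-zero angular frequencies, applied only at high
#' detector frequencies so that the smooth bulk of the object (which also
#' lives near angular DC but at low detector frequency) is preserved;
#' `strength` scales the angular notch width.
#'
#' A stripe-free sinogram is changed by less than ~1% in L2 norm.
#'
#' @param sino a [sinogram()] with >= 2 angles.
#' @param method `"mean-subtraction"` or `"fourier-damping"`.
#' @param strength method-specific strength: smoothing window in detector
#'   pixels (mean-subtraction, default a tenth of the detector width) or
#'   angular notch scale (fourier-damping, default 2).
#' @return corrected [sinogram()].
#' @export
remove_stripes <- function(sino, method = c("mean-subtraction", "fourier-damping"),
                           strength = NULL) {
  method <- match.arg(method)
  stopifnot(inherits(sino, "sinogram"))
  v <- sino$values
  if (nrow(v) < 2L) stop("need at least 2 angles")
  out <- switch(method,
    "mean-subtraction" = {
      if (is.null(strength)) strength <- ncol(v) / 10
      m <- colMeans(v)
      x <- seq_along(m)
      # symmetric-family loess downweights outlying columns; the
      # pseudoinverse fallback it occasionally warns about is benign here
      fit <- suppressWarnings(stats::loess(
        m ~ x, span = min(1, strength / length(m)), degree = 2,
        family = "symmetric",
        control = stats::loess.control(iterations = 6)))
      d0 <- m - stats::fitted(fit)
      # flag columns whose deviation is significant against the robust
      # scatter of all deviations and against the signal scale (2% of the
      # typical angular mean); clean columns stay bit-identical and
      # re-application is a near no-op
      mad <- stats::median(abs(d0 - stats::median(d0)))
      thr <- max(3 * 1.4826 * mad, 0.02 * stats::median(abs(m)))
      bad <- abs(d0 - stats::median(d0)) > thr
      d <- numeric(length(m))
      if (any(bad) && sum(!bad) > 8) {
        # offsets of the flagged columns, measured against a spline
        # through the exact clean-column means: interpolation error is only
        # the profile curvature across the (narrow) flagged gaps
        d[bad] <- m[bad] - stats::spline(x[!bad], m[!bad], xout = x[bad],
                                         method = "natural")$y
      }
      sweep(v, 2L, d)
    },
    "fourier-damping" = {
      if (is.null(strength)) strength <- 2
      na <- nrow(v); nd <- ncol(v)
      f_ang <- matrix(fftfreq(na), na, nd)
      f_det <- matrix(fftfreq(nd), na, nd, byrow = TRUE)
      sig_a <- strength / na
      sig_d <- 0.12
      notch <- exp(-f_ang^2 / (2 * sig_a^2)) * (1 - exp(-f_det^2 / (2 * sig_d^2)))
      Re(ifft2(fft2(v) * (1 - notch)))
    })
  sinogram(out, sino$angles)
}
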