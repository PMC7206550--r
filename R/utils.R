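# Internal numerical helpers shared across modules.

# DFT sample frequencies in cycles/pixel, FFT (unshifted) order.
fftfreq <- function(n) {
  if (length(n) != 1L || !is.finite(n) || n < 1)
    stop("dimension must be a positive integer")
  n <- as.integer(n)
  neg <- if (n >= 2L) -(floor(n / 2):1) else integer(0)
  c(0:floor((n - 1) / 2), neg) / n
}

fft2 <- function(x) stats::fft(x)

ifft2 <- function(x) stats::fft(x, inverse = TRUE) / length(x)

# Evaluate `code` under a temporary RNG seed, restoring global RNG state.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

#' Normalized root-mean-square error
#'
#' `nrmse(x, ref)` is `||x - ref|| / ||ref||` over all pixels. With
#' `zero_mean = TRUE` both images have their mean removed first, which is the
#' appropriate comparison for phase maps whose global offset is not
#' constrained by the data (the hologram is insensitive to a piston phase).
#'
#' @param x,ref numeric arrays of identical shape.
#' @param zero_mean subtract each image's mean before comparing.
#' @return a single non-negative number.
#' @export
nrmse <- function(x, ref, zero_mean = FALSE) {
  stopifnot(length(x) == length(ref))
  if (zero_mean) {
    x <- x - mean(x)
    ref <- ref - mean(ref)
  }
  sqrt(sum((x - ref)^2) / sum(ref^2))
}

assert_image <- function(x, name = deparse(substitute(x))) {
  if (!is.matrix(x) || !(is.numeric(x) || is.complex(x)))
    stop(sprintf("'%s' must be a numeric or complex matrix", name))
  if (any(!is.finite(x))) stop(sprintf("'%s' contains non-finite values", name))
  invisible(x)
}

assert_fresnel <- function(fresnel) {
  if (!is.numeric(fresnel) || any(!is.finite(fresnel)) || any(fresnel <= 0))
    stop("Fresnel number(s) must be finite and > 0")
  invisible(fresnel)
}

# Index map for centered padding: position 1..target maps to a source index
# (possibly out of range before boundary handling).
pad_offset <- function(n, target) floor((target - n) / 2)

map_indices <- function(n, target, mode) {
  src <- seq_len(target) - pad_offset(n, target)
  switch(mode,
    replicate = pmin(pmax(src, 1L), n),
    symmetric = {
      # reflect without repeating the edge sample: period 2n-2 (n > 1)
      if (n == 1L) rep(1L, target)
      else {
        p <- (src - 1L) %% (2L * n - 2L)
        ifelse(p < n, p + 1L, 2L * n - 1L - p)
      }
    },
    constant = ifelse(src >= 1L & src <= n, src, NA_integer_),
    stop("unknown padding mode: ", mode)
  )
}

pad_center <- function(img, target, mode = "replicate", value = 0) {
  ri <- map_indices(nrow(img), target[1], mode)
  ci <- map_indices(ncol(img), target[2], mode)
  out <- img[ifelse(is.na(ri), 1L, ri), ifelse(is.na(ci), 1L, ci), drop = FALSE]
  if (mode == "constant") {
    out[is.na(ri), ] <- value
    out[, is.na(ci)] <- value
  }
  out
}

crop_center <- function(img, target) {
  r0 <- pad_offset(target[1], nrow(img))
  c0 <- pad_offset(target[2], ncol(img))
  img[r0 + seq_len(target[1]), c0 + seq_len(target[2]), drop = FALSE]
}

# One-dimensional Tukey (tapered cosine) window.
tukey1 <- function(n, alpha = 0.2) {
  if (n == 1L) return(1)
  t <- seq(0, 1, length.out = n)
  w <- rep(1, n)
  if (alpha > 0) {
    a <- alpha / 2
    lo <- t < a
    hi <- t > 1 - a
    w[lo] <- 0.5 * (1 + cos(pi * (t[lo] / a - 1)))
    w[hi] <- 0.5 * (1 + cos(pi * ((t[hi] - 1) / a + 1)))
  }
  w
}

tukey2 <- function(shape, alpha = 0.2) {
  outer(tukey1(shape[1], alpha), tukey1(shape[2], alpha))
}

# Gaussian low-pass via Fourier multiplier exp(-2 pi^2 sigma^2 |xi|^2)
# (transfer function of a continuous Gaussian of std sigma pixels).
gauss_blur <- function(img, sigma) {
  if (sigma <= 0) return(img)
  h <- exp(-2 * pi^2 * sigma^2 * freq_normsq(dim(img)))
  Re(ifft2(fft2(img) * h))
}
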