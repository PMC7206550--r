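# Spectral diagnostics: radial power spectra and Fresnel-number checks.

#' Radially averaged power spectral density
#'
#' Averages `|FFT[img - mean(img)]|^2` over annuli of constant `|xi|`
#' (cycles/pixel). Bins are linear in `|xi|` from 0 to the Nyquist corner
#' `~0.707`; the DC element is excluded by the mean removal and by binning
#' from `|xi| > 0`. Empty bins are returned as `NA` and flagged.
#'
#' @param img image matrix.
#' @param nbins number of radial bins (default: half the smaller image
#'   dimension).
#' @return list with `xi` (bin centers, ascending), `psd` (mean power per
#'   bin, `NA` where empty), `counts` (pixels per bin) and `empty` (logical
#'   flags).
#' @export
radial_psd <- function(img, nbins = min(dim(img)) %/% 2L) {
  assert_image(img)
  nbins <- as.integer(nbins)
  if (nbins < 2L) stop("nbins must be >= 2")
  if (stats::sd(img) == 0) stop("degenerate (constant) image")
  p <- Mod(fft2(img - mean(img)))^2
  xi <- sqrt(freq_normsq(dim(img)))
  ximax <- max(xi)
  edges <- seq(0, ximax, length.out = nbins + 1L)
  idx <- pmin(findInterval(xi, edges, rightmost.closed = TRUE), nbins)
  keep <- xi > 0
  sums <- rowsum(p[keep], idx[keep])
  counts <- rowsum(rep(1, sum(keep)), idx[keep])
  psd <- rep(NA_real_, nbins)
  cnt <- rep(0, nbins)
  at <- as.integer(rownames(sums))
  psd[at] <- sums / counts
  cnt[at] <- counts
  list(xi = (edges[-1L] + edges[-(nbins + 1L)]) / 2,
       psd = psd, counts = cnt, empty = cnt == 0)
}

#' Estimate the Fresnel number from hologram fringes
#'
#' The phase CTF `sin(chi)` vanishes at `|xi| = sqrt(m * F)`, `m = 1, 2,
#' ...`, which imprints minima on the radial power spectrum of a (weakly
#' absorbing) hologram. The estimator measures dip depth of the log-PSD
#' below its smoothed envelope (so the score is robust to the spectral
#' envelope and to overall intensity rescaling `I -> a*I + b`), scores each
#' candidate `F` by the 1/m-weighted depth at its first few predicted
#' zeros combined with the weakest of those dips, searches a log-spaced
#' grid spanning `f_range` and refines the best candidate on a finer local
#' grid. Reliable spectra need clean data; with strong shot noise the dips
#' fill up with the flat noise floor and the search degrades.
#'
#' @param hologram intensity image showing interference fringes.
#' @param f_range positive interval `c(min, max)` to search.
#' @param nbins radial PSD resolution.
#' @param n_grid size of the coarse search grid.
#' @return list with `fresnel` (the estimate), `minima` (the matched
#'   `|xi|` positions), `n_zeros` (how many fell inside the usable band)
#'   and `boundary` (TRUE, with a warning, when the search clamped to an
#'   endpoint of `f_range`).
#' @export
estimate_fresnel <- function(hologram, f_range, nbins = min(dim(hologram)) %/% 2L,
                             n_grid = 400L) {
  assert_image(hologram)
  if (length(f_range) != 2L || any(f_range <= 0) || f_range[1] >= f_range[2])
    stop("f_range must be a positive interval c(min, max)")
  rp <- radial_psd(hologram, nbins)
  ok <- !rp$empty & rp$psd > 0
  if (sum(ok) < 8L) stop("no usable PSD band: cannot detect minima")
  # CTF-zero dips measured against the smooth spectral envelope: detrend
  # the log-PSD with a wide moving smooth so the score does not reward
  # candidates whose zeros merely fall where the envelope is low, and
  # restrict the band to frequencies where the envelope is clearly above
  # the high-frequency noise/harmonics floor.
  xi_ok <- rp$xi[ok]
  lp <- log(rp$psd[ok])
  trend <- smooth1(lp, max(4, length(lp) / 20))
  dip <- function(x) stats::approx(xi_ok, trend - lp, x, rule = 2)$y
  floor_est <- stats::median(rp$psd[ok][xi_ok > 0.55])
  above <- which(exp(trend) > 5 * floor_est)
  hi <- if (length(above)) min(0.45, xi_ok[max(above)]) else 0.45
  lo <- max(min(xi_ok), 0.025)
  # score: the first zero must lie in the band; depth of the first
  # max_zeros dips, 1/m-weighted, combined with the weakest dip so that a
  # single deep (speckle) dip cannot carry a wrong candidate.
  max_zeros <- 4L
  score_f <- function(f) {
    z <- sqrt(seq_len(max_zeros) * f)
    if (z[1] < lo || z[1] > hi) return(-Inf)
    z <- z[z <= hi]
    w <- 1 / seq_along(z)
    d <- dip(z)
    (sum(w * d) / sum(w) + min(d)) / 2
  }
  grid <- exp(seq(log(f_range[1]), log(f_range[2]), length.out = n_grid))
  sc <- vapply(grid, score_f, numeric(1))
  if (all(!is.finite(sc))) stop("no predicted CTF zero falls in the PSD band")
  best <- grid[which.max(sc)]
  fine <- seq(max(f_range[1], best * 0.95), min(f_range[2], best * 1.05),
              length.out = 401L)
  scf <- vapply(fine, score_f, numeric(1))
  est <- fine[which.max(scf)]
  boundary <- est <= f_range[1] * 1.001 || est >= f_range[2] * 0.999
  if (boundary)
    warning("estimate clamped to the boundary of f_range; truth may lie outside")
  zeros <- sqrt(seq_len(1000L) * est)
  zeros <- zeros[zeros >= lo & zeros <= hi]
  list(fresnel = est, minima = zeros, n_zeros = length(zeros),
       boundary = boundary)
}
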