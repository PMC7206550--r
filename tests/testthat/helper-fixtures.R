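# Shared fixtures and small oracles, all generated in code.

# centered disc indicator with optional Gaussian edge
disc_image <- function(n, radius = 0.3 * n, blur = 0,
                       cy = n / 2 + 0.5, cx = n / 2 + 0.5) {
  yy <- matrix(seq_len(n), n, n)
  xx <- t(yy)
  d <- ((yy - cy)^2 + (xx - cx)^2 < radius^2) * 1
  if (blur > 0) d <- holophase:::gauss_blur(d, blur)
  d
}

# tight support mask for a phantom phase map (small dilation)
tight_support <- function(phi, frac = 1e-4) {
  holophase:::gauss_blur((abs(phi) > frac * max(abs(phi))) * 1, 2) > 0.01
}

# band-pass an image with a frequency mask (FFT order)
bandpass <- function(img, mask) {
  Re(stats::fft(stats::fft(img) * mask, inverse = TRUE)) / length(img)
}

# off-center two-blob object for tomography tests
tomo_object <- function(n, blur = 3) {
  yy <- matrix(seq_len(n), n, n)
  xx <- t(yy)
  holophase:::gauss_blur(
    ((yy - 0.4 * n)^2 + (xx - 0.55 * n)^2 < (0.18 * n)^2) * 1 +
      0.6 * (((yy - 0.62 * n)^2 + (xx - 0.38 * n)^2) < (0.12 * n)^2), blur)
}

# random isolated detector columns (defect model for ring artifacts)
pick_isolated_columns <- function(nbad, n, minsep = 5, margin = 10) {
  cand <- sample(margin:(n - margin))
  keep <- integer(0)
  for (c_ in cand) {
    if (all(abs(c_ - keep) >= minsep)) keep <- c(keep, c_)
    if (length(keep) == nbad) break
  }
  sort(keep)
}

half_pi_angles <- function(n_ang) seq(0, pi, length.out = n_ang + 1L)[seq_len(n_ang)]
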