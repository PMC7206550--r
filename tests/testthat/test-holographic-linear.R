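# Linear holographic retrieval: CTF forward model and inversions, HoloTIE.

test_that("the CTF forward model has the textbook transfer structure", {
  z <- matrix(0, 32, 32)
  spec <- ctf_forward(z, z, c(0.01, 0.005))
  for (s in spec) {
    expect_equal(s[1, 1], 32^2 + 0i)
    expect_equal(sum(Mod(s[-1])), 0)
  }
  # at chi = pi/2 phase transfer is maximal and absorption transfer zero
  fr <- 0.01
  chi <- chirp_phase(c(64, 64), fr)
  at <- which(abs(chi - pi / 2) < 0.02)[1]
  set.seed(30)
  phi <- matrix(rnorm(64^2, sd = 1e-3), 64)
  mu <- matrix(abs(rnorm(64^2, sd = 1e-3)), 64)
  s1 <- ctf_forward(phi, mu, fr)[[1]]
  expect_equal(s1[at], 2 * sin(chi[at]) * stats::fft(phi)[at] -
                 cos(chi[at]) * stats::fft(mu)[at])
  # agrees with the nonlinear simulation for weak objects
  ph <- make_phantom(c(128, 128), max_phase = 0.01, beta_delta = 0.05, seed = 31)
  holo <- simulate_hologram(make_wavefield(ph$phi, ph$mu), 0.005, pad = "none")
  pred <- ctf_forward(ph$phi, ph$mu, 0.005)[[1]]
  meas <- stats::fft(holo)
  expect_lt(sqrt(sum(Mod(meas - pred)^2) / sum(Mod(pred[-1])^2)), 0.01)
})

test_that("multi-distance CTF inversion is accurate and regular at CTF zeros", {
  flat <- hologram_stack(list(matrix(1, 64, 64)), 5e-3)
  expect_equal(phaserec_ctf(flat), matrix(0, 64, 64))
  ph <- make_phantom(c(128, 128), max_phase = 0.05, beta_delta = 0, seed = 32)
  fl <- c(5e-3, 4e-3, 3e-3, 2e-3)
  st <- simulate_series(ph$phi, ph$mu, fl, pad = "none")
  rec <- phaserec_ctf(st, lim1 = 1e-8, lim2 = 1e-8)
  expect_lt(nrmse(rec, ph$phi, zero_mean = TRUE), 0.02)
  expect_true(all(is.finite(rec)))
})

test_that("zero-regularization CTF inversion is the exact pseudo-inverse", {
  set.seed(33)
  phi <- holophase:::gauss_blur(matrix(rnorm(32^2, sd = 1e-3), 32), 2)
  fl <- c(9e-3, 7e-3, 5e-3, 3e-3)
  spectra <- ctf_forward(phi, 0 * phi, fl)
  imgs <- lapply(spectra, function(s) Re(stats::fft(s, inverse = TRUE)) / 32^2)
  st <- hologram_stack(imgs, fl)
  rec <- phaserec_ctf(st, lim1 = 0, lim2 = 0)
  den <- Reduce(`+`, lapply(fl, function(f) (2 * sin(chirp_phase(c(32, 32), f)))^2))
  good <- den > 1e-12
  err <- stats::fft(rec) - stats::fft(phi)
  expect_lt(max(Mod(err[good])) / max(Mod(stats::fft(phi))), 1e-10)
})

test_that("the two-limit regularization tames single-distance low frequencies", {
  ph <- make_phantom(c(256, 256), max_phase = 0.4, beta_delta = 0, seed = 34)
  st <- simulate_series(ph$phi, ph$mu, 5e-3)
  rec <- phaserec_ctf(st, lim1 = 5e-4, lim2 = 1e-2, beta_delta = 0)
  expect_true(all(is.finite(rec)))
  # compare against a uniform alpha = 2*lim1 at high frequencies: the
  # two-limit filter must suppress the noise-prone band beyond the first
  # CTF maximum
  rec_uni <- phaserec_ctf(st, lim1 = 5e-4, lim2 = 5e-4)
  chi <- chirp_phase(c(256, 256), 5e-3)
  hiband <- chi > pi / 2
  e2 <- sum(Mod(stats::fft(rec))[hiband]^2)
  e1 <- sum(Mod(stats::fft(rec_uni))[hiband]^2)
  expect_lt(e2, e1)
})

test_that("constrained CTF reduces to plain CTF and benefits from support", {
  ph <- make_phantom(c(128, 128), max_phase = 0.05, beta_delta = 0, seed = 35)
  st <- simulate_series(ph$phi, ph$mu, 5e-3)
  plain <- phaserec_ctf(st)
  one <- phaserec_ctf_constrained(st, n_iter = 1)
  expect_lt(max(abs(one - plain)), 1e-10)
  supp <- tight_support(ph$phi)
  con <- phaserec_ctf_constrained(st, constraints = constraint_set(support = supp),
                                  n_iter = 30)
  expect_lt(nrmse(con[supp], ph$phi[supp]),
            0.5 * nrmse(plain[supp] - mean(plain[supp]) + mean(ph$phi[supp]),
                        ph$phi[supp]))
  # phase range projection is enforced
  con2 <- phaserec_ctf_constrained(st, constraints = constraint_set(phase_max = 0),
                                   n_iter = 5)
  expect_lte(max(con2), 1e-12)
  expect_error(phaserec_ctf_constrained(st,
    constraints = constraint_set(support = matrix(FALSE, 128, 128))), "support")
})

test_that("HoloTIE solves the two-plane transport-of-intensity problem", {
  expect_equal(phaserec_holotie(matrix(1, 32, 32), matrix(1, 32, 32),
                                0.11, 0.09), matrix(0, 32, 32))
  expect_error(phaserec_holotie(matrix(1, 16, 16), matrix(1, 16, 16), 0.1, 0.1),
               "differ")
  expect_warning(phaserec_holotie(matrix(1, 16, 16) + 1e-3, matrix(1, 16, 16),
                                  0.2, 0.1), "far apart")
  ph <- make_phantom(c(256, 256), max_phase = 0.01, beta_delta = 0,
                     smoothness = 1, seed = 36)
  psi <- make_wavefield(ph$phi)
  fa <- 0.12; fb <- 0.10
  ia <- simulate_hologram(psi, fa, pad = "none")
  ib <- simulate_hologram(psi, fb, pad = "none")
  rec <- phaserec_holotie(ia, ib, fa, fb, alpha = 1e-4)
  chi <- chirp_phase(c(256, 256), fb)     # the larger chi of the two
  band <- (chi <= 0.3) & (chi > 0.005)
  expect_lt(nrmse(bandpass(rec, band), bandpass(ph$phi, band)), 0.05)
})

test_that("uniform mid-plane intensity reduces HoloTIE to a single Poisson chain", {
  set.seed(37)
  d <- holophase:::gauss_blur(matrix(rnorm(64^2, sd = 1e-3), 64), 3)
  d <- d - mean(d)
  ia <- 1 + d; ib <- 1 - d          # mid-plane intensity exactly 1
  fa <- 0.11; fb <- 0.09
  alpha <- 1e-3
  rec <- phaserec_holotie(ia, ib, fa, fb, alpha)
  # shortcut: with I_mid = 1 the two Poisson solves collapse into
  # -P_a[laplacian(P_a[2 pi dI/dz])]
  xi2 <- freq_normsq(c(64, 64))
  pa <- 1 / (4 * pi^2 * xi2 + alpha)
  didz <- (ib - ia) / (1 / fb - 1 / fa)
  short_h <- (2 * pi) * stats::fft(didz) * pa * (4 * pi^2 * xi2) * pa
  short_h[1, 1] <- 0
  short <- Re(stats::fft(short_h, inverse = TRUE)) / 64^2
  expect_lt(max(abs(rec - short)), 1e-8)
})
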