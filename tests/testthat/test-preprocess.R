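# Flat/dark correction, outlier removal, padding, registration, alignment.

test_that("flat/dark correction inverts the acquisition model", {
  set.seed(10)
  i_true <- 1 + 0.1 * matrix(rnorm(32^2), 32)
  flat <- matrix(2, 32, 32) + 0.1 * matrix(rnorm(32^2), 32)
  dark <- matrix(0.5, 32, 32)
  raw <- dark + (flat - dark) * i_true
  out <- flat_dark_correct(raw, flat, dark)
  expect_equal(as.vector(out), as.vector(i_true), tolerance = 1e-12)
  expect_equal(attr(out, "n_flagged"), 0L)
  expect_equal(as.vector(flat_dark_correct(flat, flat, matrix(0, 32, 32))),
               rep(1, 32^2))
  expect_equal(as.vector(flat_dark_correct(raw, raw + 1, raw)), rep(0, 32^2))
  expect_error(flat_dark_correct(raw, matrix(0, 32, 32), matrix(0, 32, 32)),
               "nowhere positive")
  # dead flat pixels are flagged, not propagated
  flat2 <- flat; flat2[5, 5] <- 0.5   # equals dark there
  out2 <- flat_dark_correct(raw, flat2, dark)
  expect_equal(attr(out2, "n_flagged"), 1L)
  expect_equal(out2[5, 5], 1)
})

test_that("outlier removal corrects injected hot pixels and little else", {
  ph <- make_phantom(c(128, 128), max_phase = 0.3, beta_delta = 0.05, seed = 11)
  holo <- simulate_hologram(make_wavefield(ph$phi, ph$mu), 0.01,
                            photons = 1000, seed = 12)
  set.seed(13)
  n_hot <- round(0.001 * length(holo))
  hot <- sample(length(holo), n_hot)
  corrupted <- holo
  corrupted[hot] <- corrupted[hot] * stats::runif(n_hot, 5, 50)
  fixed <- remove_outliers(corrupted, window = 5, nsigma = 8)
  corrected <- abs(fixed[hot] - holo[hot]) < abs(corrupted[hot] - holo[hot]) / 10
  expect_gte(mean(corrected), 0.99)
  false_pos <- sum(fixed[-hot] != corrupted[-hot])
  expect_lt(false_pos / length(holo), 0.001)
  # unchanged pixels are bit-identical; clean image passes through
  clean <- remove_outliers(holo, window = 5, nsigma = 8)
  expect_lt(attr(clean, "n_replaced") / length(holo), 0.001)
  # idempotent up to isolated re-evaluations around replaced pixels
  twice <- remove_outliers(fixed, window = 5, nsigma = 8)
  expect_lt(mean(twice != fixed), 1e-4)
  # single hot pixel in a unit image
  u <- matrix(1, 16, 16); u[8, 8] <- 1e6
  expect_equal(remove_outliers(u)[8, 8], 1)
  expect_error(remove_outliers(u, window = 4), "odd")
})

test_that("pad/crop/window compose to identities and respect modes", {
  set.seed(14)
  img <- matrix(rnorm(24 * 16), 24, 16)
  expect_identical(pad_crop_window(img), img)
  padded <- pad_crop_window(img, c(48, 40))
  expect_equal(dim(padded), c(48L, 40L))
  expect_equal(pad_crop_window(padded, dim(img)), img)
  cst <- matrix(2.5, 8, 8)
  expect_equal(pad_crop_window(cst, c(20, 20), mode = "replicate"),
               matrix(2.5, 20, 20))
  expect_equal(pad_crop_window(cst, c(20, 20), mode = "symmetric"),
               matrix(2.5, 20, 20))
  con <- pad_crop_window(cst, c(12, 12), mode = "constant", value = -1)
  expect_equal(con[1, 1], -1)
  expect_equal(con[7, 7], 2.5)
  # tukey window only touches the transition band
  w <- pad_crop_window(matrix(1, 64, 64), window = "tukey", alpha = 0.2)
  expect_equal(w[32, 32], 1)
  expect_lt(w[1, 32], 1e-12)
  expect_error(pad_crop_window(img, c(0, 4)), "target")
})

test_that("subpixel registration reaches 1/upsample accuracy", {
  ph <- make_phantom(c(256, 256), max_phase = 0.5, beta_delta = 0, seed = 15)
  a <- simulate_hologram(make_wavefield(ph$phi, ph$mu), 0.01)
  expect_equal(register_translation(a, a, 10)$shift, c(0, 0))
  expect_lt(register_translation(a, a, 10)$error, 1e-6)
  # integer circular roll is recovered exactly
  b_int <- a[c(252:256, 1:251), c(4:256, 1:3)]   # roll by (5, -3)
  expect_equal(register_translation(a, b_int, 1)$shift, c(5, -3))
  # subpixel shift to 0.02 px at upsample 100
  b_sub <- apply_shift(a, 0.30, -0.70)
  reg <- register_translation(a, b_sub, upsample = 100)
  expect_lt(max(abs(reg$shift - c(0.30, -0.70))), 0.02)
  # antisymmetry within 1/upsample
  fwd <- register_translation(a, b_sub, 50)$shift
  rev <- register_translation(b_sub, a, 50)$shift
  expect_lt(max(abs(fwd + rev)), 1 / 50 + 1e-9)
  expect_error(register_translation(matrix(1, 8, 8), matrix(1, 8, 8)),
               "constant")
})

test_that("Fourier shifting is an exact inverse pair", {
  set.seed(16)
  img <- matrix(rnorm(64^2), 64)
  expect_equal(apply_shift(img, 0, 0), img)
  expect_equal(apply_shift(img, 3, -2), img[c(62:64, 1:61), c(3:64, 1:2)],
               tolerance = 1e-10)
  rt <- apply_shift(apply_shift(img, 1.37, -2.61), -1.37, 2.61)
  expect_lt(max(abs(rt - img)), 1e-10)
})

test_that("multi-distance alignment recovers simulated drifts", {
  ph <- make_phantom(c(256, 256), max_phase = 0.4, beta_delta = 0.02, seed = 17)
  fl <- c(5.0e-3, 4.6e-3, 4.2e-3, 3.9e-3)   # closely spaced defocus series
  dr <- rbind(c(0, 0), c(2.3, -1.2), c(-3.4, 0.8), c(1.1, 2.6))
  st <- simulate_series(ph$phi, ph$mu, fl, drifts = dr)
  al <- align_series(st, reference = 1, upsample = 100)
  expect_lt(max(abs(al$shifts - dr)), 0.05)
  # already aligned: shifts ~ 0
  st0 <- simulate_series(ph$phi, ph$mu, fl)
  al0 <- align_series(st0, reference = 1, upsample = 100)
  expect_lt(max(abs(al0$shifts)), 0.05)
  # with 50-photon noise: within 0.2 px
  stn <- simulate_series(ph$phi, ph$mu, fl, photons = 50, drifts = dr, seed = 18)
  aln <- align_series(stn, reference = 1, upsample = 100)
  expect_lt(max(abs(aln$shifts - dr)), 0.2)
})
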