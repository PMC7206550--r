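# Projector framework and the AP/RAAR/mHIO iterations.

make_recovery_fixture <- function(n = 128, photons = Inf, seed_noise = 11) {
  ph <- make_phantom(c(n, n), max_phase = 0.5, beta_delta = 0, seed = 7)
  support <- tight_support(ph$phi)
  stack <- simulate_series(ph$phi, ph$mu, 5e-3, photons = photons,
                           seed = seed_noise)
  list(ph = ph, support = support, stack = stack,
       cs = constraint_set(support = support, phase_max = 0,
                           amplitude = "pure_phase"))
}

test_that("the magnitude projector fixes consistent fields and unit data", {
  # exact fixed point needs the exactly unitary (uncropped) propagator
  ph <- make_phantom(c(64, 64), max_phase = 0.5, beta_delta = 0, seed = 7)
  psi <- make_wavefield(ph$phi, ph$mu)
  st_exact <- hologram_stack(list(simulate_hologram(psi, 5e-3, pad = "none"),
                                  simulate_hologram(psi, 3e-3, pad = "none")),
                             c(5e-3, 3e-3))
  pm <- project_data(psi, st_exact, pad = "none")
  expect_lt(max(Mod(pm - psi)), 1e-10)
  # I = 1 everywhere: amplitude reset to 1, phase kept
  ones <- hologram_stack(matrix(1, 32, 32), 0.01)
  cfield <- matrix(2 * exp(0.7i), 32, 32)
  out <- project_data(cfield, ones, pad = "none")
  expect_equal(Mod(out), matrix(1, 32, 32))
  expect_equal(Arg(out), matrix(0.7, 32, 32))
  # single-distance magnitude projection is idempotent
  set.seed(40)
  psi_r <- matrix(exp(1i * rnorm(32^2, sd = 0.2)), 32)
  one_st <- hologram_stack(simulate_hologram(psi_r, 0.01, pad = "none"), 0.01)
  p1 <- project_data(psi_r * 0.5, one_st, pad = "none")
  p2 <- project_data(p1, one_st, pad = "none")
  expect_lt(max(Mod(p2 - p1)), 1e-9)
  expect_error(project_data(psi_r, hologram_stack(matrix(-1, 32, 32), 0.01)),
               "negative")
})

test_that("object-constraint projection is idempotent and enforces the rules", {
  set.seed(41)
  psi <- matrix(complex(real = rnorm(64^2), imaginary = rnorm(64^2)), 64)
  allpass <- constraint_set()
  expect_equal(project_object(psi, allpass), psi)
  pure <- constraint_set(amplitude = "pure_phase")
  expect_equal(Mod(project_object(psi, pure)), matrix(1, 64, 64))
  supp <- matrix(FALSE, 64, 64); supp[20:40, 20:40] <- TRUE
  cs <- constraint_set(support = supp, phase_min = -0.4, phase_max = 0,
                       amplitude = "single_material", beta_delta = 0.1)
  once <- project_object(psi, cs)
  twice <- project_object(once, cs)
  expect_equal(twice, once, tolerance = 1e-12)
  expect_true(all(once[!supp] == 1 + 0i))
  expect_true(all(Arg(once[supp]) <= 1e-12 & Arg(once[supp]) >= -0.4 - 1e-12))
  expect_equal(Mod(once[supp]), exp(0.1 * Arg(once[supp])))
})

test_that("AP recovers a supported pure-phase object from a noiseless hologram", {
  fx <- make_recovery_fixture()
  res <- iterate_ap(fx$stack, fx$cs, iteration_schedule(n_iter = 150))
  expect_length(res$residuals, 150)
  expect_gte(stats::cor(res$phi[fx$support], fx$ph$phi[fx$support]), 0.99)
  # a consistent starting point is (numerically) stationary under the
  # exactly unitary propagator
  ph0 <- make_phantom(c(64, 64), max_phase = 0.5, beta_delta = 0, seed = 7)
  psi0 <- make_wavefield(ph0$phi, ph0$mu)
  st0 <- hologram_stack(simulate_hologram(psi0, 5e-3, pad = "none"), 5e-3)
  res0 <- iterate_ap(st0, NULL, iteration_schedule(n_iter = 3, init = psi0),
                     pad = "none")
  expect_lt(max(res0$residuals), 1e-9)
})

test_that("RAAR interpolates between reflections and magnitude projection", {
  fx <- make_recovery_fixture()
  # beta = 0 reduces to repeated project_data
  sched0 <- iteration_schedule(n_iter = 3, beta_start = 0, beta_max = 0)
  ra <- iterate_raar(fx$stack, fx$cs, sched0)
  psi <- matrix(1 + 0i, 128, 128)
  for (k in 1:3) psi <- project_data(psi, fx$stack)
  expect_lt(max(Mod(ra$psi - psi)), 1e-9)
  # recovery with the default relaxation ramp
  res <- iterate_raar(fx$stack, fx$cs, iteration_schedule(n_iter = 150))
  expect_gte(stats::cor(res$phi[fx$support], fx$ph$phi[fx$support]), 0.99)
})

test_that("mHIO requires a support and drives the exterior to the empty beam", {
  fx <- make_recovery_fixture()
  expect_error(iterate_mhio(fx$stack, constraint_set(phase_max = 0)), "support")
  res <- iterate_mhio(fx$stack, fx$cs, iteration_schedule(n_iter = 150))
  expect_gte(stats::cor(res$phi[fx$support], fx$ph$phi[fx$support]), 0.99)
  # data-free toy: I = 1, start away from the empty beam; outside the
  # support the field must relax monotonically towards 1
  ones <- hologram_stack(matrix(1, 32, 32), 0.01)
  supp <- matrix(FALSE, 32, 32); supp[12:20, 12:20] <- TRUE
  cs <- constraint_set(support = supp)
  init <- matrix(1 + 0i, 32, 32)
  set.seed(42)
  init[!supp] <- init[!supp] + 0.5 * exp(2i * pi * stats::runif(sum(!supp)))
  devs <- vapply(c(5, 15, 40), function(ni) {
    out <- iterate_mhio(ones, cs,
                        iteration_schedule(n_iter = ni, feedback = 0.5,
                                           init = init), pad = "none")
    sqrt(mean(Mod(out$psi[!supp] - 1)^2))
  }, numeric(1))
  dev0 <- sqrt(mean(Mod(init[!supp] - 1)^2))
  expect_true(all(diff(c(dev0, devs)) < 0))
  expect_lt(devs[3], 0.75 * dev0)
})

test_that("residual histories are recorded and the divergence guard trips", {
  fx <- make_recovery_fixture()
  res <- iterate_ap(fx$stack, fx$cs, iteration_schedule(n_iter = 5))
  expect_length(res$residuals, 5)
  expect_true(all(res$residuals >= 0))
})

test_that("iteration schedules validate their fields", {
  expect_error(iteration_schedule(n_iter = 0), "n_iter")
  expect_error(iteration_schedule(beta_start = 1.5), "beta")
  expect_error(iteration_schedule(feedback = 0), "feedback")
  expect_error(iteration_schedule(n_iter = 10, beta_switch = 20), "beta_switch")
  sched <- iteration_schedule(n_iter = 100)
  expect_equal(sched$beta_switch, 50)
})
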