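# Calibration chain and band-averaged features.

test_that("calibration is an exact linear subtraction", {
  grid <- freq_grid(1e9, 3e9, 10)
  body <- random_sweep(grid, seed = 1)
  expect_true(all(calibrate(body, body)$values == 0))

  tumor_term <- random_sweep(grid, seed = 2)$values * 1e-3
  body_plus <- mwi_sweep(grid, body$values + tumor_term, "body")
  out <- calibrate(body_plus, body)
  expect_equal(out$values, tumor_term, tolerance = 1e-12)
  expect_equal(out$kind, "calibrated")

  # linearity: calibrate(a + b, empty) = calibrate(a, empty) + b
  a <- random_sweep(grid, seed = 3)
  b <- random_sweep(grid, seed = 4)$values
  empty <- random_sweep(grid, seed = 5, kind = "empty")
  lhs <- calibrate(mwi_sweep(grid, a$values + b, "body"), empty)$values
  rhs <- calibrate(a, empty)$values + b
  expect_equal(lhs, rhs, tolerance = 1e-12)

  expect_error(calibrate(body, random_sweep(freq_grid(1e9, 3e9, 11))),
               class = "mwi_alignment_error")
})

test_that("calibrated output matches the generator's stored components", {
  grid <- freq_grid(0.5e9, 3.5e9, 40)
  sc <- tumor_scenario(20)
  belt <- make_belt(sc)
  sim <- simulate_sweep(sc, belt, grid)
  cal <- calibrate(sim$body, sim$empty)
  stored <- sim$components$skin + sim$components$tumor
  expect_lt(max(Mod(cal$values - stored)) / max(Mod(stored)), 1e-9)
})

test_that("skin-artifact removal kills common-mode terms and is idempotent", {
  grid <- freq_grid(1e9, 3e9, 6)
  # constant across channels at each frequency -> exactly zero after removal
  K <- complex(real = rnorm(6), imaginary = rnorm(6))
  const <- mwi_sweep(grid, array(rep(K, 64), dim = c(6, 8, 8)), "calibrated")
  expect_lt(max(Mod(remove_skin_artifact(const)$values)), 1e-12)

  sw <- random_sweep(grid, seed = 6, kind = "calibrated")
  out <- remove_skin_artifact(sw)
  means <- rowMeans(matrix(out$values, nrow = 6))
  expect_lt(max(Mod(means)), 1e-12)
  expect_equal(remove_skin_artifact(out)$values, out$values,
               tolerance = 1e-12)

  # generator: rank-1 equal-weight skin is removed exactly, leaving the
  # tumor term minus its own channel mean
  sc <- tumor_scenario(20)
  belt <- make_belt(sc)
  sim <- simulate_sweep(sc, belt, grid)
  res <- remove_skin_artifact(calibrate(sim$body, sim$empty))
  tum <- sim$components$tumor
  tmean <- rowMeans(matrix(tum, nrow = 6))
  expected <- tum - array(rep(tmean, 64), dim = dim(tum))
  expect_equal(res$values, expected, tolerance = 1e-12)

  expect_error(remove_skin_artifact(sim$body), class = "mwi_validation_error")
})

test_that("band averaging follows the declared layout and oracle means", {
  grid <- freq_grid(0.5e9, 3.5e9, 31)
  # frequency-constant sweep: every amplitude slot = a, every phase slot = phi
  a <- 0.37; phi <- 0.9
  const <- mwi_sweep(grid, array(a * exp(1i * phi), dim = c(31, 8, 8)),
                     "calibrated")
  fv <- band_average_features(const)
  expect_length(fv, 128)
  expect_equal(unname(fv[1:64]), rep(a, 64), tolerance = 1e-12)
  expect_equal(unname(fv[65:128]), rep(phi, 64), tolerance = 1e-12)
  expect_named(fv[c(1, 2, 65)], c("amp_S11", "amp_S12", "phase_S11"))

  # amplitude linear in f: direct-summation oracle over in-band samples
  f <- frequencies(grid)
  amp <- 1 + (f - f[1]) / (f[31] - f[1])
  sw <- mwi_sweep(grid, array(rep(amp, 64), dim = c(31, 8, 8)), "calibrated")
  band <- c(1.5e9, 3e9)
  sel <- f >= band[1] & f <= band[2]
  fv2 <- band_average_features(sw, band)
  expect_equal(unname(fv2[1]), mean(amp[sel]), tolerance = 1e-12)

  # invariant to out-of-band changes
  v2 <- sw$values
  v2[!sel, , ] <- v2[!sel, , ] * 100
  fv3 <- band_average_features(mwi_sweep(grid, v2, "calibrated"), band)
  expect_equal(unname(fv3), unname(fv2), tolerance = 1e-12)

  expect_error(band_average_features(sw, c(3.6e9, 4e9)),
               class = "mwi_validation_error")
})

test_that("phase averaging unwraps along frequency", {
  grid <- freq_grid(1e9, 3e9, 21)
  f <- frequencies(grid)
  # linear phase ramp crossing the -pi/pi cut: unwrapped mean is the ramp mean
  ph <- seq(2.5, 4.5, length.out = 21)
  sw <- mwi_sweep(grid, array(rep(exp(1i * ph), 64), dim = c(21, 8, 8)),
                  "calibrated")
  fv <- band_average_features(sw, c(1e9, 3e9))
  expect_equal(unname(fv[65]), mean(ph), tolerance = 1e-9)
})

test_that("full chain yields a detection null for tumor-free cases", {
  grid <- freq_grid(0.5e9, 3.5e9, 24)
  sc0 <- torso_scenario()
  belt <- make_belt(sc0)
  sim <- simulate_sweep(sc0, belt, grid)
  fv <- band_average_features(
    remove_skin_artifact(calibrate(sim$body, sim$empty)))
  expect_lt(max(fv[1:64]), 1e-10)
})
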