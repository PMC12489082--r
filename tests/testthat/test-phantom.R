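# Forward scattering model: belt geometry, signal structure, noise,
# dataset generation.

test_that("belt placement sits on the ellipse with the expected symmetry", {
  circ <- torso_scenario(torso_semi_axes = c(0.15, 0.15))
  belt <- make_belt(circ, 8)
  ang <- atan2(belt$positions[, 2], belt$positions[, 1])
  gaps <- diff(ang) %% (2 * pi)
  expect_equal(unname(gaps), rep(pi / 4, 7), tolerance = 1e-12)

  sc <- torso_scenario()
  b8 <- make_belt(sc)
  expect_equal(nrow(unique(b8$positions)), 8)
  resid <- (b8$positions[, 1] / sc$torso_semi_axes[1])^2 +
    (b8$positions[, 2] / sc$torso_semi_axes[2])^2 - 1
  expect_lt(max(abs(resid)), 1e-9)
  expect_equal(b8$positions[1, 1:2], c(sc$torso_semi_axes[1], 0),
               ignore_attr = TRUE)

  expect_error(make_belt(sc, 2), class = "mwi_validation_error")
  expect_error(torso_scenario(torso_semi_axes = c(0, 0.1)),
               class = "mwi_validation_error")
})

test_that("generated sweeps are reciprocal and calibration-separable", {
  grid <- freq_grid(0.5e9, 3.5e9, 40L)
  sc <- tumor_scenario(20)
  belt <- make_belt(sc)
  sim <- simulate_sweep(sc, belt, grid)
  expect_true(is_reciprocal(sim$body, 1e-9))
  expect_true(is_reciprocal(sim$empty, 1e-9))
  # body - empty equals skin + tumor exactly
  expect_equal(sim$body$values - sim$empty$values,
               sim$components$skin + sim$components$tumor, tolerance = 1e-12)

  # no tumor: residual after both calibration steps is numerically zero
  sc0 <- torso_scenario()
  sim0 <- simulate_sweep(sc0, belt, grid)
  resid <- remove_skin_artifact(calibrate(sim0$body, sim0$empty))
  expect_lt(max(Mod(resid$values)), 1e-12)

  expect_error(
    torso_scenario(tumor = list(center = c(0, -0.11), diameter_mm = 10)),
    class = "mwi_validation_error")
})

test_that("tumor response grows with diameter and decays with belt offset", {
  grid <- freq_grid(0.5e9, 3.5e9, 40L)
  energy <- function(d, offset = 0) {
    sc <- tumor_scenario(d, offset = offset)
    sim <- simulate_sweep(sc, make_belt(sc), grid)
    f <- frequencies(grid)
    inb <- f >= 1.5e9 & f <= 3e9
    c(total = sum(Mod(sim$components$tumor)^2),
      inband = mean(Mod(sim$components$tumor[inb, , ])))
  }
  e10 <- energy(10); e30 <- energy(30)
  expect_gt(e30[["total"]], e10[["total"]])
  # Born term is linear in volume: |T| energy scales ~ (30/10)^6
  expect_gt(e30[["total"]] / e10[["total"]], 100)

  o0 <- energy(20, 0); o40 <- energy(20, 40)
  expect_lt(o40[["inband"]], o0[["inband"]])

  # monotone over the canonical size ladder
  lvl <- vapply(c(8, 20, 36, 48), function(d) energy(d)[["inband"]], 0)
  expect_true(all(diff(lvl) > 0))
  # and strictly decreasing over a ladder of offsets
  off <- vapply(c(0, 10, 20, 40), function(o) energy(20, o)[["inband"]], 0)
  expect_true(all(diff(off) < 0))
})

test_that("multiplicative noise is bounded, seeded and reciprocity-preserving", {
  sw <- random_sweep(freq_grid(1e9, 3e9, 12))
  expect_identical(add_noise(sw, noise_spec(0)), sw)

  n10 <- noise_spec(0.10, seed = 9)
  a <- add_noise(sw, n10)
  b <- add_noise(sw, n10)
  expect_identical(a$values, b$values)
  expect_true(is_reciprocal(a))

  relmag <- abs(Mod(a$values) / Mod(sw$values) - 1)
  expect_lte(max(relmag), 0.10 + 1e-12)
  expect_gt(max(relmag), 0.05)  # perturbation actually happened

  expect_error(noise_spec(-0.1), class = "mwi_validation_error")
  expect_error(noise_spec(1.5), class = "mwi_validation_error")
})

test_that("default dataset design reproduces the campaign counts", {
  grid <- freq_grid(0.5e9, 3.5e9, 4L)
  ds <- generate_dataset(grid = grid, seed = 5)
  expect_equal(nrow(ds$manifest), 170)
  expect_equal(as.vector(table(ds$manifest$simulation_set)), c(140, 20, 10))
  ab <- ds$manifest[ds$manifest$simulation_set %in% c("A", "B"), ]
  expect_equal(attr(ds$manifest, "n_class0"), 26)
  expect_equal(sum(ab$class_label == 0), 26)
  expect_equal(sum(ab$class_label == 1), 134)
  expect_equal(sum(ds$manifest$lung_side == "left"),
               sum(ds$manifest$lung_side == "right"))

  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  design <- list(set_A = list(diameters = c(5, 15), offset = 0),
                 set_B = NULL, set_C = NULL)
  generate_dataset(design, grid, seed = 3, dir = d1)
  generate_dataset(design, grid, seed = 3, dir = d2)
  expect_identical(readLines(file.path(d1, "manifest.csv")),
                   readLines(file.path(d2, "manifest.csv")))
  expect_identical(unname(tools::md5sum(list.files(file.path(d1, "sweeps"),
                                                   full.names = TRUE))),
                   unname(tools::md5sum(list.files(file.path(d2, "sweeps"),
                                                   full.names = TRUE))))

  dup <- list(set_A = list(diameters = c(10, 10), offset = 0),
              set_B = NULL, set_C = NULL)
  expect_error(generate_dataset(dup, grid), class = "mwi_validation_error")
})
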