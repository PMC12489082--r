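# Backprojection reconstruction, normalization and rendering.

test_that("reconstruction matches a brute-force oracle on a small instance", {
  grid <- freq_grid(1e9, 3e9, 5)
  set.seed(11)
  na <- 2
  v <- array(complex(real = rnorm(5 * na * na),
                     imaginary = rnorm(5 * na * na)), dim = c(5, na, na))
  v <- (v + aperm(v, c(1, 3, 2))) / 2
  sw <- mwi_sweep(grid, v, "calibrated")
  positions <- cbind(c(-0.1, 0.1), c(0.02, -0.03), 0)
  belt <- structure(list(n_antennas = na, positions = positions,
                         belt_plane_height = 0), class = "antenna_belt")
  px <- pixel_grid(16, 16, c(-0.15, 0.15, -0.1, 0.1))
  bg <- tissue_dielectric(35, 0.7)
  img <- reconstruct_image(sw, belt, px, bg)

  k <- 2 * pi * frequencies(grid) * sqrt(35) / 299792458
  ax <- mwibelt:::pixel_axes(px)
  oracle <- matrix(0, 16, 16)
  for (iy in 1:16) for (ix in 1:16) {
    p <- c(ax$x[ix], ax$y[iy], 0)
    acc <- 0i
    for (q in 1:5) for (i in 1:na) for (j in 1:na) {
      di <- sqrt(sum((p - positions[i, ])^2))
      dj <- sqrt(sum((p - positions[j, ])^2))
      acc <- acc + v[q, i, j] * exp(1i * k[q] * (di + dj))
    }
    oracle[iy, ix] <- Mod(acc)
  }
  expect_lt(max(abs(img$intensity - oracle)) / max(oracle), 1e-9)
})

test_that("an all-zero sweep images to zero and intensity is homogeneous", {
  grid <- freq_grid(1e9, 3e9, 4)
  sc <- torso_scenario()
  belt <- make_belt(sc)
  px <- default_pixel_grid(sc, 12)
  zero <- mwi_sweep(grid, array(0i, c(4, 8, 8)), "calibrated")
  expect_true(all(reconstruct_image(zero, belt, px,
                                    sc$background)$intensity == 0))

  sw <- random_sweep(grid, kind = "calibrated")
  i1 <- reconstruct_image(sw, belt, px, sc$background)$intensity
  sw3 <- mwi_sweep(grid, sw$values * 3, "calibrated")
  i3 <- reconstruct_image(sw3, belt, px, sc$background)$intensity
  expect_equal(i3, 3 * i1, tolerance = 1e-12)

  tiny <- pixel_grid(4, 4, c(-0.01, 0.01, -0.01, 0.01))
  expect_error(reconstruct_image(sw, belt, tiny, sc$background),
               class = "mwi_validation_error")
})

test_that("an on-plane point scatterer is localized within one pixel", {
  grid <- freq_grid(0.5e9, 3.5e9, 64)
  npx <- 64
  set.seed(21)
  miss <- 0
  for (rep in 1:20) {
    side <- sample(c("left", "right"), 1)
    sc0 <- torso_scenario(background = tissue_dielectric(35, 0))
    ctr <- sc0$lung_centers[side, ]
    p0 <- ctr + runif(2, -0.02, 0.02)
    sc <- torso_scenario(background = tissue_dielectric(35, 0),
                         tumor = list(center = p0, diameter_mm = 6))
    belt <- make_belt(sc)
    sim <- simulate_sweep(sc, belt, grid)
    sw <- mwi_sweep(grid, sim$components$tumor, "calibrated")
    px <- default_pixel_grid(sc, npx)
    img <- reconstruct_image(sw, belt, px, sc$background)
    ax <- mwibelt:::pixel_axes(px)
    w <- which(img$intensity == max(img$intensity), arr.ind = TRUE)[1, ]
    ix0 <- which.min(abs(ax$x - p0[1]))
    iy0 <- which.min(abs(ax$y - p0[2]))
    if (max(abs(c(w[2] - ix0, w[1] - iy0))) > 1) miss <- miss + 1
  }
  expect_equal(miss, 0)
})

test_that("mirrored scenarios produce mirrored images", {
  grid <- freq_grid(0.5e9, 3.5e9, 24)
  img_for <- function(x0) {
    sc <- torso_scenario(tumor = list(center = c(x0, 0.01),
                                      diameter_mm = 20))
    belt <- make_belt(sc)
    sim <- simulate_sweep(sc, belt, grid)
    px <- default_pixel_grid(sc, 32)
    reconstruct_image(mwi_sweep(grid, sim$components$tumor, "calibrated"),
                      belt, px, sc$background)$intensity
  }
  left <- img_for(-0.07)
  right <- img_for(0.07)
  expect_lt(max(abs(left - right[, rev(seq_len(ncol(right)))])) / max(left),
            1e-9)
})

test_that("healthy normalization scales as specified", {
  fx <- get_fixtures()
  img <- fx$images[[1]]
  own <- normalize_to_reference(img, max(img$intensity))
  expect_equal(max(normalized_intensity(own)), 1, tolerance = 1e-12)
  dbl <- normalize_to_reference(img, 2 * img$normalization_ref)
  expect_equal(normalized_intensity(dbl),
               normalized_intensity(img) / 2, tolerance = 1e-12)
  expect_error(normalize_to_reference(img, 0), class = "mwi_validation_error")

  # normalized peak strictly increases over the size ladder
  peaks <- vapply(fx$images[paste0("A-left-d", c("08", "12", "20", "36", "48"),
                                   ".00-o+000")],
                  function(im) max(normalized_intensity(im)), 0)
  expect_true(all(diff(peaks) > 0))
})

test_that("rendering is deterministic and resizes to the learner input", {
  fx <- get_fixtures()
  img <- fx$images[["A-left-d20.00-o+000"]]
  r <- render_image(img, size = c(634, 496), clip_max = 2)
  expect_equal(dim(r), c(496, 634, 3))
  expect_true(all(r >= 0 & r <= 1))
  r2 <- resize_raster(r, c(400, 400))
  expect_equal(dim(r2), c(400, 400, 3))

  const <- img
  const$intensity[] <- 1
  rc <- render_image(normalize_to_reference(const, 2), size = c(20, 10))
  expect_lt(diff(range(rc[, , 1])), 1e-12)

  t1 <- withr::local_tempfile(fileext = ".png")
  t2 <- withr::local_tempfile(fileext = ".png")
  write_raster_png(render_image(img, size = c(64, 64), clip_max = 2), t1)
  write_raster_png(render_image(img, size = c(64, 64), clip_max = 2), t2)
  expect_identical(readBin(t1, "raw", file.size(t1)),
                   readBin(t2, "raw", file.size(t2)))
})
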