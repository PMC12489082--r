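# Learners: gradient-boosted detector/size models, the CNN pair, persistence
# and noise fine-tuning.

test_that("the boosted detector separates well-separated classes", {
  tab <- separated_table()
  b <- train_xgb_detector(tab, seed = 3)
  p <- predict(b, tab$x)
  expect_equal(accuracy(tab$label, p$label), 1)
  expect_true(all(p$prob > 0 & p$prob < 1))
  # configuration echoed in the bundle manifest
  expect_equal(b$manifest$config[c("n_estimators", "max_depth", "eta",
                                   "subsample")],
               list(n_estimators = 10L, max_depth = 3L, eta = 0.3,
                    subsample = 0.5), ignore_attr = TRUE)

  bad <- labeled_table(tab$x[, 1:10], tab$label, tab$case_id)
  expect_error(train_xgb_detector(bad), class = "mwi_dimension_error")
})

test_that("bundles round-trip through save/load with identical predictions", {
  tab <- separated_table(n0 = 30, n1 = 30)
  held <- separated_table(n0 = 25, n1 = 25, seed = 77)
  b <- train_xgb_detector(tab, seed = 1)
  dirp <- withr::local_tempdir()
  save_bundle(b, file.path(dirp, "det"))
  b2 <- load_bundle(file.path(dirp, "det"))
  expect_identical(predict(b2, held$x), predict(b, held$x))

  # CNN round-trip
  set.seed(5)
  imgs <- lapply(1:6, function(i) array(runif(16 * 16 * 3), c(16, 16, 3)))
  cs <- image_set(imgs, runif(6, 1, 30), paste0("r", 1:6))
  cb <- train_cnn(build_cnn("size", cnn_config(input_size = c(16, 16, 3),
                                               epochs = 2, batch_size = 2,
                                               seed = 2)), cs, seed = 3)
  save_bundle(cb, file.path(dirp, "cnn"))
  cb2 <- load_bundle(file.path(dirp, "cnn"))
  expect_identical(predict(cb2, imgs), predict(cb, imgs))
})

test_that("the boosted size model fits degenerate and sane targets", {
  set.seed(9)
  x <- matrix(rnorm(40 * 128), 40)
  const <- labeled_table(x, rep(7, 40), sprintf("k%02d", 1:40))
  b <- train_xgb_size(const, size_config(n_estimators = 50), seed = 1)
  expect_equal(unname(predict(b, x)), rep(7, 40), tolerance = 1e-3)
  expect_equal(b$manifest$config$n_estimators, 50)
  expect_equal(size_config()$n_estimators, 1000L)
  expect_equal(size_config()$max_depth, 4L)

  neg <- labeled_table(x, rep(-1, 40), sprintf("k%02d", 1:40))
  expect_error(train_xgb_size(neg), class = "mwi_validation_error")
})

test_that("the CNN honors its architectural contract", {
  b <- build_cnn("detector", cnn_config(seed = 4))
  expect_lt(n_parameters(b), 100000)
  set.seed(2)
  imgs <- lapply(1:4, function(i) array(runif(32 * 32 * 3), c(32, 32, 3)))
  p <- predict(b, imgs)
  expect_true(all(p$prob > 0 & p$prob < 1))

  bs <- build_cnn("size", cnn_config(seed = 4))
  ps <- predict(bs, imgs)
  expect_true(is.numeric(ps) && all(is.finite(ps)))
  expect_error(build_cnn("oracle"), class = NULL)
})

test_that("CNN training reduces the loss, memorizes, and is order-invariant", {
  set.seed(31)
  imgs <- lapply(1:20, function(i) {
    lvl <- runif(1)
    array(lvl + 0.05 * runif(16 * 16 * 3), c(16, 16, 3))
  })
  y <- vapply(imgs, function(a) 30 * mean(a[, , 1]), 0)
  set <- image_set(imgs, y, sprintf("s%02d", 1:20))
  b <- train_cnn(build_cnn("size", cnn_config(input_size = c(16, 16, 3),
                                              epochs = 5, batch_size = 4,
                                              seed = 6)), set, seed = 7)
  expect_gt(b$fit$loss[1], b$fit$loss[3])

  # memorization of a single duplicated image
  one <- image_set(rep(imgs[1], 8), rep(12, 8), paste0("m", 1:8))
  bm <- train_cnn(build_cnn("size", cnn_config(input_size = c(16, 16, 3),
                                               epochs = 40, batch_size = 8,
                                               seed = 8)), one, seed = 9)
  expect_lt(abs(predict(bm, imgs[1]) - 12), 0.5)

  # permuted batch gives identically permuted outputs
  perm <- sample(20)
  expect_equal(predict(b, set$images[perm]), predict(b, set$images)[perm],
               tolerance = 1e-12)
})

test_that("noise fine-tuning continues training without forgetting clean data", {
  fx <- get_fixtures()
  labels <- fx$manifest$class_label
  feats <- feature_matrix(fx$features)
  tab <- labeled_table(feats, labels, fx$manifest$case_id)
  det <- train_xgb_detector(balance_dataset(tab, k = 3, seed = 1), seed = 2)
  clean_pred <- predict(det, feats)$label

  # zero noise: a no-op perturbation leaves clean predictions unchanged
  ft0 <- finetune_with_noise(det, fx$calibrated, labels, noise_levels = 0,
                             fraction = 1, seed = 3)
  expect_gt(xgboost::xgb.get.num.boosted.rounds(ft0$bundle$fit),
            xgboost::xgb.get.num.boosted.rounds(det$fit))
  expect_equal(predict(ft0$bundle, feats)$label, clean_pred)

  expect_error(finetune_with_noise(det, fx$calibrated, labels, fraction = 0),
               class = "mwi_validation_error")
  cnnb <- build_cnn("size", cnn_config(input_size = c(16, 16, 3)))
  expect_error(finetune_with_noise(cnnb, fx$calibrated, labels),
               class = "mwi_validation_error")
})

test_that("fine-tuned size model is not worse than naive on 10%-noise tests", {
  fx <- get_fixtures()
  radii <- fx$manifest$tumor_diameter_mm / 2
  feats <- feature_matrix(fx$features)
  tab <- labeled_table(feats, radii, fx$manifest$case_id)
  b <- train_xgb_size(tab, size_config(n_estimators = 200), seed = 4)
  ft <- finetune_with_noise(b, fx$calibrated, radii, fraction = 1, seed = 5)
  noisy <- vapply(seq_along(fx$calibrated), function(i) {
    band_average_features(add_noise(fx$calibrated[[i]],
                                    noise_spec(0.10, seed = 100 + i)))
  }, numeric(128))
  noisy <- t(noisy)
  mse_naive <- mean_squared_error(radii, predict(b, noisy))
  mse_ft <- mean_squared_error(radii, predict(ft$bundle, noisy))
  expect_lte(mse_ft, mse_naive)
})
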