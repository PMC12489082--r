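# The four learners: gradient-boosted detector and size regressor on
# band-averaged spectral features, and convolutional detector and size
# regressor on reconstructed images; plus persistence and the noise-robust
# fine-tuning protocol.

#' Gradient-boosted model configuration
#'
#' Defaults follow the tuned settings of the study design: the detector uses
#' 10 trees of depth 3; the size regressor 1000 trees of depth 4; both use
#' learning rate 0.3 and row subsampling 0.5.
#'
#' @param n_estimators number of boosting rounds.
#' @param max_depth maximum tree depth.
#' @param eta learning rate.
#' @param subsample row subsampling fraction.
#' @param n_estimators_finetune additional rounds appended during noise
#'   fine-tuning (training continuation).
#' @return a list of class `xgb_config`.
#' @export
detector_config <- function(n_estimators = 10L, max_depth = 3L, eta = 0.3,
                            subsample = 0.5, n_estimators_finetune = 10L) {
  structure(list(n_estimators = n_estimators, max_depth = max_depth,
                 eta = eta, subsample = subsample,
                 n_estimators_finetune = n_estimators_finetune),
            class = "xgb_config")
}

#' @rdname detector_config
#' @export
size_config <- function(n_estimators = 1000L, max_depth = 4L, eta = 0.3,
                        subsample = 0.5, n_estimators_finetune = 200L) {
  structure(list(n_estimators = n_estimators, max_depth = max_depth,
                 eta = eta, subsample = subsample,
                 n_estimators_finetune = n_estimators_finetune),
            class = "xgb_config")
}

#' Convolutional network configuration
#'
#' The committed default architecture is four blocks of
#' `[3x3 conv (8, 16, 32, 32 filters) -> ReLU -> 2x2 max-pool]`, global
#' average pooling, a 16-unit ReLU dense layer and a scalar head (sigmoid
#' for detection, linear for size) — under 100,000 trainable weights. The
#' global-average-pooling head makes the network input-size agnostic, so
#' reduced-resolution smoke runs use the same topology.
#'
#' @param input_size `(height, width, channels)` the pipeline feeds.
#' @param epochs training epochs (default 300).
#' @param finetune_epochs continued-training epochs for noise fine-tuning.
#' @param lr Adam learning rate.
#' @param batch_size minibatch size.
#' @param filters convolution filter counts per block.
#' @param dense_units hidden dense width.
#' @param seed weight-initialization seed.
#' @return a list of class `cnn_config`.
#' @export
cnn_config <- function(input_size = c(400L, 400L, 3L), epochs = 300L,
                       finetune_epochs = 100L, lr = 1e-3, batch_size = 16L,
                       filters = c(8L, 16L, 32L, 32L), dense_units = 16L,
                       seed = 1L) {
  structure(list(input_size = as.integer(input_size),
                 epochs = as.integer(epochs),
                 finetune_epochs = as.integer(finetune_epochs),
                 lr = lr, batch_size = as.integer(batch_size),
                 filters = as.integer(filters),
                 dense_units = as.integer(dense_units),
                 seed = as.integer(seed)),
            class = "cnn_config")
}

new_bundle <- function(kind, fit, config, manifest) {
  structure(list(kind = kind, fit = fit, config = config,
                 manifest = manifest),
            class = "mwi_bundle")
}

#' @export
print.mwi_bundle <- function(x, ...) {
  cat(sprintf("<mwi_bundle:%s> trained on %d cases\n", x$kind,
              length(x$manifest$case_ids)))
  invisible(x)
}

check_feature_dim <- function(x) {
  if (ncol(x) != 128)
    mwi_stop("tabular models expect 128 band-averaged features, got %d",
             "mwi_dimension_error", ncol(x))
}

xgb_params <- function(config, objective) {
  list(objective = objective, max_depth = config$max_depth, eta = config$eta,
       subsample = config$subsample, nthread = 1)
}

#' Train the gradient-boosted tumor detector
#'
#' @param table a balanced [labeled_table()] of 128-feature rows with 0/1
#'   labels.
#' @param config a [detector_config()].
#' @param seed training seed.
#' @return an `mwi_bundle` of kind `xgb_detector`.
#' @export
train_xgb_detector <- function(table, config = detector_config(), seed = 1L) {
  stopifnot(inherits(table, "labeled_table"))
  check_feature_dim(table$x)
  if (!all(table$label %in% c(0, 1)))
    mwi_stop("detector labels must be 0/1", "mwi_validation_error")
  d <- xgboost::xgb.DMatrix(table$x, label = table$label)
  fit <- with_seed(seed, xgboost::xgb.train(
    params = xgb_params(config, "binary:logistic"), data = d,
    nrounds = config$n_estimators, verbose = 0))
  new_bundle("xgb_detector", fit, config,
             list(case_ids = table$case_id, seed = seed, config = config))
}

#' Train the gradient-boosted tumor size regressor
#'
#' Targets are tumor radii in mm; the study design feeds only on-plane
#' (zero-offset) cases, since off-plane attenuation biases size downward.
#'
#' @param table a [labeled_table()] whose `label` holds radii in mm.
#' @param config a [size_config()].
#' @param seed training seed.
#' @return an `mwi_bundle` of kind `xgb_size`.
#' @export
train_xgb_size <- function(table, config = size_config(), seed = 1L) {
  stopifnot(inherits(table, "labeled_table"))
  check_feature_dim(table$x)
  if (any(table$label < 0))
    mwi_stop("size targets must be non-negative radii (mm)",
             "mwi_validation_error")
  d <- xgboost::xgb.DMatrix(table$x, label = table$label)
  fit <- with_seed(seed, xgboost::xgb.train(
    params = xgb_params(config, "reg:squarederror"), data = d,
    nrounds = config$n_estimators, verbose = 0))
  new_bundle("xgb_size", fit, config,
             list(case_ids = table$case_id, seed = seed, config = config))
}

#' Build an untrained convolutional model
#'
#' @param kind `"detector"` (sigmoid head, binary cross-entropy) or
#'   `"size"` (linear head, squared error).
#' @param config a [cnn_config()].
#' @return an `mwi_bundle` of kind `cnn_detector` or `cnn_size`.
#' @export
build_cnn <- function(kind = c("detector", "size"), config = cnn_config()) {
  kind <- match.arg(kind)
  weights <- with_seed(config$seed,
    cnn_init_cpp(config$filters, config$input_size[3], config$dense_units))
  fit <- list(weights = weights, head = if (kind == "detector") 0L else 1L,
              y_center = 0, y_scale = 1, loss = numeric(0))
  new_bundle(paste0("cnn_", kind), fit, config,
             list(case_ids = character(0), seed = config$seed,
                  config = config))
}

#' Number of trainable parameters of a CNN bundle
#' @param bundle an `mwi_bundle` of a CNN kind.
#' @return integer parameter count.
#' @export
n_parameters <- function(bundle) {
  stopifnot(inherits(bundle, "mwi_bundle"),
            bundle$kind %in% c("cnn_detector", "cnn_size"))
  as.integer(cnn_n_parameters_cpp(bundle$fit$weights))
}

stack_images <- function(images) {
  d <- dim(images[[1]])
  if (length(d) == 2) d <- c(d, 1L)
  x <- array(0, dim = c(d, length(images)))
  for (i in seq_along(images)) x[, , , i] <- images[[i]]
  x
}

#' Train (or continue training) a convolutional model
#'
#' Size targets are standardized internally (the head stays linear; the
#' center/scale are stored in the bundle and undone at prediction), which
#' keeps the Adam step size meaningful for targets in mm.
#'
#' @param bundle a [build_cnn()] output (or previously trained bundle).
#' @param set an [image_set()] with labels (0/1) or radius targets (mm).
#' @param epochs number of epochs (defaults to the bundle config's).
#' @param seed shuffling seed.
#' @return the bundle with updated weights and per-epoch training loss in
#'   `fit$loss`.
#' @export
train_cnn <- function(bundle, set, epochs = NULL, seed = 1L) {
  stopifnot(inherits(bundle, "mwi_bundle"),
            bundle$kind %in% c("cnn_detector", "cnn_size"),
            inherits(set, "image_set"))
  if (length(set$images) == 0)
    mwi_stop("empty training set", "mwi_validation_error")
  if (is.null(epochs)) epochs <- bundle$config$epochs
  x <- stack_images(set$images)
  y <- as.numeric(set$label)
  if (bundle$fit$head == 1L) {
    ctr <- mean(y); scl <- stats::sd(y)
    if (!is.finite(scl) || scl == 0) scl <- 1
    # first training fixes the standardization; continuation reuses it
    if (length(bundle$fit$loss) == 0) {
      bundle$fit$y_center <- ctr
      bundle$fit$y_scale <- scl
    }
    y <- (y - bundle$fit$y_center) / bundle$fit$y_scale
  }
  res <- with_seed(seed, cnn_train_cpp(
    bundle$fit$weights, x, y, as.integer(epochs), bundle$config$lr,
    bundle$config$batch_size, bundle$fit$head))
  bundle$fit$weights <- res$weights
  bundle$fit$loss <- c(bundle$fit$loss, as.numeric(res$loss))
  bundle$manifest$case_ids <- union(bundle$manifest$case_ids, set$parent_id)
  bundle
}

#' Predict from a trained bundle
#'
#' @param object an `mwi_bundle`.
#' @param newdata a numeric matrix of 128-feature rows (tabular kinds), or an
#'   [image_set()] / list of rasters (CNN kinds).
#' @param threshold detection probability threshold.
#' @param ... unused.
#' @return detectors: data.frame with `prob` and 0/1 `label`; size models:
#'   numeric radii in mm.
#' @export
predict.mwi_bundle <- function(object, newdata, threshold = 0.5, ...) {
  if (object$kind %in% c("xgb_detector", "xgb_size")) {
    x <- if (inherits(newdata, "labeled_table")) newdata$x else as.matrix(newdata)
    check_feature_dim(x)
    p <- predict(object$fit, xgboost::xgb.DMatrix(x))
  } else {
    images <- if (inherits(newdata, "image_set")) newdata$images else newdata
    p <- as.numeric(cnn_predict_cpp(object$fit$weights, stack_images(images),
                                    object$fit$head))
    if (object$fit$head == 1L)
      p <- p * object$fit$y_scale + object$fit$y_center
  }
  if (object$kind %in% c("xgb_detector", "cnn_detector")) {
    data.frame(prob = p, label = as.integer(p > threshold))
  } else {
    p
  }
}

#' Save / load a model bundle
#'
#' Bundles persist as a directory holding a JSON manifest plus a weights
#' blob; a reloaded bundle reproduces predictions exactly.
#'
#' @param bundle an `mwi_bundle`.
#' @param dir directory to create/read.
#' @return `save_bundle`: `dir` invisibly; `load_bundle`: the bundle.
#' @export
save_bundle <- function(bundle, dir) {
  stopifnot(inherits(bundle, "mwi_bundle"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  meta <- list(kind = bundle$kind, config = unclass(bundle$config),
               manifest = bundle$manifest)
  meta$manifest$config <- unclass(meta$manifest$config)
  jsonlite::write_json(meta, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  if (bundle$kind %in% c("xgb_detector", "xgb_size")) {
    raw <- xgboost::xgb.save.raw(bundle$fit)
    writeBin(raw, file.path(dir, "weights.ubj"))
  } else {
    saveRDS(bundle$fit, file.path(dir, "weights.rds"))
  }
  invisible(dir)
}

#' @rdname save_bundle
#' @export
load_bundle <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "manifest.json"),
                              simplifyVector = TRUE)
  kind <- meta$kind
  if (kind %in% c("xgb_detector", "xgb_size")) {
    raw <- readBin(file.path(dir, "weights.ubj"), "raw",
                   n = file.size(file.path(dir, "weights.ubj")))
    fit <- xgboost::xgb.load.raw(raw)
    config <- structure(meta$config, class = "xgb_config")
  } else {
    fit <- readRDS(file.path(dir, "weights.rds"))
    config <- structure(meta$config, class = "cnn_config")
  }
  new_bundle(kind, fit, config, meta$manifest)
}

#' Noise-robust fine-tuning
#'
#' Draws a random fraction of the supplied cases, builds noisy copies of each
#' at every noise level (multiplicative perturbation of the calibrated
#' S-parameters), and continues training on the noisy set: gradient-boosted
#' bundles append further boosting rounds (incremental learning); CNN bundles
#' continue for `finetune_epochs` with the same optimizer and loss.
#'
#' @param bundle a trained `mwi_bundle`.
#' @param sweeps named list of calibrated [mwi_sweep()]s.
#' @param targets labels (detectors) or radii in mm (size models), aligned
#'   with `sweeps`.
#' @param noise_levels relative noise levels (canonically 0.01, 0.05, 0.10).
#' @param fraction fraction of cases sampled into the fine-tuning subset.
#' @param seed seed for subset sampling and noise draws.
#' @param make_input function mapping a calibrated sweep to a model input
#'   (a 128-feature row or a raster). Defaults to [band_average_features()]
#'   for tabular kinds; required for CNN kinds.
#' @return list with `bundle` (the fine-tuned bundle) and `subset_ids` (the
#'   case ids used, so callers can hold out the complement).
#' @export
finetune_with_noise <- function(bundle, sweeps, targets,
                                noise_levels = c(0.01, 0.05, 0.10),
                                fraction = 0.5, seed = 1L,
                                make_input = NULL) {
  stopifnot(inherits(bundle, "mwi_bundle"), is.list(sweeps),
            length(sweeps) == length(targets))
  if (!is_number(fraction) || fraction <= 0 || fraction > 1)
    mwi_stop("fraction must be in (0, 1]", "mwi_validation_error")
  tabular <- bundle$kind %in% c("xgb_detector", "xgb_size")
  if (is.null(make_input)) {
    if (!tabular)
      mwi_stop("make_input is required for CNN bundles",
               "mwi_validation_error")
    make_input <- function(sw) band_average_features(sw)
  }
  n <- length(sweeps)
  idx <- with_seed(substream_seed(seed, "finetune-sample"),
                   sort(sample.int(n, max(1L, round(fraction * n)))))
  ids <- names(sweeps)[idx]
  inputs <- list(); y <- numeric(0); input_ids <- character(0)
  for (lev in noise_levels) {
    for (q in idx) {
      nseed <- substream_seed(seed, sprintf("noise-%s-%g", names(sweeps)[q],
                                            lev))
      noisy <- add_noise(sweeps[[q]], noise_spec(lev, nseed))
      inputs[[length(inputs) + 1L]] <- make_input(noisy)
      y <- c(y, targets[q])
      input_ids <- c(input_ids,
                     sprintf("%s-n%g-%d", names(sweeps)[q], lev,
                             length(inputs)))
    }
  }
  if (tabular) {
    x <- do.call(rbind, inputs)
    d <- xgboost::xgb.DMatrix(x, label = y)
    obj <- if (bundle$kind == "xgb_detector") "binary:logistic"
           else "reg:squarederror"
    fit <- with_seed(substream_seed(seed, "finetune-train"),
      xgboost::xgb.train(params = xgb_params(bundle$config, obj), data = d,
                         nrounds = bundle$config$n_estimators_finetune,
                         xgb_model = bundle$fit, verbose = 0))
    bundle$fit <- fit
  } else {
    set <- image_set(inputs, y, input_ids,
                     parent_id = rep(names(sweeps)[idx],
                                     times = length(noise_levels)))
    bundle <- train_cnn(bundle, set,
                        epochs = bundle$config$finetune_epochs,
                        seed = substream_seed(seed, "finetune-train"))
  }
  bundle$manifest$finetuned <- list(noise_levels = noise_levels,
                                    fraction = fraction, seed = seed)
  list(bundle = bundle, subset_ids = ids)
}
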