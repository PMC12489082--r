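# One-command reproduction of the full synthetic study:
# generate -> calibrate -> image -> features -> balance -> train -> finetune
# -> evaluate.

#' Pipeline run configuration
#'
#' The `smoke` profile reproduces the full chain at reduced cost (coarser
#' frequency grid, smaller reconstruction/render resolution, fewer CNN
#' epochs) and is the default; the `full` profile honors the campaign's
#' native settings (500 frequency points, 634x496 renders resized to
#' 400x400, 300 training epochs, 100 fine-tuning epochs).
#'
#' @param profile `"smoke"` or `"full"`.
#' @param seed root seed; every stage draws a named substream from it.
#' @param design dataset design, see [dataset_design()].
#' @return a list of class `run_config`.
#' @export
run_config <- function(profile = c("smoke", "full"), seed = 0L,
                       design = dataset_design()) {
  profile <- match.arg(profile)
  smoke <- profile == "smoke"
  cfg <- list(
    profile = profile,
    seed = as.integer(seed),
    design = design,
    grid = if (smoke) freq_grid(0.5e9, 3.5e9, 100L) else freq_grid(),
    band = c(1.5e9, 3.0e9),
    image_px = if (smoke) 48L else 128L,
    render_native = if (smoke) NULL else c(634L, 496L),
    cnn_input = if (smoke) c(48L, 48L) else c(400L, 400L),
    detector = detector_config(),
    size = size_config(),
    cnn_detector = cnn_config(
      input_size = c(if (smoke) c(48L, 48L) else c(400L, 400L), 3L),
      epochs = if (smoke) 12L else 300L,
      finetune_epochs = if (smoke) 8L else 100L),
    cnn_size = cnn_config(
      input_size = c(if (smoke) c(48L, 48L) else c(400L, 400L), 3L),
      epochs = if (smoke) 25L else 300L,
      finetune_epochs = if (smoke) 8L else 100L),
    n_size_test = 10L,
    detector_test_fraction = 0.2,
    noise = list(levels = c(0.01, 0.05, 0.10), fraction = 0.5,
                 test_level = 0.10, n_test = 20L),
    clip_quantile = 0.995
  )
  structure(cfg, class = "run_config")
}

config_as_list <- function(x) {
  if (is.list(x)) lapply(unclass(x), config_as_list) else x
}

flatten_raster <- function(r) as.vector(r)
unflatten_raster <- function(v, d) array(v, dim = d)

raster_pipeline <- function(belt, pixels, background, healthy_max, clip_max,
                            render_native, cnn_input) {
  function(sweep) {
    img <- normalize_to_reference(
      reconstruct_image(sweep, belt, pixels, background), healthy_max)
    if (is.null(render_native)) {
      render_image(img, size = cnn_input, clip_max = clip_max)
    } else {
      resize_raster(render_image(img, size = render_native,
                                 clip_max = clip_max), cnn_input)
    }
  }
}

#' Run the full synthetic study
#'
#' Generates the dataset, calibrates every case, reconstructs and renders
#' images, builds band-averaged features, balances the detection set with
#' ADASYN, trains the four learners, fine-tunes the selected models on a
#' noise-infused subset, and writes an evaluation report. Every stage draws
#' a named seed substream from `config$seed`, so a rerun with the same
#' configuration is fully reproducible.
#'
#' @param config a [run_config()].
#' @param dir output directory for artifacts (manifest, features, bundles,
#'   report, config stamp). `NULL` keeps everything in memory.
#' @param write_sweeps also write every Touchstone sweep file (large).
#' @return a list with the manifest, features, rasters, normalized images,
#'   trained and fine-tuned bundles, noisy-test comparison and the report.
#' @export
run_all <- function(config = run_config(), dir = NULL, write_sweeps = FALSE) {
  stopifnot(inherits(config, "run_config"))
  seed <- config$seed
  if (!is.null(dir)) dir.create(dir, recursive = TRUE, showWarnings = FALSE)

  ds <- mwi_stage("generate", generate_dataset(
    config$design, config$grid, seed = substream_seed(seed, "generate"),
    dir = if (write_sweeps) dir else NULL))
  manifest <- ds$manifest

  calibrated <- mwi_stage("calibrate", lapply(ds$cases, function(cs)
    remove_skin_artifact(calibrate(cs$body, cs$empty))))

  features <- mwi_stage("features",
                        feature_table(calibrated, manifest, config$band))

  # imaging: per-phantom healthy reference and shared pixel grid
  imaging <- mwi_stage("image", {
    phantoms <- unique(manifest$phantom_id)
    ref <- list(); px <- list(); bg <- list(); belt0 <- list()
    for (ph in phantoms) {
      cs <- ds$cases[[manifest$case_id[manifest$phantom_id == ph][1]]]
      sc0 <- cs$scenario; sc0$tumor <- NULL; sc0$belt_offset_mm <- 0
      belt0[[ph]] <- make_belt(sc0)
      px[[ph]] <- default_pixel_grid(sc0, config$image_px)
      bg[[ph]] <- sc0$background
      ref[[ph]] <- healthy_reference(sc0, belt0[[ph]], config$grid,
                                     px[[ph]])$healthy_max
    }
    images <- lapply(manifest$case_id, function(id) {
      ph <- manifest$phantom_id[manifest$case_id == id]
      normalize_to_reference(
        reconstruct_image(calibrated[[id]], ds$cases[[id]]$belt, px[[ph]],
                          bg[[ph]]), ref[[ph]])
    })
    names(images) <- manifest$case_id
    list(images = images, ref = ref, px = px, bg = bg, belt0 = belt0)
  })

  # stable color scale: high quantile of the in-domain normalized images
  male_ids <- manifest$case_id[manifest$phantom_id == "phantom_male"]
  clip_max <- stats::quantile(
    unlist(lapply(imaging$images[male_ids], normalized_intensity)),
    config$clip_quantile, names = FALSE)
  rasters <- mwi_stage("render", lapply(imaging$images, function(img) {
    if (is.null(config$render_native)) {
      render_image(img, size = config$cnn_input, clip_max = clip_max)
    } else {
      resize_raster(render_image(img, size = config$render_native,
                                 clip_max = clip_max), config$cnn_input)
    }
  }))

  ab <- manifest$simulation_set %in% c("A", "B")
  ab_ids <- manifest$case_id[ab]
  a_ids <- manifest$case_id[manifest$simulation_set == "A"]

  # detection split: stratified hold-out of original cases
  detector_test_ids <- with_seed(substream_seed(seed, "detector-split"), {
    cls <- manifest$class_label[ab]
    c(sample(ab_ids[cls == 0], max(1, round(0.2 * sum(cls == 0)))),
      sample(ab_ids[cls == 1], max(1, round(0.2 * sum(cls == 1)))))
  })
  det_train_ids <- setdiff(ab_ids, detector_test_ids)

  fx <- feature_matrix(features)
  rownames(fx) <- features$case_id
  det_table <- labeled_table(fx[det_train_ids, , drop = FALSE],
                             manifest$class_label[match(det_train_ids,
                                                        manifest$case_id)],
                             det_train_ids)
  det_balanced <- mwi_stage("balance", balance_dataset(
    det_table, k = 5L, seed = substream_seed(seed, "adasyn-tabular")))
  xgb_detector <- mwi_stage("train-detector", train_xgb_detector(
    det_balanced, config$detector, seed = substream_seed(seed, "xgb-det")))

  # image detector: ADASYN on flattened rasters of the training cases
  rdim <- dim(rasters[[1]])
  det_img_table <- labeled_table(
    t(vapply(det_train_ids, function(id) flatten_raster(rasters[[id]]),
             numeric(prod(rdim)))),
    manifest$class_label[match(det_train_ids, manifest$case_id)],
    det_train_ids)
  det_img_bal <- balance_dataset(det_img_table, k = 5L,
                                 seed = substream_seed(seed, "adasyn-image"))
  det_img_set <- image_set(
    lapply(seq_len(nrow(det_img_bal$x)),
           function(i) unflatten_raster(det_img_bal$x[i, ], rdim)),
    det_img_bal$label, det_img_bal$case_id, det_img_bal$parent_id,
    det_img_bal$provenance)
  cfg_cd <- config$cnn_detector
  cfg_cd$seed <- substream_seed(seed, "cnn-det-init")
  cnn_detector <- mwi_stage("train-cnn-detector", train_cnn(
    build_cnn("detector", cfg_cd), det_img_set,
    seed = substream_seed(seed, "cnn-det-train")))

  # size models: on-plane (set A) cases only, 10 held-out test cases
  size_test_ids <- with_seed(substream_seed(seed, "size-testset"), {
    left <- a_ids[manifest$lung_side[match(a_ids, manifest$case_id)] == "left"]
    right <- setdiff(a_ids, left)
    c(sample(left, config$n_size_test %/% 2),
      sample(right, config$n_size_test - config$n_size_test %/% 2))
  })
  radius <- manifest$tumor_diameter_mm[match(a_ids, manifest$case_id)] / 2
  size_table <- labeled_table(fx[a_ids, , drop = FALSE], radius, a_ids)
  size_split <- leakage_safe_split(size_table, size_test_ids, 0.8,
                                   substream_seed(seed, "size-split"))
  xgb_size <- mwi_stage("train-size", train_xgb_size(
    size_split$train, config$size, seed = substream_seed(seed, "xgb-size")))

  size_img_set <- image_set(rasters[a_ids], radius, a_ids)
  size_img_aug <- augment_images(size_img_set)
  size_img_split <- leakage_safe_split(size_img_aug, size_test_ids, 0.8,
                                       substream_seed(seed, "size-img-split"))
  cfg_cs <- config$cnn_size
  cfg_cs$seed <- substream_seed(seed, "cnn-size-init")
  cnn_size <- mwi_stage("train-cnn-size", train_cnn(
    build_cnn("size", cfg_cs), size_img_split$train,
    seed = substream_seed(seed, "cnn-size-train")))

  bundles <- list(xgb_detector = xgb_detector, xgb_size = xgb_size,
                  cnn_detector = cnn_detector, cnn_size = cnn_size)

  # noise-robust fine-tuning of the deployed pair (tabular detector,
  # image-based size model), evaluated on a noisy held-out subset of A
  noise <- config$noise
  a_sweeps <- calibrated[a_ids]
  a_labels <- manifest$class_label[match(a_ids, manifest$case_id)]
  ph <- "phantom_male"
  make_raster <- raster_pipeline(imaging$belt0[[ph]], imaging$px[[ph]],
                                 imaging$bg[[ph]], imaging$ref[[ph]],
                                 clip_max, config$render_native,
                                 config$cnn_input)
  ft_det <- mwi_stage("finetune-detector", finetune_with_noise(
    xgb_detector, a_sweeps, a_labels, noise$levels, noise$fraction,
    seed = substream_seed(seed, "finetune-det")))
  ft_size <- mwi_stage("finetune-size", finetune_with_noise(
    cnn_size, a_sweeps, radius, noise$levels, noise$fraction,
    seed = substream_seed(seed, "finetune-size"), make_input = make_raster))

  noisy_eval <- mwi_stage("noisy-test", {
    unused <- setdiff(a_ids, ft_det$subset_ids)
    test_ids <- with_seed(substream_seed(seed, "noisy-test"),
                          sample(unused, min(noise$n_test, length(unused))))
    noisy <- lapply(test_ids, function(id) add_noise(
      calibrated[[id]],
      noise_spec(noise$test_level, substream_seed(seed, paste0("nt-", id)))))
    names(noisy) <- test_ids
    nf <- t(vapply(noisy, function(sw) band_average_features(sw, config$band),
                   numeric(128)))
    nlab <- manifest$class_label[match(test_ids, manifest$case_id)]
    nrad <- manifest$tumor_diameter_mm[match(test_ids, manifest$case_id)] / 2
    nimg <- lapply(noisy, make_raster)
    data.frame(
      model = c("xgb_detector", "cnn_size"),
      metric = c("accuracy", "mse_mm2"),
      naive = c(accuracy(nlab, predict(xgb_detector, nf)$label),
                mean_squared_error(nrad, predict(cnn_size, nimg))),
      finetuned = c(accuracy(nlab, predict(ft_det$bundle, nf)$label),
                    mean_squared_error(nrad, predict(ft_size$bundle, nimg))),
      n = length(test_ids)
    )
  })

  report <- mwi_stage("evaluate", evaluation_report(
    manifest, bundles, features, rasters, size_test_ids, detector_test_ids,
    dir = if (is.null(dir)) NULL else file.path(dir, "report")))

  if (!is.null(dir)) {
    write_manifest(manifest, file.path(dir, "manifest.csv"))
    utils::write.csv(features, file.path(dir, "features.csv"),
                     row.names = FALSE)
    yaml::write_yaml(config_as_list(config), file.path(dir, "config.yaml"))
    stamp <- list(seed = seed,
                  config_md5 = unname(tools::md5sum(file.path(dir,
                                                              "config.yaml"))))
    jsonlite::write_json(stamp, file.path(dir, "run_meta.json"),
                         auto_unbox = TRUE)
    for (nm in names(bundles))
      save_bundle(bundles[[nm]], file.path(dir, "bundles", nm))
    save_bundle(ft_det$bundle, file.path(dir, "bundles",
                                         "xgb_detector_finetuned"))
    save_bundle(ft_size$bundle, file.path(dir, "bundles",
                                          "cnn_size_finetuned"))
  }

  list(config = config, manifest = manifest, features = features,
       calibrated = calibrated, images = imaging$images, rasters = rasters,
       clip_max = clip_max, bundles = bundles,
       finetuned = list(xgb_detector = ft_det, cnn_size = ft_size),
       noisy_eval = noisy_eval, report = report,
       size_test_ids = size_test_ids, detector_test_ids = detector_test_ids,
       imaging_refs = imaging[c("ref", "px", "bg", "belt0")], dir = dir)
}
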