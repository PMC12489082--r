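# Held-out evaluation report: per-model metrics in-domain and cross-phantom,
# fused decisions and stage assignments.

#' Evaluation report over held-out cases
#'
#' Computes detector accuracy and size-model mean squared error on the
#' held-out in-domain cases, and — when second-phantom cases are supplied —
#' a cross-phantom generalization section. Each held-out case also receives
#' a fused decision (OR over detector positions for the same tumor, maximum
#' over size predictions) and a size-based stage assignment.
#'
#' @param manifest dataset manifest (with `class_label`).
#' @param bundles named list with elements `xgb_detector`, `xgb_size`,
#'   `cnn_detector`, `cnn_size` (any may be omitted).
#' @param features feature table from [feature_table()].
#' @param rasters named list of rendered rasters per case id.
#' @param size_test_ids held-out case ids for the size models.
#' @param detector_test_ids held-out case ids for the detectors.
#' @param dir optional output directory for `report.csv` and `report.md`.
#' @return list of class `mwi_report` with `per_case` (data.frame) and
#'   `metrics` (data.frame).
#' @export
evaluation_report <- function(manifest, bundles, features, rasters,
                              size_test_ids, detector_test_ids, dir = NULL) {
  check_leak <- function(bundle, ids) {
    if (is.null(bundle)) return(invisible(NULL))
    bad <- intersect(bundle$manifest$case_ids, ids)
    if (length(bad) > 0)
      mwi_stop("train/test leakage: %s", "mwi_leakage_error",
               paste(utils::head(bad, 3), collapse = ", "))
  }
  check_leak(bundles$xgb_detector, detector_test_ids)
  check_leak(bundles$cnn_detector, detector_test_ids)
  check_leak(bundles$xgb_size, size_test_ids)
  check_leak(bundles$cnn_size, size_test_ids)

  c_ids <- manifest$case_id[manifest$simulation_set == "C"]
  ids <- unique(c(detector_test_ids, size_test_ids, c_ids))
  mrow <- manifest[match(ids, manifest$case_id), ]
  fx <- feature_matrix(features)[match(ids, features$case_id), , drop = FALSE]
  img <- rasters[ids]

  per_case <- data.frame(
    case_id = ids, simulation_set = mrow$simulation_set,
    lung_side = mrow$lung_side,
    true_diameter_mm = mrow$tumor_diameter_mm,
    true_radius_mm = mrow$tumor_diameter_mm / 2,
    true_class = mrow$class_label, stringsAsFactors = FALSE
  )
  if (!is.null(bundles$xgb_detector)) {
    d <- predict(bundles$xgb_detector, fx)
    per_case$xgb_prob <- d$prob; per_case$xgb_label <- d$label
  }
  if (!is.null(bundles$cnn_detector)) {
    d <- predict(bundles$cnn_detector, img)
    per_case$cnn_prob <- d$prob; per_case$cnn_label <- d$label
  }
  if (!is.null(bundles$xgb_size))
    per_case$xgb_radius_mm <- predict(bundles$xgb_size, fx)
  if (!is.null(bundles$cnn_size))
    per_case$cnn_radius_mm <- predict(bundles$cnn_size, img)

  # positions measuring the same tumor: same phantom, lung and diameter
  tumor_key <- paste(mrow$phantom_id, mrow$lung_side, mrow$tumor_diameter_mm)
  if (!is.null(per_case$xgb_label))
    per_case$fused_label <- stats::ave(per_case$xgb_label, tumor_key,
                                       FUN = fuse_detection)
  if (!is.null(per_case$cnn_radius_mm)) {
    per_case$fused_radius_mm <- stats::ave(per_case$cnn_radius_mm, tumor_key,
                                           FUN = fuse_size)
    per_case$stage <- assign_stage(pmax(2 * per_case$fused_radius_mm, 0))
  }

  metric_rows <- list()
  add_metric <- function(model, section, metric, value, n) {
    metric_rows[[length(metric_rows) + 1L]] <<- data.frame(
      model = model, section = section, metric = metric, value = value, n = n)
  }
  sections <- list(in_domain = ids[per_case$simulation_set != "C"])
  if (length(c_ids) > 0) sections$cross_phantom <- c_ids
  for (sec in names(sections)) {
    sel_det <- per_case$case_id %in%
      intersect(sections[[sec]], if (sec == "cross_phantom") c_ids
                else detector_test_ids)
    sel_size <- per_case$case_id %in%
      intersect(sections[[sec]], if (sec == "cross_phantom") c_ids
                else size_test_ids)
    for (mdl in c("xgb", "cnn")) {
      lab <- per_case[[paste0(mdl, "_label")]]
      if (!is.null(lab) && any(sel_det))
        add_metric(paste0(mdl, "_detector"), sec, "accuracy",
                   accuracy(per_case$true_class[sel_det], lab[sel_det]),
                   sum(sel_det))
      rad <- per_case[[paste0(mdl, "_radius_mm")]]
      if (!is.null(rad) && any(sel_size))
        add_metric(paste0(mdl, "_size"), sec, "mse_mm2",
                   mean_squared_error(per_case$true_radius_mm[sel_size],
                                      rad[sel_size]),
                   sum(sel_size))
    }
  }
  metrics <- do.call(rbind, metric_rows)
  report <- structure(list(per_case = per_case, metrics = metrics),
                      class = "mwi_report")
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(per_case, file.path(dir, "report.csv"),
                     row.names = FALSE)
    md <- c("# Evaluation report", "",
            sprintf("- %s [%s] %s = %.4g (n = %d)", metrics$model,
                    metrics$section, metrics$metric, metrics$value,
                    metrics$n),
            "",
            "Size MSE is reported in mm^2 (squared radius error); the",
            "report labels follow the campaign's 'mm' phrasing for the",
            "same quantity.")
    writeLines(md, file.path(dir, "report.md"))
  }
  report
}

#' @export
print.mwi_report <- function(x, ...) {
  cat(sprintf("<mwi_report> %d held-out cases\n", nrow(x$per_case)))
  print(x$metrics, row.names = FALSE)
  invisible(x)
}
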