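# Multi-position decision fusion, staging, and evaluation statistics.

#' Fuse detections across belt positions
#'
#' Belt placement relative to the (unknown) tumor plane attenuates the
#' response, so readings are taken at several vertical positions and a tumor
#' is called present if any reading detects one (logical OR).
#'
#' @param labels integer 0/1 detections, one per belt position.
#' @return 0 or 1.
#' @export
fuse_detection <- function(labels) {
  if (length(labels) == 0)
    mwi_stop("fuse_detection needs at least one position", "mwi_validation_error")
  if (!all(labels %in% c(0, 1)))
    mwi_stop("labels must be 0/1", "mwi_validation_error")
  as.integer(any(labels == 1))
}

#' Fuse size predictions across belt positions
#'
#' Off-plane positions under-estimate size (the scattering response decays
#' with belt offset), so the maximum prediction over positions is taken.
#'
#' @param sizes_mm numeric size predictions, one per position.
#' @return the maximum prediction (mm).
#' @export
fuse_size <- function(sizes_mm) {
  if (length(sizes_mm) == 0)
    mwi_stop("fuse_size needs at least one position", "mwi_validation_error")
  max(sizes_mm)
}

#' Classification accuracy
#'
#' @param truth,predicted equal-length label vectors.
#' @return fraction of agreeing positions.
#' @export
accuracy <- function(truth, predicted) {
  if (length(truth) != length(predicted))
    mwi_stop("truth and predicted lengths differ", "mwi_validation_error")
  mean(truth == predicted)
}

#' Mean squared error
#'
#' @param truth,predicted equal-length numeric vectors.
#' @return mean of squared differences.
#' @export
mean_squared_error <- function(truth, predicted) {
  if (length(truth) != length(predicted) || length(truth) < 1)
    mwi_stop("truth and predicted must be equal-length, non-empty",
             "mwi_validation_error")
  mean((truth - predicted)^2)
}

#' Two-sample t test (pooled Student's t by default)
#'
#' Unpaired two-sample t test with pooled variance and
#' `df = n_a + n_b - 2`, reporting the two-tailed p value. Welch's
#' approximation is available behind `var_equal = FALSE`. The degenerate
#' case of zero pooled variance is documented: equal means give
#' `t = 0, p = 1`; unequal means give an infinite statistic and `p = 0`.
#'
#' @param a,b numeric samples (each of length at least 2).
#' @param var_equal pool the variances (Student) or not (Welch).
#' @return list with `statistic`, `p_value`, `df`.
#' @export
two_sample_ttest <- function(a, b, var_equal = TRUE) {
  if (length(a) < 2 || length(b) < 2)
    mwi_stop("each sample needs at least 2 observations",
             "mwi_validation_error")
  if (stats::var(a) == 0 && stats::var(b) == 0) {
    if (mean(a) == mean(b))
      return(list(statistic = 0, p_value = 1,
                  df = length(a) + length(b) - 2))
    return(list(statistic = sign(mean(a) - mean(b)) * Inf, p_value = 0,
                df = length(a) + length(b) - 2))
  }
  ht <- stats::t.test(a, b, var.equal = var_equal)
  list(statistic = unname(ht$statistic), p_value = ht$p.value,
       df = unname(ht$parameter))
}

#' Bundled benchmark table of actual vs predicted tumor radii
#'
#' A 10-case held-out benchmark of actual tumor radii (mm) with the radii
#' predicted by a tabular gradient-boosted regressor and by an image-based
#' CNN regressor; used to validate the evaluation statistics
#' ([mean_squared_error()], [two_sample_ttest()]) against known values.
#'
#' @return data.frame with columns `actual_radius_mm`, `xgb_radius_mm`,
#'   `cnn_radius_mm`.
#' @export
reference_predictions <- function() {
  utils::read.csv(system.file("extdata", "benchmark_radius_predictions.csv",
                              package = "mwibelt"))
}
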