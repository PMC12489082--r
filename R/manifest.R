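# Case manifests, binary class labelling and size-based stage assignment.

manifest_columns <- c("case_id", "phantom_id", "tumor_diameter_mm", "lung_side",
                      "belt_offset_mm", "body_sweep_path", "empty_sweep_path",
                      "simulation_set")

#' Binary tumor class from diameter
#'
#' Class 0 is "no tumor or a very small tumor" (largest dimension at most
#' 8 mm); class 1 is a tumor larger than 8 mm. The boundary value 8 mm itself
#' is class 0.
#'
#' @param diameter_mm numeric vector of tumor diameters in mm (0 = no tumor).
#' @return integer vector of 0/1 labels.
#' @export
derive_class <- function(diameter_mm) {
  if (any(!is.finite(diameter_mm)) || any(diameter_mm < 0))
    mwi_stop("diameters must be finite and non-negative", "mwi_validation_error")
  as.integer(diameter_mm > 8)
}

#' Early-stage NSCLC label from tumor size
#'
#' Maps the tumor's largest dimension to the early-stage bins: IA up to 30 mm,
#' IB over 30 up to 40 mm, IIA over 40 up to 50 mm, and IIB for anything
#' larger (this size-only lookup cannot distinguish IIB from later stages and
#' reports IIB). Size 0 means no tumor. The 40 and 50 mm boundary points are
#' assigned to the lower stage so the bins partition the axis without gaps.
#'
#' @param size_mm numeric vector of sizes (largest dimension, mm).
#' @return character vector with values in
#'   `c("none", "IA", "IB", "IIA", "IIB")`.
#' @examples
#' assign_stage(c(0, 28, 45, 60))
#' @export
assign_stage <- function(size_mm) {
  if (any(!is.finite(size_mm)) || any(size_mm < 0))
    mwi_stop("size_mm must be finite and non-negative", "mwi_validation_error")
  out <- character(length(size_mm))
  out[size_mm == 0] <- "none"
  out[size_mm > 0 & size_mm <= 30] <- "IA"
  out[size_mm > 30 & size_mm <= 40] <- "IB"
  out[size_mm > 40 & size_mm <= 50] <- "IIA"
  out[size_mm > 50] <- "IIB"
  out
}

validate_manifest <- function(df) {
  missing <- setdiff(manifest_columns, names(df))
  if (length(missing) > 0)
    mwi_stop("manifest is missing column(s): %s", "mwi_schema_error",
             paste(missing, collapse = ", "))
  if (any(!is.finite(df$tumor_diameter_mm)) || any(df$tumor_diameter_mm < 0))
    mwi_stop("tumor_diameter_mm must be non-negative", "mwi_validation_error")
  if (!all(df$lung_side %in% c("left", "right", "none")))
    mwi_stop("lung_side must be one of left/right/none", "mwi_validation_error")
  bad <- xor(df$tumor_diameter_mm == 0, df$lung_side == "none")
  if (any(bad))
    mwi_stop("tumor_diameter_mm must be 0 exactly when lung_side is 'none'",
             "mwi_validation_error")
  if (anyDuplicated(df$case_id))
    mwi_stop("duplicate case_id in manifest", "mwi_validation_error")
  if (!all(df$simulation_set %in% c("A", "B", "C")))
    mwi_stop("simulation_set must be A, B or C", "mwi_validation_error")
  invisible(df)
}

#' Read a case manifest
#'
#' The class label is recomputed from the diameter on every read; a stored
#' label column, if present, is ignored rather than trusted.
#'
#' @param path path to a UTF-8 CSV manifest.
#' @return a data.frame with the manifest columns plus a derived
#'   `class_label` column.
#' @export
read_manifest <- function(path) {
  if (!file.exists(path))
    mwi_stop("manifest '%s' does not exist", "mwi_io_error", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  df <- df[, intersect(names(df), manifest_columns), drop = FALSE]
  validate_manifest(df)
  df$class_label <- derive_class(df$tumor_diameter_mm)
  df
}

#' Write a case manifest
#'
#' @param rows a data.frame holding the manifest columns (any derived label
#'   column is dropped before writing — labels are never stored as
#'   authoritative).
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_manifest <- function(rows, path) {
  validate_manifest(rows)
  utils::write.csv(rows[, manifest_columns, drop = FALSE], path,
                   row.names = FALSE, quote = FALSE)
  invisible(path)
}
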