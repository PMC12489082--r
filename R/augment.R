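# Image augmentation (flips and 180-degree rotation) and leakage-safe
# train/validation/test splitting.

#' Horizontal flip (across the vertical axis)
#' @param raster array `h x w x c` or matrix.
#' @return flipped array of the same shape.
#' @export
flip_horizontal <- function(raster) {
  if (is.matrix(raster)) return(raster[, rev(seq_len(ncol(raster))), drop = FALSE])
  raster[, rev(seq_len(dim(raster)[2])), , drop = FALSE]
}

#' Vertical flip (across the horizontal axis)
#' @param raster array `h x w x c` or matrix.
#' @return flipped array of the same shape.
#' @export
flip_vertical <- function(raster) {
  if (is.matrix(raster)) return(raster[rev(seq_len(nrow(raster))), , drop = FALSE])
  raster[rev(seq_len(dim(raster)[1])), , , drop = FALSE]
}

#' 180-degree rotation (horizontal then vertical flip)
#' @param raster array `h x w x c` or matrix.
#' @return rotated array of the same shape.
#' @export
rotate_180 <- function(raster) {
  flip_vertical(flip_horizontal(raster))
}

#' Labeled image set
#'
#' @param images list of rasters (arrays `h x w x c`), all the same shape.
#' @param label numeric labels/targets, one per image.
#' @param case_id unique ids per instance.
#' @param parent_id originating case id per instance.
#' @param provenance `"original"` or `"augmented"` per instance.
#' @return an object of class `image_set`.
#' @export
image_set <- function(images, label, case_id, parent_id = case_id,
                      provenance = rep("original", length(images))) {
  stopifnot(is.list(images), length(images) == length(label),
            length(images) == length(case_id))
  if (anyDuplicated(case_id))
    mwi_stop("duplicate case_id in image_set", "mwi_validation_error")
  structure(list(images = images, label = label,
                 case_id = as.character(case_id),
                 parent_id = as.character(parent_id),
                 provenance = as.character(provenance)),
            class = "image_set")
}

#' @export
print.image_set <- function(x, ...) {
  d <- dim(x$images[[1]])
  cat(sprintf("<image_set> %d instances of %s\n", length(x$images),
              paste(d, collapse = "x")))
  invisible(x)
}

set_subset <- function(set, idx) {
  image_set(set$images[idx], set$label[idx], set$case_id[idx],
            set$parent_id[idx], set$provenance[idx])
}

#' Quadruple an image set by flip augmentation
#'
#' Each original yields four instances: itself, its horizontal flip, its
#' vertical flip, and the 180-degree rotation (both flips composed). Labels
#' are copied; the three new instances carry provenance `"augmented"` and
#' their original's id as parent, so leakage-safe splitting can exclude all
#' descendants of a held-out case.
#'
#' @param set an [image_set()].
#' @return an [image_set()] with four times as many instances.
#' @export
augment_images <- function(set) {
  stopifnot(inherits(set, "image_set"))
  if (length(set$images) == 0)
    mwi_stop("cannot augment an empty image set", "mwi_validation_error")
  ops <- list(hflip = flip_horizontal, vflip = flip_vertical,
              rot180 = rotate_180)
  images <- set$images
  label <- set$label
  case_id <- set$case_id
  parent_id <- set$parent_id
  provenance <- set$provenance
  for (op in names(ops)) {
    images <- c(images, lapply(set$images, ops[[op]]))
    label <- c(label, set$label)
    case_id <- c(case_id, paste0(set$case_id, "-", op))
    parent_id <- c(parent_id, set$parent_id)
    provenance <- c(provenance, rep("augmented", length(set$images)))
  }
  image_set(images, label, case_id, parent_id, provenance)
}

#' Leakage-safe train/validation/test split
#'
#' Removes the held-out cases *and every synthetic or augmented descendant
#' of them* from the training pool, then splits the remaining pool by
#' originating case so no case contributes to more than one partition.
#'
#' @param data a [labeled_table()] or [image_set()].
#' @param test_ids original case ids held out as the test set (test
#'   partitions contain only original instances).
#' @param train_fraction fraction of the remaining originating cases
#'   assigned to training (the rest form the validation partition).
#' @param seed split seed.
#' @return list with `train`, `validation`, `test` (same class as `data`).
#' @export
leakage_safe_split <- function(data, test_ids = character(0),
                               train_fraction = 0.8, seed = 1L) {
  stopifnot(inherits(data, "labeled_table") || inherits(data, "image_set"))
  if (!is_number(train_fraction) || train_fraction <= 0 || train_fraction > 1)
    mwi_stop("train_fraction must be in (0, 1]", "mwi_validation_error")
  originals <- unique(data$parent_id)
  if (!all(test_ids %in% originals))
    mwi_stop("test_ids must be existing originating case ids",
             "mwi_validation_error")
  take <- function(idx) {
    if (inherits(data, "labeled_table")) table_subset(data, idx)
    else set_subset(data, idx)
  }
  is_test_desc <- data$parent_id %in% test_ids
  test_idx <- which(is_test_desc & data$provenance == "original")
  pool_parents <- setdiff(originals, test_ids)
  n_train <- max(1L, round(train_fraction * length(pool_parents)))
  train_parents <- with_seed(seed,
    sample(pool_parents, min(n_train, length(pool_parents))))
  train_idx <- which(data$parent_id %in% train_parents)
  val_idx <- which(!is_test_desc & !(data$parent_id %in% train_parents))
  # internal consistency: no originating case on two sides of any split
  stopifnot(
    length(intersect(data$parent_id[train_idx], data$parent_id[val_idx])) == 0,
    length(intersect(data$parent_id[train_idx], data$parent_id[test_idx])) == 0,
    length(intersect(data$parent_id[val_idx], data$parent_id[test_idx])) == 0
  )
  list(train = take(train_idx), validation = take(val_idx),
       test = take(test_idx))
}
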