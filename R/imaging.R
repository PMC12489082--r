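# Frequency-domain multistatic backprojection, healthy-reference
# normalization, and 3-channel rendering for the image-based models.

#' Reconstruction pixel grid
#'
#' @param nx,ny pixel counts per axis.
#' @param extent physical rectangle `c(xmin, xmax, ymin, ymax)` in m covering
#'   the torso cross-section.
#' @return an object of class `pixel_grid`.
#' @export
pixel_grid <- function(nx, ny, extent) {
  if (!is_count(nx) || !is_count(ny) || nx * ny < 4)
    mwi_stop("pixel grid must have nx*ny >= 4", "mwi_validation_error")
  if (length(extent) != 4 || extent[1] >= extent[2] || extent[3] >= extent[4])
    mwi_stop("extent must be c(xmin, xmax, ymin, ymax) with min < max",
             "mwi_validation_error")
  structure(list(nx = as.integer(nx), ny = as.integer(ny),
                 extent = as.numeric(extent)),
            class = "pixel_grid")
}

#' Default pixel grid for a scenario
#'
#' A square grid slightly larger than the torso ellipse, so it encloses the
#' belt.
#'
#' @param scenario a [torso_scenario()].
#' @param n pixels per axis.
#' @return a [pixel_grid()].
#' @export
default_pixel_grid <- function(scenario, n = 64L) {
  a <- scenario$torso_semi_axes[1] * 1.05
  b <- scenario$torso_semi_axes[2] * 1.05
  pixel_grid(n, n, c(-a, a, -b, b))
}

pixel_axes <- function(px) {
  dx <- (px$extent[2] - px$extent[1]) / px$nx
  dy <- (px$extent[4] - px$extent[3]) / px$ny
  list(x = px$extent[1] + (seq_len(px$nx) - 0.5) * dx,
       y = px$extent[3] + (seq_len(px$ny) - 0.5) * dy)
}

# pixel centers (npix x 3) ordered column-major for an (ny x nx) matrix
pixel_centers <- function(px, z) {
  ax <- pixel_axes(px)
  cbind(rep(ax$x, each = px$ny), rep(ax$y, times = px$nx), z)
}

#' Multistatic backprojection image reconstruction
#'
#' Phase-compensated coherent summation over all transmit-receive pairs and
#' frequencies, using the homogeneous-background wavenumber
#' `k(f) = 2 pi f sqrt(eps_r) / c`. Plain uniform weighting; the output is
#' the magnitude of the coherent sum (set `magnitude_squared` for intensity
#' squared). Monostatic (i = j) terms are included by default.
#'
#' @param calibrated a calibrated [mwi_sweep()].
#' @param belt an [make_belt()] output.
#' @param pixels a [pixel_grid()]; its extent must enclose the belt's
#'   plane projection.
#' @param background a [tissue_dielectric()] giving the propagation medium.
#' @param include_monostatic include i = j channels.
#' @param magnitude_squared image `|sum|^2` instead of `|sum|`.
#' @return an object of class `mwi_image`: `intensity` (`ny` x `nx` matrix,
#'   non-negative), `pixels`, and `normalization_ref` (`NULL` until
#'   [normalize_to_reference()] is applied).
#' @export
reconstruct_image <- function(calibrated, belt, pixels, background,
                              include_monostatic = TRUE,
                              magnitude_squared = FALSE) {
  stopifnot(inherits(calibrated, "mwi_sweep"), inherits(belt, "antenna_belt"),
            inherits(pixels, "pixel_grid"),
            inherits(background, "tissue_dielectric"))
  pos <- belt$positions
  ex <- pixels$extent
  tol <- 1e-9
  if (any(pos[, 1] < ex[1] - tol | pos[, 1] > ex[2] + tol |
          pos[, 2] < ex[3] - tol | pos[, 2] > ex[4] + tol))
    mwi_stop("pixel grid does not enclose the antenna belt",
             "mwi_validation_error")
  f <- frequencies(calibrated$grid)
  k <- background_wavenumber(background, f)
  S <- aperm(calibrated$values, c(2, 3, 1))
  if (!include_monostatic) {
    for (q in seq_along(f)) diag(S[, , q]) <- 0i
  }
  centers <- pixel_centers(pixels, belt$belt_plane_height)
  val <- backproject_cpp(S, pos, centers, k)
  if (magnitude_squared) val <- val^2
  structure(list(intensity = matrix(val, pixels$ny, pixels$nx),
                 pixels = pixels, normalization_ref = NULL),
            class = "mwi_image")
}

#' @export
print.mwi_image <- function(x, ...) {
  cat(sprintf("<mwi_image> %dx%d px, peak %.3g%s\n",
              x$pixels$ny, x$pixels$nx, max(x$intensity),
              if (is.null(x$normalization_ref)) ""
              else sprintf(", ref %.3g", x$normalization_ref)))
  invisible(x)
}

#' Normalize an image to the healthy-case maximum
#'
#' @param image an [reconstruct_image()] output.
#' @param healthy_max positive reference (maximum intensity of the healthy
#'   case). Normalized values may exceed 1 for tumor cases.
#' @return the image with `normalization_ref` set.
#' @export
normalize_to_reference <- function(image, healthy_max) {
  stopifnot(inherits(image, "mwi_image"))
  if (!is_number(healthy_max) || healthy_max <= 0)
    mwi_stop("healthy_max must be a positive number", "mwi_validation_error")
  image$normalization_ref <- healthy_max
  image
}

#' Normalized intensity matrix of an image
#'
#' @param image a normalized [mwi_image()].
#' @return numeric matrix `intensity / normalization_ref`.
#' @export
normalized_intensity <- function(image) {
  stopifnot(inherits(image, "mwi_image"))
  if (is.null(image$normalization_ref))
    mwi_stop("image has not been normalized to a healthy reference",
             "mwi_validation_error")
  image$intensity / image$normalization_ref
}

#' Healthy-reference reconstruction for a phantom
#'
#' Reconstructs the tumor-free scenario after empty-domain calibration. The
#' residual at this stage is the skin reflection, which dominates a healthy
#' record; its image maximum is the normalization reference shared by all
#' cases of the phantom. (After the second calibration step a synthetic
#' healthy case is identically zero, so the skin-stage image is the natural
#' reference.)
#'
#' @param scenario a [torso_scenario()] (its tumor, if any, is removed).
#' @param belt an [make_belt()] output.
#' @param grid a [freq_grid()].
#' @param pixels a [pixel_grid()].
#' @return list with `image` (the healthy reconstruction) and `healthy_max`.
#' @export
healthy_reference <- function(scenario, belt, grid, pixels) {
  scenario$tumor <- NULL
  sim <- simulate_sweep(scenario, belt, grid)
  img <- reconstruct_image(calibrate(sim$body, sim$empty), belt, pixels,
                           scenario$background)
  list(image = img, healthy_max = max(img$intensity))
}

# Bilinear resize of a single matrix to (h, w) output pixels.
resize_matrix_bilinear <- function(m, w, h) {
  ny <- nrow(m); nx <- ncol(m)
  xi <- pmin(pmax((seq_len(w) - 0.5) * nx / w + 0.5, 1), nx)
  yi <- pmin(pmax((seq_len(h) - 0.5) * ny / h + 0.5, 1), ny)
  x0 <- pmin(floor(xi), max(nx - 1, 1)); fx <- xi - x0
  y0 <- pmin(floor(yi), max(ny - 1, 1)); fy <- yi - y0
  x1 <- pmin(x0 + 1, nx); y1 <- pmin(y0 + 1, ny)
  m[y0, x0, drop = FALSE] * ((1 - fy) %o% (1 - fx)) +
    m[y1, x0, drop = FALSE] * (fy %o% (1 - fx)) +
    m[y0, x1, drop = FALSE] * ((1 - fy) %o% fx) +
    m[y1, x1, drop = FALSE] * (fy %o% fx)
}

#' Resize a 3-channel raster
#'
#' @param raster array `h x w x 3` in `[0, 1]`.
#' @param size target `(width, height)` in pixels.
#' @return resized array with bilinear interpolation.
#' @export
resize_raster <- function(raster, size) {
  if (length(size) != 2 || any(size < 1))
    mwi_stop("size must be positive (width, height)", "mwi_validation_error")
  out <- array(0, dim = c(size[2], size[1], dim(raster)[3]))
  for (c in seq_len(dim(raster)[3]))
    out[, , c] <- resize_matrix_bilinear(raster[, , c], size[1], size[2])
  out
}

#' Render a normalized image as a 3-channel raster
#'
#' Applies a fixed perceptual colormap to normalized values clipped to
#' `[0, clip_max]`. The default render size matches the pipeline's native
#' image dimensions (634 x 496); the learner input is produced by a further
#' bilinear resize (default 400 x 400).
#'
#' @param image a normalized [mwi_image()].
#' @param size `(width, height)` of the rendered raster.
#' @param clip_max upper clip value on the normalized scale; defaults to the
#'   image's own maximum. A pipeline-wide value (e.g. the 99.5th percentile
#'   of healthy-normalized training images) gives a stable color scale
#'   across cases.
#' @param palette vector of colors (defaults to 256-level viridis).
#' @return array `height x width x 3` of RGB values in `[0, 1]`.
#' @export
render_image <- function(image, size = c(634L, 496L), clip_max = NULL,
                         palette = grDevices::hcl.colors(256, "viridis")) {
  v <- normalized_intensity(image)
  if (length(size) != 2 || any(size < 1))
    mwi_stop("size must be positive (width, height)", "mwi_validation_error")
  if (is.null(clip_max)) clip_max <- max(v)
  if (clip_max <= 0) clip_max <- 1
  v <- pmin(pmax(v / clip_max, 0), 1)
  idx <- matrix(pmin(floor(v * (length(palette) - 1)) + 1L, length(palette)),
                nrow(v), ncol(v))
  rgb <- grDevices::col2rgb(palette) / 255
  base <- array(0, dim = c(nrow(v), ncol(v), 3))
  for (c in 1:3) base[, , c] <- matrix(rgb[c, idx], nrow(v), ncol(v))
  # image rows run bottom-to-top in physical y; flip so rasters are top-down
  base <- base[rev(seq_len(nrow(v))), , , drop = FALSE]
  resize_raster(base, size)
}

#' Write a raster to a PNG file
#'
#' @param raster array `h x w x 3` in `[0, 1]`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_raster_png <- function(raster, path) {
  png::writePNG(raster, path)
  invisible(path)
}
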