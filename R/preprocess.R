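# Two-step calibration and band-averaged feature construction.

#' Empty-domain calibration
#'
#' Element-wise complex subtraction of the empty-domain sweep from the
#' body-present sweep, removing antenna coupling and fixed clutter introduced
#' by the imaging domain. No resampling is performed: the two grids must be
#' identical.
#'
#' @param body body-present [mwi_sweep()].
#' @param empty empty-domain [mwi_sweep()] on the same grid.
#' @return a calibrated [mwi_sweep()].
#' @export
calibrate <- function(body, empty) {
  stopifnot(inherits(body, "mwi_sweep"), inherits(empty, "mwi_sweep"))
  if (!grids_identical(body$grid, empty$grid) ||
      n_antennas(body) != n_antennas(empty))
    mwi_stop("body and empty sweeps are not on the same grid/port layout",
             "mwi_alignment_error")
  mwi_sweep(body$grid, body$values - empty$values, kind = "calibrated")
}

#' Skin-artifact removal
#'
#' At each frequency, the complex mean over all transmit/receive channels is
#' subtracted from every channel. The dominant skin reflection is common-mode
#' across channels, so this mean removal suppresses it; the operation is
#' idempotent and leaves every per-frequency channel mean at zero.
#'
#' @param calibrated a calibrated [mwi_sweep()].
#' @return an [mwi_sweep()] with zero channel mean at every frequency.
#' @export
remove_skin_artifact <- function(calibrated) {
  stopifnot(inherits(calibrated, "mwi_sweep"))
  if (calibrated$kind != "calibrated")
    mwi_stop("skin-artifact removal expects a calibrated sweep",
             "mwi_validation_error")
  v <- calibrated$values
  d <- dim(v)
  m <- rowMeans(matrix(v, nrow = d[1]))
  mwi_sweep(calibrated$grid, v - array(rep(m, d[2] * d[3]), dim = d),
            kind = "calibrated")
}

channel_names <- function(na = 8L) {
  idx <- expand.grid(j = seq_len(na), i = seq_len(na))[, c("i", "j")]
  idx <- idx[order(idx$i, idx$j), ]
  sprintf("S%d%d", idx$i, idx$j)
}

#' Band-averaged feature vector
#'
#' Averages each channel's amplitude and phase over the operating band
#' (default 1.5-3 GHz, where the tumor-induced variation is most prominent),
#' yielding 64 amplitude means followed by 64 phase means for channel order
#' (1,1), (1,2), ..., (1,8), (2,1), ..., (8,8) — 128 values in total.
#' Amplitudes are averaged in linear units; phase is unwrapped along
#' frequency per channel before averaging (a wrapped-phase average is not
#' stable). In-band sample selection is inclusive of both band endpoints.
#'
#' @param sweep an [mwi_sweep()].
#' @param band numeric `(f_lo, f_hi)` in Hz, within the sweep grid.
#' @return named numeric vector of length `2 * n_antennas^2` with attribute
#'   `band`.
#' @export
band_average_features <- function(sweep, band = c(1.5e9, 3.0e9)) {
  stopifnot(inherits(sweep, "mwi_sweep"))
  f <- frequencies(sweep$grid)
  if (length(band) != 2 || band[1] >= band[2] ||
      band[1] < sweep$grid$f_start - 1e-6 || band[2] > sweep$grid$f_stop + 1e-6)
    mwi_stop("band must lie within the sweep grid", "mwi_validation_error")
  sel <- which(f >= band[1] & f <= band[2])
  if (length(sel) < 2)
    mwi_stop("fewer than 2 in-band frequency samples", "mwi_validation_error")
  na <- n_antennas(sweep)
  v <- sweep$values[sel, , , drop = FALSE]
  amp <- numeric(na * na)
  phs <- numeric(na * na)
  q <- 0
  for (i in seq_len(na)) for (j in seq_len(na)) {
    q <- q + 1
    s <- v[, i, j]
    amp[q] <- mean(Mod(s))
    phs[q] <- mean(signal::unwrap(Arg(s)))
  }
  ch <- channel_names(na)
  out <- c(amp, phs)
  names(out) <- c(paste0("amp_", ch), paste0("phase_", ch))
  if (any(!is.finite(out)))
    mwi_stop("non-finite feature value", "mwi_validation_error")
  attr(out, "band") <- band
  out
}

#' Feature table for a set of calibrated sweeps
#'
#' @param calibrated named list of calibrated [mwi_sweep()]s (names are case
#'   ids).
#' @param manifest matching manifest data.frame.
#' @param band operating band passed to [band_average_features()].
#' @return a data.frame: `case_id`, `class_label`, `tumor_diameter_mm`,
#'   `radius_mm`, `simulation_set`, `belt_offset_mm`, then the 128 feature
#'   columns.
#' @export
feature_table <- function(calibrated, manifest, band = c(1.5e9, 3.0e9)) {
  stopifnot(all(manifest$case_id %in% names(calibrated)))
  feats <- t(vapply(manifest$case_id,
                    function(id) band_average_features(calibrated[[id]], band),
                    numeric(2 * n_antennas(calibrated[[1]])^2)))
  cbind(
    data.frame(case_id = manifest$case_id,
               class_label = derive_class(manifest$tumor_diameter_mm),
               tumor_diameter_mm = manifest$tumor_diameter_mm,
               radius_mm = manifest$tumor_diameter_mm / 2,
               simulation_set = manifest$simulation_set,
               belt_offset_mm = manifest$belt_offset_mm,
               stringsAsFactors = FALSE),
    as.data.frame(feats, row.names = FALSE)
  )
}

feature_matrix <- function(features) {
  as.matrix(features[, grep("^(amp|phase)_", names(features)), drop = FALSE])
}
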