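#' Complex S-matrix sweep
#'
#' Container for an `n_f x n_a x n_a` array of complex scattering coefficients
#' indexed `(frequency, transmit port, receive port)`, tagged as a raw
#' body-present record, an empty-domain record, or a calibrated difference.
#'
#' @param grid a [freq_grid()].
#' @param values complex array with dim `c(n_points, n_antennas, n_antennas)`.
#' @param kind one of `"body"`, `"empty"`, `"calibrated"`.
#' @return an object of class `mwi_sweep`.
#' @export
mwi_sweep <- function(grid, values, kind = c("body", "empty", "calibrated")) {
  kind <- match.arg(kind)
  stopifnot(inherits(grid, "freq_grid"))
  if (!is.complex(values)) values <- array(as.complex(values), dim = dim(values))
  d <- dim(values)
  if (length(d) != 3L || d[1] != grid$n_points || d[2] != d[3])
    mwi_stop("values must be (n_points, n_antennas, n_antennas); got (%s)",
             "mwi_dimension_error", paste(d, collapse = ", "))
  if (!all(is.finite(Re(values))) || !all(is.finite(Im(values))))
    mwi_stop("sweep contains non-finite values", "mwi_validation_error")
  structure(list(grid = grid, values = values, kind = kind),
            class = "mwi_sweep")
}

#' Number of antenna ports of a sweep
#' @param sweep an [mwi_sweep()].
#' @return integer port count.
#' @export
n_antennas <- function(sweep) {
  stopifnot(inherits(sweep, "mwi_sweep"))
  dim(sweep$values)[2]
}

#' Check transmit/receive reciprocity of a sweep
#'
#' A passive reciprocal network satisfies `S[f, i, j] == S[f, j, i]`; every
#' sweep produced by the forward model is reciprocal by construction.
#'
#' @param sweep an [mwi_sweep()].
#' @param tol relative tolerance.
#' @return logical.
#' @export
is_reciprocal <- function(sweep, tol = 1e-9) {
  v <- sweep$values
  vt <- aperm(v, c(1, 3, 2))
  scale <- max(Mod(v), .Machine$double.eps)
  max(Mod(v - vt)) <= tol * scale
}

#' @export
print.mwi_sweep <- function(x, ...) {
  cat(sprintf("<mwi_sweep:%s> %d ports, %d frequency points (%g-%g GHz)\n",
              x$kind, n_antennas(x), x$grid$n_points,
              x$grid$f_start / 1e9, x$grid$f_stop / 1e9))
  invisible(x)
}
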