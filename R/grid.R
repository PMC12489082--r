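#' Uniform frequency grid
#'
#' The sensing protocol sweeps a uniform frequency grid; the default matches
#' the belt's acquisition settings: 500 points from 0.5 to 3.5 GHz.
#'
#' @param f_start start frequency in Hz.
#' @param f_stop stop frequency in Hz; must exceed `f_start`.
#' @param n_points number of uniformly spaced points (at least 2).
#' @return an object of class `freq_grid`.
#' @examples
#' g <- freq_grid()
#' length(frequencies(g))
#' @export
freq_grid <- function(f_start = 0.5e9, f_stop = 3.5e9, n_points = 500L) {
  if (!is_number(f_start) || !is_number(f_stop) || f_start <= 0)
    mwi_stop("frequencies must be positive finite numbers", "mwi_validation_error")
  if (f_start >= f_stop)
    mwi_stop("f_start (%g) must be below f_stop (%g)", "mwi_validation_error",
             f_start, f_stop)
  if (!is_count(n_points) || n_points < 2)
    mwi_stop("n_points must be an integer >= 2", "mwi_validation_error")
  structure(
    list(f_start = as.numeric(f_start), f_stop = as.numeric(f_stop),
         n_points = as.integer(n_points)),
    class = "freq_grid"
  )
}

#' Frequencies of a grid
#'
#' @param grid a [freq_grid()].
#' @return numeric vector of strictly increasing frequencies in Hz.
#' @export
frequencies <- function(grid) {
  stopifnot(inherits(grid, "freq_grid"))
  seq(grid$f_start, grid$f_stop, length.out = grid$n_points)
}

#' @export
print.freq_grid <- function(x, ...) {
  cat(sprintf("<freq_grid> %g-%g GHz, %d points\n",
              x$f_start / 1e9, x$f_stop / 1e9, x$n_points))
  invisible(x)
}

grids_identical <- function(a, b, tol = 1e-12) {
  a$n_points == b$n_points &&
    abs(a$f_start - b$f_start) <= tol * max(1, abs(b$f_start)) &&
    abs(a$f_stop - b$f_stop) <= tol * max(1, abs(b$f_stop))
}
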