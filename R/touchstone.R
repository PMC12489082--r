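# Touchstone v1.x 8-port (.s8p) reader/writer.
#
# Frequencies are held in Hz internally and written in GHz with an explicit
# unit token; phase is radians internally, degrees only at the file boundary
# (MA encoding). Files written by write_sweep use real/imaginary (RI) encoding
# at full double precision so round-trips are lossless to well below 1e-9.

port_count_from_path <- function(path) {
  m <- regmatches(path, regexpr("\\.s([0-9]+)p$", path, ignore.case = TRUE))
  if (length(m) == 0) return(NA_integer_)
  as.integer(sub("\\.s([0-9]+)p$", "\\1", m, ignore.case = TRUE))
}

#' Write an S-matrix sweep to a Touchstone file
#'
#' @param sweep an [mwi_sweep()].
#' @param path output path, conventionally ending in `.s8p`.
#' @return `path`, invisibly.
#' @export
write_sweep <- function(sweep, path) {
  stopifnot(inherits(sweep, "mwi_sweep"))
  na <- n_antennas(sweep)
  f_ghz <- frequencies(sweep$grid) / 1e9
  con <- tryCatch(file(path, "w"),
                  error = function(e) mwi_stop("cannot open '%s' for writing",
                                               "mwi_io_error", path))
  on.exit(close(con))
  writeLines(c(
    sprintf("! %d-port S-parameter sweep (real/imaginary encoding)", na),
    sprintf("! kind: %s", sweep$kind),
    "# GHZ S RI R 50"
  ), con)
  v <- sweep$values
  for (q in seq_along(f_ghz)) {
    # row-major matrix entries, 4 complex pairs per line (Touchstone v1 layout)
    vv <- as.vector(t(v[q, , ]))  # row-major (i, j) channel order
    row <- as.vector(rbind(Re(vv), Im(vv)))
    pairs <- matrix(row, nrow = 8)  # 4 complex pairs per column
    first <- TRUE
    for (blk in seq_len(ncol(pairs))) {
      nums <- sprintf("% .17e", pairs[, blk])
      prefix <- if (first) sprintf("% .12f", f_ghz[q]) else "          "
      writeLines(paste(c(prefix, nums), collapse = " "), con)
      first <- FALSE
    }
  }
  invisible(path)
}

#' Read an S-matrix sweep from a Touchstone file
#'
#' Accepts the Touchstone v1.x 8-port dialect in real/imaginary (`RI`) or
#' magnitude/angle (`MA`, degrees) encoding, with frequencies in Hz, kHz, MHz
#' or GHz per the option line.
#'
#' @param path path to a `.s8p` file.
#' @return an [mwi_sweep()], grid inferred from the file.
#' @export
read_sweep <- function(path) {
  if (!file.exists(path))
    mwi_stop("file '%s' does not exist", "mwi_io_error", path)
  nport <- port_count_from_path(path)
  if (!is.na(nport) && nport != 8L)
    mwi_stop("expected an 8-port file, got %d ports ('%s')",
             "mwi_dimension_error", nport, path)
  lines <- readLines(path, warn = FALSE)
  kind <- "body"
  km <- grep("^!\\s*kind:", lines, value = TRUE)
  if (length(km) > 0) {
    k <- trimws(sub("^!\\s*kind:", "", km[1]))
    if (k %in% c("body", "empty", "calibrated")) kind <- k
  }
  unit <- 1e9; fmt <- "RI"
  opt <- grep("^\\s*#", lines)
  if (length(opt) > 0) {
    toks <- toupper(strsplit(trimws(sub("^\\s*#", "", lines[opt[1]])), "\\s+")[[1]])
    units <- c(HZ = 1, KHZ = 1e3, MHZ = 1e6, GHZ = 1e9)
    u <- intersect(toks, names(units))
    if (length(u) > 0) unit <- units[[u[1]]]
    ff <- intersect(toks, c("RI", "MA", "DB"))
    if (length(ff) > 0) fmt <- ff[1]
    if (fmt == "DB")
      mwi_stop("DB-encoded Touchstone files are not supported", "mwi_parse_error")
  }
  nums <- list()
  for (i in seq_along(lines)) {
    ln <- sub("!.*$", "", lines[i])
    ln <- trimws(ln)
    if (nchar(ln) == 0 || startsWith(ln, "#")) next
    toks <- strsplit(ln, "[[:space:],]+")[[1]]
    toks <- toks[nzchar(toks)]
    vals <- suppressWarnings(as.numeric(toks))
    if (anyNA(vals))
      mwi_stop("malformed Touchstone data on line %d of '%s': '%s'",
               "mwi_parse_error", i, path, lines[i])
    nums[[length(nums) + 1L]] <- vals
  }
  nums <- unlist(nums)
  per_point <- 1L + 2L * 64L
  if (length(nums) == 0 || length(nums) %% per_point != 0)
    mwi_stop("'%s' does not contain whole 8-port frequency records (%d values)",
             "mwi_parse_error", path, length(nums))
  nf <- length(nums) %/% per_point
  rec <- matrix(nums, nrow = per_point)
  f <- rec[1, ] * unit
  if (any(diff(f) <= 0))
    mwi_stop("frequencies in '%s' are not strictly increasing", "mwi_parse_error",
             path)
  a <- rec[seq(2, per_point, by = 2), , drop = FALSE]  # 64 x nf
  b <- rec[seq(3, per_point, by = 2), , drop = FALSE]
  if (fmt == "MA") {
    s <- a * exp(1i * b * pi / 180)
  } else {
    s <- a + 1i * b
  }
  # file order is row-major (i,j); fill [f, i, j]
  values <- array(NA_complex_, dim = c(nf, 8, 8))
  for (i in 1:8) for (j in 1:8) {
    values[, i, j] <- s[(i - 1) * 8 + j, ]
  }
  grid <- freq_grid(f[1], f[nf], nf)
  fg <- frequencies(grid)
  if (max(abs(fg - f)) > 1e-6 * max(f))
    mwi_stop("'%s' frequencies are not uniformly spaced", "mwi_parse_error", path)
  mwi_sweep(grid, values, kind = kind)
}
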