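# Parametric torso phantom and Born-approximation forward scattering model.
#
# The generator stands in for full-wave electromagnetic simulation of voxel
# body models. It is built so that the downstream chain is exercised on the
# same signal structure a full-wave run would produce: a tumor term whose
# energy grows with tumor volume and decays with antenna distance (hence with
# belt offset), additive fixed clutter removable by empty-domain subtraction,
# and a common-mode skin reflection removable by cross-channel mean removal.

C_LIGHT <- 299792458
EPS0 <- 8.8541878128e-12
ETA0 <- 376.730313668

#' Tissue dielectric properties
#'
#' @param eps_r relative permittivity (at least 1).
#' @param sigma conductivity in S/m (non-negative).
#' @return an object of class `tissue_dielectric`.
#' @export
tissue_dielectric <- function(eps_r, sigma) {
  if (!is_number(eps_r) || eps_r < 1)
    mwi_stop("eps_r must be a number >= 1", "mwi_validation_error")
  if (!is_number(sigma) || sigma < 0)
    mwi_stop("sigma must be a non-negative number", "mwi_validation_error")
  structure(list(eps_r = eps_r, sigma = sigma), class = "tissue_dielectric")
}

# Default dielectric palette. Values are placeholders consistent with the
# qualitative ordering of published tissue curves (tumor >> lung), not fitted
# dispersion models.
default_tissues <- function() {
  list(
    background = tissue_dielectric(35, 0.7),
    lung = tissue_dielectric(20, 0.4),
    tumor = tissue_dielectric(55, 1.5)
  )
}

#' Parametric torso scenario
#'
#' An elliptic torso cross-section with two circular lung regions and an
#' optional spherical tumor. The tumor's axial plane is `z = 0`; the belt
#' plane sits at `z = belt_offset_mm / 1000`, so a nonzero offset lengthens
#' every antenna-tumor path.
#'
#' @param phantom_id identifier string.
#' @param torso_semi_axes ellipse semi-axes `(a, b)` in m.
#' @param background a [tissue_dielectric()] for the averaged torso interior.
#' @param lung_centers 2x2 matrix of lung center `(x, y)` coordinates in m
#'   (rows named left/right).
#' @param lung_radius lung region radius in m.
#' @param tumor `NULL`, or a list with `center` (2-D or 3-D, m),
#'   `diameter_mm`, and optionally `tissue` (a [tissue_dielectric()]).
#' @param belt_offset_mm signed vertical distance from tumor plane to belt
#'   plane, in mm.
#' @param clutter_seed integer seed controlling the fixed clutter realization.
#' @return an object of class `torso_scenario`.
#' @export
torso_scenario <- function(phantom_id = "phantom_male",
                           torso_semi_axes = c(0.17, 0.12),
                           background = default_tissues()$background,
                           lung_centers = rbind(left = c(-0.07, 0.01),
                                                right = c(0.07, 0.01)),
                           lung_radius = 0.05,
                           tumor = NULL,
                           belt_offset_mm = 0,
                           clutter_seed = 1L) {
  if (length(torso_semi_axes) != 2 || any(!is.finite(torso_semi_axes)) ||
      any(torso_semi_axes <= 0))
    mwi_stop("torso_semi_axes must be two positive lengths",
             "mwi_validation_error")
  stopifnot(inherits(background, "tissue_dielectric"))
  lung_centers <- rbind(lung_centers)
  if (!all(dim(lung_centers) == c(2, 2)))
    mwi_stop("lung_centers must be a 2x2 matrix", "mwi_validation_error")
  if (!is_number(lung_radius) || lung_radius <= 0)
    mwi_stop("lung_radius must be positive", "mwi_validation_error")
  if (!is.null(tumor)) {
    if (is.null(tumor$tissue)) tumor$tissue <- default_tissues()$tumor
    stopifnot(inherits(tumor$tissue, "tissue_dielectric"))
    if (length(tumor$center) == 2) tumor$center <- c(tumor$center, 0)
    if (length(tumor$center) != 3 || any(!is.finite(tumor$center)))
      mwi_stop("tumor center must be a 2-D or 3-D coordinate",
               "mwi_validation_error")
    d2 <- sqrt(colSums((t(lung_centers) - tumor$center[1:2])^2))
    if (all(d2 > lung_radius))
      mwi_stop("tumor center lies outside both lung regions",
               "mwi_validation_error")
    dmax <- 2 * lung_radius * 1000
    if (!is_number(tumor$diameter_mm) || tumor$diameter_mm <= 0 ||
        tumor$diameter_mm > dmax)
      mwi_stop("tumor diameter must be in (0, %g] mm", "mwi_validation_error",
               dmax)
  }
  structure(list(
    phantom_id = phantom_id,
    torso_semi_axes = as.numeric(torso_semi_axes),
    background = background,
    lung_centers = lung_centers,
    lung_radius = lung_radius,
    tumor = tumor,
    belt_offset_mm = as.numeric(belt_offset_mm),
    clutter_seed = as.integer(clutter_seed)
  ), class = "torso_scenario")
}

#' @export
print.torso_scenario <- function(x, ...) {
  t <- if (is.null(x$tumor)) "no tumor"
       else sprintf("tumor %.1f mm", x$tumor$diameter_mm)
  cat(sprintf("<torso_scenario:%s> a=%.3f b=%.3f m, %s, belt offset %g mm\n",
              x$phantom_id, x$torso_semi_axes[1], x$torso_semi_axes[2], t,
              x$belt_offset_mm))
  invisible(x)
}

#' Place the antenna belt on a scenario
#'
#' Antennas sit at equal parameter increments on the torso ellipse at the
#' belt plane, first antenna on the +x axis, counter-clockwise.
#'
#' @param scenario a [torso_scenario()].
#' @param n_antennas number of antennas (default 8, at least 3).
#' @return an object of class `antenna_belt` with a `positions` matrix
#'   (`n_antennas` x 3, m) and `belt_plane_height` (m).
#' @export
make_belt <- function(scenario, n_antennas = 8L) {
  stopifnot(inherits(scenario, "torso_scenario"))
  if (!is_count(n_antennas) || n_antennas < 3)
    mwi_stop("n_antennas must be an integer >= 3", "mwi_validation_error")
  ab <- scenario$torso_semi_axes
  if (any(ab <= 0))
    mwi_stop("degenerate torso ellipse", "mwi_validation_error")
  z <- scenario$belt_offset_mm / 1000
  t <- 2 * pi * (seq_len(n_antennas) - 1) / n_antennas
  pos <- cbind(ab[1] * cos(t), ab[2] * sin(t), z)
  rownames(pos) <- paste0("ant", seq_len(n_antennas))
  structure(list(n_antennas = as.integer(n_antennas), positions = pos,
                 belt_plane_height = z),
            class = "antenna_belt")
}

#' @export
print.antenna_belt <- function(x, ...) {
  cat(sprintf("<antenna_belt> %d antennas at z=%g m\n",
              x$n_antennas, x$belt_plane_height))
  invisible(x)
}

# Complex relative permittivity eps_r - i sigma / (omega eps0).
complex_permittivity <- function(tissue, f) {
  tissue$eps_r - 1i * tissue$sigma / (2 * pi * f * EPS0)
}

# Background wavenumber (rad/m) and amplitude loss coefficient (Np/m).
background_wavenumber <- function(background, f) {
  2 * pi * f * sqrt(background$eps_r) / C_LIGHT
}
background_loss <- function(background) {
  (background$sigma / 2) * ETA0 / sqrt(background$eps_r)
}

# Overall Born scattering gain. Chosen once so that the in-band mean tumor
# term for a 20 mm tumor at zero offset on the default phantom sits roughly
# 40 dB below the mean clutter magnitude: the calibration chain has to matter.
TUMOR_GAIN <- 1.8e3

# Fixed clutter realization: deterministic in (clutter_seed, antenna
# geometry, frequency). Reciprocal by construction.
clutter_sweep <- function(scenario, belt, f) {
  na <- belt$n_antennas
  pos <- belt$positions
  dmat <- as.matrix(stats::dist(pos))
  amp <- matrix(0, na, na)
  phs <- matrix(0, na, na)
  with_seed(scenario$clutter_seed, {
    ud <- stats::runif(na)
    uo <- stats::runif(na * (na - 1) / 2)
    po <- stats::runif(na * (na + 1) / 2, 0, 2 * pi)
    diag(amp) <- 0.6 + 0.2 * ud
    k <- 0; kp <- 0
    for (i in seq_len(na)) for (j in i:na) {
      kp <- kp + 1
      phs[i, j] <- phs[j, i] <- po[kp]
      if (j > i) {
        k <- k + 1
        amp[i, j] <- amp[j, i] <- (0.05 + 0.05 * uo[k]) * exp(-3 * dmat[i, j])
      }
    }
  })
  tau <- dmat * sqrt(scenario$background$eps_r) / C_LIGHT
  diag(tau) <- 1e-10
  nf <- length(f)
  out <- array(0i, dim = c(nf, na, na))
  for (i in seq_len(na)) for (j in seq_len(na)) {
    out[, i, j] <- amp[i, j] * exp(-1i * (2 * pi * f * tau[i, j] + phs[i, j]))
  }
  out
}

# Common-mode skin reflection: identical across all channels at each
# frequency (rank-1 with equal weights), so cross-channel mean subtraction
# removes it exactly.
skin_sweep <- function(scenario, f, na) {
  tau <- 2 * 0.1 * sqrt(scenario$background$eps_r) / C_LIGHT
  K <- 0.02 * exp(-1i * 2 * pi * f * tau)
  array(rep(K, na * na), dim = c(length(f), na, na))
}

# Born point-scatterer tumor term.
tumor_sweep <- function(scenario, belt, f) {
  na <- belt$n_antennas
  nf <- length(f)
  out <- array(0i, dim = c(nf, na, na))
  tm <- scenario$tumor
  if (is.null(tm)) return(out)
  r_m <- tm$diameter_mm / 2000
  vol <- 4 / 3 * pi * r_m^3
  chi <- (complex_permittivity(tm$tissue, f) -
            complex_permittivity(scenario$background, f)) /
    complex_permittivity(scenario$background, f)
  k <- background_wavenumber(scenario$background, f)
  alpha <- background_loss(scenario$background)
  d <- sqrt(colSums((t(belt$positions) - tm$center)^2))
  E <- exp(-outer(alpha + 1i * k, d)) / rep(d, each = nf)  # nf x na
  g <- TUMOR_GAIN * vol * chi
  for (i in seq_len(na)) for (j in seq_len(na)) {
    out[, i, j] <- g * E[, i] * E[, j]
  }
  out
}

#' Simulate body-present and empty-domain sweeps for a scenario
#'
#' The empty-domain sweep holds the fixed clutter only; the body sweep adds a
#' common-mode skin reflection and, when a tumor is present, a Born
#' point-scatterer term whose energy scales with tumor volume and decays with
#' every antenna-tumor distance (so with belt offset). Both sweeps are
#' reciprocal by construction. The individual model components are attached
#' for verification of the calibration chain.
#'
#' @param scenario a [torso_scenario()].
#' @param belt an [make_belt()] output.
#' @param grid a [freq_grid()].
#' @return a list with elements `body`, `empty` (both [mwi_sweep()]) and
#'   `components` (list of complex arrays `clutter`, `skin`, `tumor`).
#' @export
simulate_sweep <- function(scenario, belt, grid = freq_grid()) {
  stopifnot(inherits(scenario, "torso_scenario"),
            inherits(belt, "antenna_belt"), inherits(grid, "freq_grid"))
  f <- frequencies(grid)
  cl <- clutter_sweep(scenario, belt, f)
  sk <- skin_sweep(scenario, f, belt$n_antennas)
  tu <- tumor_sweep(scenario, belt, f)
  list(
    body = mwi_sweep(grid, cl + sk + tu, kind = "body"),
    empty = mwi_sweep(grid, cl, kind = "empty"),
    components = list(clutter = cl, skin = sk, tumor = tu)
  )
}

#' Multiplicative measurement-noise specification
#'
#' @param relative_level fraction in `[0, 1]`; canonical protocol levels are
#'   0.01, 0.05 and 0.10.
#' @param seed integer seed.
#' @return an object of class `noise_spec`.
#' @export
noise_spec <- function(relative_level, seed = 1L) {
  if (!is_number(relative_level) || relative_level < 0 || relative_level > 1)
    mwi_stop("relative_level must be in [0, 1]", "mwi_validation_error")
  structure(list(relative_level = relative_level, seed = as.integer(seed)),
            class = "noise_spec")
}

#' Perturb a sweep with multiplicative measurement noise
#'
#' Each entry's magnitude is multiplied by `1 + u`, `u ~ U(-p, +p)`, and its
#' phase is perturbed additively by `U(-p, +p) * |phase|`, independently per
#' `(frequency, i <= j)` and mirrored to the lower triangle so reciprocity is
#' preserved. Level 0 returns the input unchanged.
#'
#' @param sweep an [mwi_sweep()].
#' @param noise a [noise_spec()].
#' @return a perturbed [mwi_sweep()].
#' @export
add_noise <- function(sweep, noise) {
  stopifnot(inherits(sweep, "mwi_sweep"), inherits(noise, "noise_spec"))
  p <- noise$relative_level
  if (p == 0) return(sweep)
  v <- sweep$values
  nf <- dim(v)[1]; na <- dim(v)[2]
  npair <- na * (na + 1) / 2
  with_seed(noise$seed, {
    u <- matrix(stats::runif(nf * npair, -p, p), nf, npair)
    w <- matrix(stats::runif(nf * npair, -p, p), nf, npair)
    kp <- 0
    for (i in seq_len(na)) for (j in i:na) {
      kp <- kp + 1
      s <- v[, i, j]
      m <- Mod(s) * (1 + u[, kp])
      ph <- Arg(s) + w[, kp] * abs(Arg(s))
      v[, i, j] <- m * exp(1i * ph)
      v[, j, i] <- v[, i, j]
    }
  })
  mwi_sweep(sweep$grid, v, kind = sweep$kind)
}
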