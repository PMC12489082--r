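# Study-design dataset generator: three simulation sets emulating the
# measurement campaign — an on-plane size sweep (A), off-plane belt positions
# (B), and a second, differently shaped phantom (C).

#' Default dataset design
#'
#' Set A: 70 tumor diameters per lung, uniformly covering 2-60 mm, belt on the
#' tumor plane. Set B: 10 cases per lung at nonzero belt offsets, half of them
#' with small (class 0) tumors so that A and B together hold 26 class-0 and
#' 134 class-1 cases. Set C: 10 cases on a second phantom with different
#' semi-axes and background dielectric, used only to probe generalization.
#'
#' @param n_sizes_A number of diameters per lung in set A.
#' @return a list with elements `set_A`, `set_B`, `set_C`.
#' @export
dataset_design <- function(n_sizes_A = 70L) {
  list(
    set_A = list(
      diameters = seq(2, 60, length.out = n_sizes_A),
      offset = 0
    ),
    set_B = list(
      diameters = c(3, 4.5, 6, 7, 8, 15, 25, 35, 45, 55),
      offsets = c(10, -15, 20, -25, 30, -35, 40, -45, 50, -30)
    ),
    set_C = list(
      phantom = list(
        phantom_id = "phantom_female",
        torso_semi_axes = c(0.15, 0.105),
        background = tissue_dielectric(30, 0.6)
      ),
      diameters = c(10, 20, 30, 40, 50),
      offset = 0
    )
  )
}

case_scenario <- function(set, side, diameter, offset, phantom_args,
                          clutter_seed) {
  args <- c(phantom_args, list(belt_offset_mm = offset,
                               clutter_seed = clutter_seed))
  sc0 <- do.call(torso_scenario, args)
  center <- sc0$lung_centers[side, ]
  args$tumor <- list(center = c(center, 0), diameter_mm = diameter)
  do.call(torso_scenario, args)
}

#' Generate the full synthetic dataset
#'
#' Builds every case of the design, simulates paired body/empty sweeps, and
#' assembles the case manifest. Fully reproducible under a fixed seed; the
#' clutter realization is shared by all cases of the same phantom (it is a
#' property of the imaging domain, which empty-domain calibration removes).
#'
#' @param design a [dataset_design()] list; `set_B` and/or `set_C` may be
#'   `NULL` to omit those sets.
#' @param grid a [freq_grid()].
#' @param seed root seed.
#' @param dir optional directory; when given, Touchstone sweep files and
#'   `manifest.csv` are written under it.
#' @return a list with `manifest` (data.frame, including derived
#'   `class_label`, with attribute `n_class0`) and `cases` (named list of
#'   `list(scenario, belt, body, empty)`).
#' @export
generate_dataset <- function(design = dataset_design(), grid = freq_grid(),
                             seed = 1L, dir = NULL) {
  specs <- list()
  add_case <- function(set, side, diameter, offset, phantom_args) {
    id <- sprintf("%s-%s-d%05.2f-o%+04d", set, side, diameter,
                  as.integer(round(offset)))
    specs[[length(specs) + 1L]] <<- list(id = id, set = set, side = side,
                                         diameter = diameter, offset = offset,
                                         phantom_args = phantom_args)
  }
  male <- list(phantom_id = "phantom_male")
  for (side in c("left", "right")) {
    for (d in design$set_A$diameters)
      add_case("A", side, d, design$set_A$offset, male)
    if (!is.null(design$set_B)) {
      for (q in seq_along(design$set_B$diameters))
        add_case("B", side, design$set_B$diameters[q],
                 design$set_B$offsets[q], male)
    }
    if (!is.null(design$set_C)) {
      for (d in design$set_C$diameters)
        add_case("C", side, d, design$set_C$offset, design$set_C$phantom)
    }
  }
  ids <- vapply(specs, `[[`, "", "id")
  if (anyDuplicated(ids))
    mwi_stop("duplicate case_id in dataset design: %s", "mwi_validation_error",
             ids[anyDuplicated(ids)])
  if (!is.null(dir)) dir.create(file.path(dir, "sweeps"),
                                recursive = TRUE, showWarnings = FALSE)
  cases <- vector("list", length(specs))
  names(cases) <- ids
  rows <- vector("list", length(specs))
  for (q in seq_along(specs)) {
    sp <- specs[[q]]
    cseed <- substream_seed(seed, sp$phantom_args$phantom_id)
    sc <- case_scenario(sp$set, sp$side, sp$diameter, sp$offset,
                        sp$phantom_args, cseed)
    belt <- make_belt(sc)
    sim <- simulate_sweep(sc, belt, grid)
    bp <- ""; ep <- ""
    if (!is.null(dir)) {
      # paths are stored relative to the dataset directory
      bp <- file.path("sweeps", paste0(sp$id, "_body.s8p"))
      ep <- file.path("sweeps", paste0(sp$id, "_empty.s8p"))
      write_sweep(sim$body, file.path(dir, bp))
      write_sweep(sim$empty, file.path(dir, ep))
    }
    cases[[q]] <- list(scenario = sc, belt = belt,
                       body = sim$body, empty = sim$empty)
    rows[[q]] <- data.frame(
      case_id = sp$id, phantom_id = sc$phantom_id,
      tumor_diameter_mm = sp$diameter, lung_side = sp$side,
      belt_offset_mm = sp$offset, body_sweep_path = bp, empty_sweep_path = ep,
      simulation_set = sp$set, stringsAsFactors = FALSE
    )
    mwi_log("generate", "case %s", sp$id)
  }
  manifest <- do.call(rbind, rows)
  validate_manifest(manifest)
  manifest$class_label <- derive_class(manifest$tumor_diameter_mm)
  attr(manifest, "n_class0") <- sum(manifest$class_label == 0)
  if (!is.null(dir)) write_manifest(manifest, file.path(dir, "manifest.csv"))
  list(manifest = manifest, cases = cases)
}

#' Build the miniature fixture dataset
#'
#' A 12-case dataset (6 diameters per lung: 4, 8, 12, 20, 36 and 48 mm, belt
#' on the tumor plane) with calibrated sweeps, band-averaged features and
#' healthy-normalized reconstructions, used by the test suite and examples.
#'
#' @param seed root seed.
#' @param grid frequency grid (reduced point count by default).
#' @param image_px reconstruction grid resolution per axis.
#' @return a list with `manifest`, `cases`, `calibrated`, `features`
#'   (data.frame), `images` (named list of [reconstruct_image()] outputs,
#'   healthy-normalized) and `healthy_max`.
#' @export
make_fixtures <- function(seed = 1L, grid = freq_grid(0.5e9, 3.5e9, 64L),
                          image_px = 32L) {
  design <- list(
    set_A = list(diameters = c(4, 8, 12, 20, 36, 48), offset = 0),
    set_B = NULL, set_C = NULL
  )
  ds <- generate_dataset(design, grid = grid, seed = seed)
  calib <- lapply(ds$cases, function(cs)
    remove_skin_artifact(calibrate(cs$body, cs$empty)))
  feats <- feature_table(calib, ds$manifest)
  belt <- ds$cases[[1]]$belt
  px <- default_pixel_grid(ds$cases[[1]]$scenario, image_px)
  bg <- ds$cases[[1]]$scenario$background
  healthy <- healthy_reference(ds$cases[[1]]$scenario, belt, grid, px)
  images <- lapply(calib, function(sw) {
    normalize_to_reference(reconstruct_image(sw, belt, px, bg),
                           healthy$healthy_max)
  })
  list(manifest = ds$manifest, cases = ds$cases, calibrated = calib,
       features = feats, images = images, healthy_max = healthy$healthy_max)
}
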