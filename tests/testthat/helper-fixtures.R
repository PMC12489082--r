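# Shared fixtures, built once per test run and cached.

.cache <- new.env(parent = emptyenv())

# 12-case miniature dataset (64-point grid, 32 px reconstructions)
get_fixtures <- function() {
  if (is.null(.cache$fx)) .cache$fx <- make_fixtures(seed = 1)
  .cache$fx
}

# default smoke-profile study at seed 0 (the parameter-recovery run)
get_smoke_run <- function() {
  if (is.null(.cache$run)) .cache$run <- run_all(run_config("smoke", seed = 0))
  .cache$run
}

# small tumor scenario on the default phantom
tumor_scenario <- function(diameter_mm = 20, side = "left", offset = 0,
                           sigma_bg = 0.7) {
  sc0 <- torso_scenario()
  torso_scenario(
    background = tissue_dielectric(35, sigma_bg),
    tumor = list(center = sc0$lung_centers[side, ],
                 diameter_mm = diameter_mm),
    belt_offset_mm = offset
  )
}

# random reciprocal complex sweep
random_sweep <- function(grid = freq_grid(1e9, 3e9, 8), na = 8, seed = 42,
                         kind = "body") {
  set.seed(seed)
  v <- array(complex(real = rnorm(grid$n_points * na * na),
                     imaginary = rnorm(grid$n_points * na * na)),
             dim = c(grid$n_points, na, na))
  v <- (v + aperm(v, c(1, 3, 2))) / 2
  mwi_sweep(grid, v, kind = kind)
}

# tiny labeled table with well-separated classes in 128 dims
separated_table <- function(n0 = 20, n1 = 20, gap = 10, seed = 7) {
  set.seed(seed)
  x <- rbind(matrix(rnorm(n0 * 128), n0),
             matrix(rnorm(n1 * 128, mean = gap), n1))
  labeled_table(x, c(rep(0, n0), rep(1, n1)),
                sprintf("case%03d", seq_len(n0 + n1)))
}
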