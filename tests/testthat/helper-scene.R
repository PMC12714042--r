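# Shared fixture builders: a small default optical scene and compact
# mosaic geometries used across the module tests.

test_grid <- function(step = 0.1) wavelength_grid(555, 605, step)

test_filters <- function(grid = test_grid()) {
  list(A = make_passband(583, 598, peak = 0.85, edge_width = 4.5, grid = grid),
       AB = make_passband(562, 598, peak = 0.85, edge_width = 4.5, grid = grid))
}

test_scene <- function(step = 0.1) {
  grid <- test_grid(step)
  f <- test_filters(grid)
  list(grid = grid, filter_A = f$A, filter_AB = f$AB, dip = dip_model())
}

# ideal unit-rectangle "filter" on a grid restricted to the band itself,
# so the trapezoid over the grid is exactly the integral over the band
rect_band_spectrum <- function(lo, hi, step = 0.02) {
  g <- wavelength_grid(lo, hi, step)
  new_spectrum(g, rep(1, length(g$values)))
}

unclass_mat <- function(x) matrix(as.numeric(x), nrow(x), ncol(x))

small_config <- function(seed = 1L, n_tiles = 8L, states = c(1.333, 1.341, 1.3495),
                         state_duration_s = 200, frame_period_s = 20) {
  cfg <- default_run_config(seed)
  cfg$scene$geometry$n_tiles_x <- n_tiles
  cfg$scene$geometry$n_tiles_y <- n_tiles
  cfg$scene$protocol$levels <- states
  cfg$scene$protocol$state_duration_s <- state_duration_s
  cfg$scene$frame_period_s <- frame_period_s
  cfg$spectrometer$period_s <- 50
  cfg
}
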