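# In-code fixtures shared across the suite.

pet_grid <- function(shape = c(12, 12, 12))
  image_grid(shape, c(2.8, 2.8, 2.0))

# small phantom configuration: a compact GTV so fits and Monte-Carlo loops
# stay fast; geometry stays on the PET grid
small_phantom_config <- function(seed = 1L, noise = list(), ...) {
  phantom_config(
    grid = image_grid(c(16, 16, 18), c(2.8, 2.8, 2.0)),
    gtv_semiaxes_mm = c(14, 14, 11),
    seed = seed, noise = noise, ...)
}

constant_map <- function(grid, value, unit = "a.u.", name = "const")
  parametric_map(grid, array(value, grid$shape), unit, name)

# aligned box mask: voxel index ranges given as 1-based inclusive triples
box_mask <- function(grid, from, to, label = "GTV") {
  m <- array(FALSE, grid$shape)
  m[from[1]:to[1], from[2]:to[2], from[3]:to[3]] <- TRUE
  roi_mask(grid, m, label)
}

# uniform-frame series from a voxel x frame value matrix
series_from_matrix <- function(grid, vals, dt, unit = "kBq/mL",
                               name = "dyn") {
  nt <- ncol(vals)
  dynamic_series(grid, array(vals, c(grid$shape, nt)),
                 frame_starts = (seq_len(nt) - 1) * dt,
                 frame_durations = dt, unit = unit, name = name)
}
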