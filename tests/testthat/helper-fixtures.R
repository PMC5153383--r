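# Shared fixtures: everything is generated in code at test time.

cube_grid <- function(n, h = 2, centered = FALSE) {
  origin <- if (centered) -(n - 1) / 2 * h * c(1, 1, 1) else c(0, 0, 0)
  voxel_grid(c(n, n, n), h, origin)
}

# radial distance array from the grid centre
radius_array <- function(grid) {
  ctr <- grid$origin + (grid$shape - 1) / 2 * grid$spacing
  x <- array(voxel_centers(grid, 1), grid$shape)
  y <- array(rep(voxel_centers(grid, 2), each = grid$shape[1]), grid$shape)
  z <- array(rep(voxel_centers(grid, 3),
                 each = grid$shape[1] * grid$shape[2]), grid$shape)
  sqrt((x - ctr[1])^2 + (y - ctr[2])^2 + (z - ctr[3])^2)
}

ball_mask <- function(grid, radius_mm, center_offset = c(0, 0, 0)) {
  ctr <- grid$origin + (grid$shape - 1) / 2 * grid$spacing + center_offset
  x <- array(voxel_centers(grid, 1), grid$shape)
  y <- array(rep(voxel_centers(grid, 2), each = grid$shape[1]), grid$shape)
  z <- array(rep(voxel_centers(grid, 3),
                 each = grid$shape[1] * grid$shape[2]), grid$shape)
  label_mask((x - ctr[1])^2 + (y - ctr[2])^2 + (z - ctr[3])^2 <= radius_mm^2,
             grid)
}

# independent rank-definition oracle for Dxx/V100/Davg/Dmax
metrics_oracle <- function(doses) {
  ds <- sort(doses, decreasing = TRUE)
  n <- length(ds)
  list(d_avg = mean(doses), d_max = max(doses),
       d50 = ds[ceiling(0.5 * n)], d70 = ds[ceiling(0.7 * n)],
       d90 = ds[ceiling(0.9 * n)], v100 = 100 * sum(doses > 100) / n)
}

# geometric stand-in for the bioheat simulator: a spherical kill zone
# centred on the active-tip midpoint whose radius grows with duration
fake_zone_predictor <- function(dose_grid, r0 = 6, r600 = 16) {
  function(electrode, duration) {
    ctr <- electrode$tip_position -
      electrode$active_length / 2 * electrode$direction
    r <- r0 + (r600 - r0) * duration / 600
    x <- array(voxel_centers(dose_grid, 1), dose_grid$shape)
    y <- array(rep(voxel_centers(dose_grid, 2), each = dose_grid$shape[1]),
               dose_grid$shape)
    z <- array(rep(voxel_centers(dose_grid, 3),
                   each = dose_grid$shape[1] * dose_grid$shape[2]),
               dose_grid$shape)
    label_mask((x - ctr[1])^2 + (y - ctr[2])^2 + (z - ctr[3])^2 <= r^2,
               dose_grid)
  }
}

# small phantom spec that generates quickly on a 48^3 grid
small_phantom_spec <- function(seed, ...) {
  phantom_spec(seed = seed, grid = cube_grid(48, 2),
               tumor_volume = 60, cold_diameter = 22,
               infused_activity = 1.0, target_davg = 120, ...)
}
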