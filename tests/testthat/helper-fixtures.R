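# shared synthetic fixtures, all built in code

# plus-sign polyomino extruded one voxel: body 5, hull 7 (octagon x height 1)
plus_prism <- function() {
  cbind(z = 0L, y = c(1L, 0L, 1L, 2L, 1L), x = c(0L, 1L, 1L, 1L, 2L))
}

# filled box of voxels with the given (z, y, x) extents
box_voxels <- function(nz, ny, nx) {
  as.matrix(expand.grid(z = seq_len(nz) - 1L, y = seq_len(ny) - 1L,
                        x = seq_len(nx) - 1L))
}

# voxelized ball of the given radius (voxel units)
ball_voxels <- function(r) {
  g <- as.matrix(expand.grid(z = -r:r, y = -r:r, x = -r:r))
  g[rowSums(g^2) <= r^2, , drop = FALSE] + r
}

# three well-separated ellipsoids in a small grid
small_morph_spec <- function(noise_sd = 0, seed = 1) {
  cells <- list(
    cell_truth(c(15, 15, 12), c(5, 5, 5), c(1, 0, 0), 2),
    cell_truth(c(45, 15, 12), c(5, 10, 5), c(0, 2, 0), 2),
    cell_truth(c(30, 45, 12), c(8, 5, 5), c(0, 0, 1), 2))
  morph_stack_spec(grid_shape = c(24, 64, 64), voxel_pitch_um = 1,
                   cells = cells, background_level = 0.05,
                   noise_sd = noise_sd, blur_sigma_um = 0.5, seed = seed)
}

small_morph_config <- function() {
  morph_config(downsample_factor = 1, blur_sigma_px = 1, unit_to_um = 1)
}

# one bright static cell plus dark background, tiny and fast
small_movie_spec <- function(events = NULL, noise_sd = 0, seed = 1,
                             duration_s = 60) {
  cells <- data.frame(center_x_px = 24, center_y_px = 24, radius_px = 8,
                      baseline_F = 200)
  calcium_movie_spec(frame_shape = c(48, 48), cells = cells, events = events,
                     background_F = 100, noise_sd = noise_sd, seed = seed,
                     duration_s = duration_s)
}

fast_calcium_config <- function(...) {
  calcium_config(downsample_factor = 1, ...)
}

# connected components of a voxel set under ~1-neighbourhood adjacency,
# via DBSCAN with min_samples = 1 (every point is core)
n_components <- function(vox) {
  lab <- dbscan_voxels(vox, eps = 1.8, min_samples = 1)
  length(unique(lab[lab > 0]))
}
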