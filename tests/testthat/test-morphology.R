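test_that("preprocessing isolates a bright cube exactly when bimodal", {
  arr <- array(10, dim = c(30, 30, 30))
  arr[5:24, 5:24, 5:24] <- 200
  stack <- structure(list(channels = list(membrane = arr, nucleus = arr),
                          voxel_pitch_um = 1), class = "volumetric_image")
  cfg <- morph_config(downsample_factor = 1, blur_sigma_px = 0)
  clouds <- preprocess_stack(stack, cfg)
  expect_equal(nrow(clouds$cell_cloud$coords), 20^3)
  expect_true(all(clouds$cell_cloud$coords >= 4 & clouds$cell_cloud$coords <= 23))
})

test_that("single-valued channels raise a degenerate-input error", {
  arr <- array(0, dim = c(8, 8, 8))
  stack <- structure(list(channels = list(membrane = arr, nucleus = arr),
                          voxel_pitch_um = 1), class = "volumetric_image")
  expect_error(preprocess_stack(stack, morph_config()), "membrane")
})

test_that("downsampling a cube shrinks it by the block factor", {
  arr <- array(0, dim = c(48, 48, 48))
  arr[5:44, 5:44, 5:44] <- 200
  stack <- structure(list(channels = list(membrane = arr, nucleus = arr),
                          voxel_pitch_um = 1), class = "volumetric_image")
  cfg <- morph_config(downsample_factor = 2, blur_sigma_px = 1)
  clouds <- preprocess_stack(stack, cfg)
  n <- nrow(clouds$cell_cloud$coords)
  # a 40-voxel cube pooled 2x is ~20^3, give or take a 1-voxel blur halo
  expect_gte(n, 18^3)
  expect_lte(n, 22^3)
})

test_that("volumetric filters drop strictly-below-threshold components", {
  mk <- function(n) {
    g <- box_voxels(8, 8, 8)[seq_len(n), , drop = FALSE]
    segmented_cell(g, cell_id = n)
  }
  cfg <- morph_config()
  out <- filter_components(list(mk(49), mk(50), mk(200)),
                           list(mk(4), mk(5)), cfg)
  expect_equal(vapply(out$cells, function(s) s$volume_units, numeric(1)),
               c(50, 200))
  expect_equal(out$dropped_cells, 1)
  expect_equal(vapply(out$nuclei, function(s) s$volume_units, numeric(1)), 5)
  expect_equal(out$dropped_nuclei, 1)
})

test_that("nucleus matching: containment, fallback, ties, and misses", {
  cell1 <- segmented_cell(box_voxels(6, 6, 6), cell_id = 1)
  cell2 <- segmented_cell(sweep(box_voxels(6, 6, 6), 2, c(0L, 0L, 30L), "+"),
                          cell_id = 2)
  nuc_inside <- segmented_cell(sweep(box_voxels(2, 2, 2), 2, c(2L, 2L, 2L), "+"))
  m <- match_nuclei(list(cell1, cell2), list(nuc_inside), morph_config())
  expect_equal(m$nucleus_idx[m$cell_id == 1], 1)
  expect_true(is.na(m$nucleus_idx[m$cell_id == 2]))
  # equidistant nucleus between the two cells: containment fails,
  # tie broken towards the lower cell_id, decision logged
  nuc_mid <- segmented_cell(sweep(box_voxels(2, 2, 2), 2, c(2L, 14L, 17L), "+"))
  expect_message(
    m2 <- match_nuclei(list(cell1, cell2), list(nuc_mid), morph_config()),
    "equidistant")
  expect_equal(m2$nucleus_idx[m2$cell_id == 1], 1)
  # nucleus beyond the matching radius stays unmatched
  far <- segmented_cell(sweep(box_voxels(2, 2, 2), 2, c(0L, 0L, 500L), "+"))
  m3 <- match_nuclei(list(cell1), list(far), morph_config())
  expect_true(is.na(m3$nucleus_idx))
})

test_that("aspect ratio is range_y over range_x", {
  ball <- segmented_cell(ball_voxels(6))
  expect_equal(aspect_ratio(ball), 1.0)
  slab <- segmented_cell(box_voxels(2, 20, 10))
  expect_equal(aspect_ratio(slab), 2.0)
  single <- segmented_cell(matrix(c(3L, 4L, 5L), 1))
  expect_equal(aspect_ratio(single), 1.0)
})

test_that("circularity follows the fitted-ellipse closed form", {
  cfg <- morph_config()
  mk <- function(ny, nx) segmented_cell(box_voxels(1, ny, nx))
  expect_equal(circularity(mk(7, 7), cfg), 1.0)
  expect_equal(circularity(mk(2, 4), cfg), 0.8)    # 2XY/(X^2+Y^2), X=2 Y=1
  expect_equal(circularity(mk(1, 10), cfg), 20 / 101)
  # projected-area mode: 4 pi A / P_e^2 with the true area
  cfg2 <- morph_config(circularity_mode = "projected_area")
  cell <- mk(2, 4)
  Pe <- 2 * pi * sqrt((2^2 + 1^2) / 2)
  expect_equal(circularity(cell, cfg2), 4 * pi * 8 / Pe^2)
})

test_that("centroid distance is Euclidean with unit conversion", {
  a <- segmented_cell(matrix(c(0L, 0L, 0L), 1))
  b <- segmented_cell(matrix(c(0L, 3L, 4L), 1))
  cfg <- morph_config(unit_to_um = 0.62)
  expect_equal(as.numeric(centroid_distance(a, b, cfg)), 5.0)
  expect_equal(attr(centroid_distance(a, b, cfg), "um"), 3.1)
  expect_equal(as.numeric(centroid_distance(a, a, cfg)), 0)
})

test_that("solidity is hull volume over body volume, >= 1", {
  expect_equal(solidity(segmented_cell(box_voxels(4, 6, 5))), 1.0)
  # plus-sign prism: hull area by shoelace on the known octagon, x height 1
  oct <- rbind(c(1, 0), c(2, 0), c(3, 1), c(3, 2), c(2, 3), c(1, 3),
               c(0, 2), c(0, 1))
  shoelace <- abs(sum(oct[, 1] * oct[c(2:8, 1), 2] -
                        oct[c(2:8, 1), 1] * oct[, 2])) / 2
  expect_equal(shoelace, 7)
  expect_equal(solidity(segmented_cell(plus_prism())), shoelace / 5)
})

test_that("ramification normalises the hull perimeter to a circle", {
  # square face: R = 2 / sqrt(pi)
  expect_equal(ramification(segmented_cell(box_voxels(2, 10, 10))),
               2 / sqrt(pi), tolerance = 1e-12)
  # disk projection: R ~ 1 (within voxelization error)
  r <- 30L
  g <- as.matrix(expand.grid(y = -r:r, x = -r:r))
  disk <- cbind(z = 0L, g[rowSums(g^2) <= r^2, , drop = FALSE] + r)
  expect_equal(ramification(segmented_cell(disk)), 1.0, tolerance = 0.03)
})

test_that("QC excludes flagged records and Grubbs outliers", {
  base <- data.frame(cell_id = 1:5, volume_units = 100, hull_volume_units = 100,
                     aspect_ratio = c(8, 9, 10, 50, 9.5), circularity = 0.8,
                     centroid_distance_units = c(10, 20, 30, 25, 120),
                     centroid_distance_um = NA, solidity = 1.2,
                     ramification = 1.1, nucleus_idx = 1:5,
                     qc_flags = c("", "", "", "", "centroid_out_of_range"))
  qc <- apply_qc(base, morph_config())
  expect_true(5 %in% qc$excluded$cell_id)       # flagged at scoring time
  expect_true(4 %in% qc$excluded$cell_id)       # Grubbs on {8,9,10,50,9.5}
  expect_match(qc$excluded$qc_flags[qc$excluded$cell_id == 4],
               "grubbs_outlier")
  expect_setequal(qc$kept$cell_id, c(1, 2, 3))
  # Grubbs skipped with a warning below 3 clean records
  expect_warning(apply_qc(base[1:2, ], morph_config()), "fewer than 3")
  # zero-variance metrics exclude nothing
  flat <- base
  flat$aspect_ratio <- 1
  flat$qc_flags <- ""
  flat$centroid_distance_units <- 10
  qc2 <- apply_qc(flat, morph_config())
  expect_equal(nrow(qc2$excluded), 0)
})

test_that("pipeline recovers disjoint ellipsoids with true geometry", {
  sim <- generate_morphology_stack(small_morph_spec())
  res <- analyze_morphology(sim$stack, small_morph_config())
  expect_equal(length(res$cells), 3)
  expect_equal(sum(!is.na(res$matches$nucleus_idx)), 3)
  # cells come out sorted by centroid; truth cells are laid out to match
  truth <- sim$truth[order(sim$truth$centroid_z_um, sim$truth$centroid_y_um,
                           sim$truth$centroid_x_um), ]
  ar_est <- vapply(res$cells, aspect_ratio, numeric(1))
  ar_true <- truth$range_y_um / truth$range_x_um
  expect_equal(ar_est, ar_true, tolerance = 0.1)
  cd_err <- abs(res$matches$distance_units - truth$centroid_distance_um)
  expect_true(all(cd_err < 1))
})

test_that("identical stack and config give identical records", {
  sim <- generate_morphology_stack(small_morph_spec(noise_sd = 0.02, seed = 5))
  r1 <- analyze_morphology(sim$stack, small_morph_config())
  r2 <- analyze_morphology(sim$stack, small_morph_config())
  expect_identical(r1$records, r2$records)
})

test_that("shape invariants hold across random voxel bodies", {
  set.seed(21)
  cfg <- morph_config()
  for (rep in 1:8) {
    nz <- sample(2:6, 1); ny <- sample(3:12, 1); nx <- sample(3:12, 1)
    cell <- segmented_cell(box_voxels(nz, ny, nx))
    expect_gte(solidity(cell), 1 - 1e-9)
    expect_lte(solidity(cell), 1.02)          # convex body
    co <- circularity(cell, cfg)
    expect_gt(co, 0); expect_lte(co, 1)
    expect_gte(ramification(cell), 1 - 0.02)  # isoperimetric bound on hulls
    # circularity symmetric under X<->Y swap
    swapped <- segmented_cell(box_voxels(nz, nx, ny))
    expect_equal(circularity(swapped, cfg), co, tolerance = 1e-12)
    expect_equal(aspect_ratio(swapped), 1 / aspect_ratio(cell),
                 tolerance = 1e-12)
  }
  # corner-point hulls circumscribe: a radius-r ball's hull behaves like
  # a polyhedral (r + 0.5) ball, so solidity converges to 1 only as ~1.5/r
  ball <- segmented_cell(ball_voxels(7))
  expect_gte(solidity(ball), 1)
  expect_lte(solidity(ball), (1 + 1.5 / 7)^3)
})
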