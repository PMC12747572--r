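#' Configuration for the 3D morphometry pipeline
#'
#' Defaults follow the pipeline's working conventions: Otsu thresholding
#' after a 2-pixel Gaussian blur, 4x majority-vote downsampling (one
#' downsampled voxel edge is the "unit"), DBSCAN with eps = 2 units and
#' min_samples = 10, volumetric filters at 50 cell units / 5 nucleus units,
#' a 100-unit cap on nucleus-to-body centroid distance, and 0.62 um per
#' unit so that 100 units is about 62 um and a 50-unit volume about 12 um^3.
#'
#' @param blur_sigma_px in-plane Gaussian blur sigma (pixels).
#' @param threshold_method `"otsu"` (default) or `"fixed"`.
#' @param fixed_threshold threshold on the normalised [0, 1] intensity used
#'   when `threshold_method = "fixed"`.
#' @param downsample_factor integer block edge for majority-vote pooling.
#' @param dbscan_eps,dbscan_min_samples DBSCAN parameters in voxel units.
#' @param min_cell_volume_units,min_nucleus_volume_units volumetric filters;
#'   components strictly below these voxel counts are discarded.
#' @param max_centroid_distance_units QC cap on the body-to-nucleus centroid
#'   distance (also the nucleus matching radius).
#' @param unit_to_um micrometres per downsampled voxel edge.
#' @param grubbs_alpha two-sided significance level of the iterative Grubbs
#'   outlier screen.
#' @param circularity_mode `"ellipse"` (area and perimeter both from the
#'   range-fitted ellipse) or `"projected_area"` (true projected area over
#'   the ellipse perimeter).
#' @return object of class `morph_config`.
#' @export
morph_config <- function(blur_sigma_px = 2, threshold_method = c("otsu", "fixed"),
                         fixed_threshold = NULL, downsample_factor = 4,
                         dbscan_eps = 2, dbscan_min_samples = 10,
                         min_cell_volume_units = 50, min_nucleus_volume_units = 5,
                         max_centroid_distance_units = 100, unit_to_um = 0.62,
                         grubbs_alpha = 0.05,
                         circularity_mode = c("ellipse", "projected_area")) {
  threshold_method <- match.arg(threshold_method)
  circularity_mode <- match.arg(circularity_mode)
  stopifnot(downsample_factor >= 1, dbscan_eps > 0, dbscan_min_samples >= 1,
            min_cell_volume_units > 0, min_nucleus_volume_units > 0,
            max_centroid_distance_units > 0, unit_to_um > 0,
            grubbs_alpha > 0, grubbs_alpha < 1, blur_sigma_px >= 0)
  if (threshold_method == "fixed" && is.null(fixed_threshold))
    stop("fixed_threshold required when threshold_method = 'fixed'")
  structure(list(blur_sigma_px = blur_sigma_px,
                 threshold_method = threshold_method,
                 fixed_threshold = fixed_threshold,
                 downsample_factor = as.integer(downsample_factor),
                 dbscan_eps = dbscan_eps,
                 dbscan_min_samples = dbscan_min_samples,
                 min_cell_volume_units = min_cell_volume_units,
                 min_nucleus_volume_units = min_nucleus_volume_units,
                 max_centroid_distance_units = max_centroid_distance_units,
                 unit_to_um = unit_to_um, grubbs_alpha = grubbs_alpha,
                 circularity_mode = circularity_mode),
            class = "morph_config")
}

#' Voxel cloud constructor
#'
#' Deduplicates and sorts coordinates lexicographically (z, y, x) so that
#' all downstream labelling is independent of input order.
#'
#' @param coords integer matrix, columns (z, y, x), 0-based.
#' @param channel `"cell"` or `"nucleus"`.
#' @return object of class `voxel_cloud`.
#' @export
voxel_cloud <- function(coords, channel = c("cell", "nucleus")) {
  channel <- match.arg(channel)
  coords <- unique(as.matrix(coords))
  storage.mode(coords) <- "integer"
  if (ncol(coords) != 3) stop("coords must have 3 columns (z, y, x)")
  if (nrow(coords))
    coords <- coords[order(coords[, 1], coords[, 2], coords[, 3]), ,
                     drop = FALSE]
  colnames(coords) <- c("z", "y", "x")
  structure(list(coords = coords, channel = channel), class = "voxel_cloud")
}

## majority-vote block pooling of a logical (Z, Y, X) array; blocks with
## occupancy >= 0.5 are occupied. Trailing partial blocks are dropped.
downsample_binary <- function(bin, f) {
  if (f == 1) return(bin)
  d <- dim(bin) %/% f
  if (any(d == 0)) stop("grid smaller than one downsampling block")
  bin <- bin[seq_len(d[1] * f), seq_len(d[2] * f), seq_len(d[3] * f),
             drop = FALSE]
  a <- array(as.numeric(bin), dim = c(f, d[1], f, d[2], f, d[3]))
  occ <- apply(a, c(2, 4, 6), mean)
  occ >= 0.5
}

#' Preprocess a two-channel stack into binary voxel clouds
#'
#' Per channel: min-max contrast normalisation to [0, 1], per-slice Gaussian
#' blur, thresholding (Otsu on the full volume histogram by default), then
#' majority-vote downsampling into the "unit" grid.
#'
#' @param stack a `volumetric_image` with `membrane` and `nucleus` channels.
#' @param cfg a [morph_config()].
#' @return list with `cell_cloud` and `nucleus_cloud` ([voxel_cloud()]s).
#' @export
preprocess_stack <- function(stack, cfg = morph_config()) {
  stopifnot(inherits(stack, "volumetric_image"))
  if (!all(c("membrane", "nucleus") %in% names(stack$channels)))
    stop("stack must carry membrane and nucleus channels")
  one <- function(name, channel_kind) {
    arr <- stack$channels[[name]]
    rng <- range(arr)
    if (rng[1] == rng[2])
      stop(sprintf("degenerate input: channel '%s' is single-valued", name))
    arr <- (arr - rng[1]) / (rng[2] - rng[1])
    arr <- blur_stack(arr, cfg$blur_sigma_px)
    arr[arr < 0] <- 0; arr[arr > 1] <- 1
    thr <- if (cfg$threshold_method == "otsu")
      EBImage::otsu(matrix(arr, nrow = dim(arr)[2]), range = c(0, 1))
    else cfg$fixed_threshold
    bin <- arr > thr
    bin <- downsample_binary(bin, cfg$downsample_factor)
    idx <- which(bin, arr.ind = TRUE)
    voxel_cloud(idx - 1L, channel_kind)
  }
  list(cell_cloud = one("membrane", "cell"),
       nucleus_cloud = one("nucleus", "nucleus"))
}

#' Materialise a segmented cell from its voxel set
#'
#' Computes voxel count, inclusive axis ranges (max - min + 1), the centroid
#' of the voxel cube centres, the convex hull volume over voxel-cube corner
#' points, and the three axis-aligned projections with their areas and hull
#' perimeters.
#'
#' @param vox integer matrix of voxel indices, columns (z, y, x).
#' @param cell_id identifier stored on the object.
#' @return object of class `segmented_cell`.
#' @export
segmented_cell <- function(vox, cell_id = NA_integer_) {
  vox <- unique(as.matrix(vox))
  if (!nrow(vox)) stop("empty voxel set")
  storage.mode(vox) <- "integer"
  colnames(vox) <- c("z", "y", "x")
  rng <- apply(vox, 2, function(v) max(v) - min(v) + 1L)
  centroid <- colMeans(vox) + 0.5
  hull_vol <- voxel_hull_volume(boundary_voxels(vox))
  proj <- list(
    xy = project_cells(vox[, c("y", "x"), drop = FALSE]),
    xz = project_cells(vox[, c("z", "x"), drop = FALSE]),
    yz = project_cells(vox[, c("z", "y"), drop = FALSE]))
  structure(list(cell_id = cell_id, voxels = vox,
                 volume_units = nrow(vox),
                 range_z = rng[["z"]], range_y = rng[["y"]], range_x = rng[["x"]],
                 centroid = centroid, hull_volume_units = hull_vol,
                 projections = proj),
            class = "segmented_cell")
}

## drop voxels whose 6 face neighbours are all present (they cannot carry
## hull vertices); keeps hull input small for compact bodies
boundary_voxels <- function(vox) {
  if (nrow(vox) <= 8) return(vox)
  key <- paste(vox[, 1], vox[, 2], vox[, 3])
  interior <- rep(TRUE, nrow(vox))
  for (d in list(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0), c(0, -1, 0),
                 c(0, 0, 1), c(0, 0, -1))) {
    nb <- sweep(vox, 2, d, "+")
    interior <- interior & (paste(nb[, 1], nb[, 2], nb[, 3]) %in% key)
  }
  if (all(interior)) vox else vox[!interior, , drop = FALSE]
}

project_cells <- function(pix2) {
  pix2 <- unique(pix2)
  list(pixels = pix2, area = nrow(pix2),
       hull_perimeter = pixel_hull_perimeter(pix2))
}

#' Segment a voxel cloud into individual cells with DBSCAN
#'
#' Noise-labelled voxels are discarded; clusters are materialised as
#' [segmented_cell()] objects sorted by lexicographic centroid so the output
#' is deterministic.
#'
#' @param cloud a [voxel_cloud()].
#' @param cfg a [morph_config()].
#' @return list of `segmented_cell` objects (empty, with a warning, for an
#'   empty cloud).
#' @export
segment_cells <- function(cloud, cfg = morph_config()) {
  stopifnot(inherits(cloud, "voxel_cloud"))
  if (!nrow(cloud$coords)) {
    warning("empty voxel cloud: no cells segmented")
    return(list())
  }
  labels <- dbscan_voxels(cloud$coords, cfg$dbscan_eps, cfg$dbscan_min_samples)
  coords <- attr(labels, "coords")
  ids <- sort(unique(labels[labels > 0]))
  cells <- lapply(ids, function(k)
    segmented_cell(coords[labels == k, , drop = FALSE]))
  cen <- t(vapply(cells, function(s) s$centroid, numeric(3)))
  ord <- order(cen[, 1], cen[, 2], cen[, 3])
  cells <- cells[ord]
  for (i in seq_along(cells)) cells[[i]]$cell_id <- i
  cells
}

#' Volumetric filtering of segmented components
#'
#' Cells strictly below `min_cell_volume_units` and nuclei strictly below
#' `min_nucleus_volume_units` are considered non-cell fragments and dropped;
#' the boundary value itself is retained.
#'
#' @param cells,nuclei lists of [segmented_cell()] objects.
#' @param cfg a [morph_config()].
#' @return list with `cells`, `nuclei`, and the dropped counts.
#' @export
filter_components <- function(cells, nuclei, cfg = morph_config()) {
  keep_c <- vapply(cells, function(s)
    s$volume_units >= cfg$min_cell_volume_units, logical(1))
  keep_n <- vapply(nuclei, function(s)
    s$volume_units >= cfg$min_nucleus_volume_units, logical(1))
  list(cells = cells[keep_c], nuclei = nuclei[keep_n],
       dropped_cells = sum(!keep_c), dropped_nuclei = sum(!keep_n))
}

#' Match nuclei to cell bodies
#'
#' A nucleus belongs to the cell whose voxel set contains its centroid
#' voxel; failing containment, to the nearest cell centroid within
#' `max_centroid_distance_units`. Each cell receives at most one nucleus
#' (the nearest by centroid distance; ties go to the lower nucleus index,
#' and equidistant cells to the lower cell_id, with a message).
#'
#' @param cells,nuclei filtered lists of [segmented_cell()] objects.
#' @param cfg a [morph_config()].
#' @return data.frame with `cell_id`, `nucleus_idx` (NA when unmatched) and
#'   the matching distance in units.
#' @export
match_nuclei <- function(cells, nuclei, cfg = morph_config()) {
  if (!length(cells))
    return(data.frame(cell_id = integer(), nucleus_idx = integer(),
                      distance_units = numeric()))
  cell_keys <- lapply(cells, function(s)
    paste(s$voxels[, 1], s$voxels[, 2], s$voxels[, 3]))
  cell_cent <- t(vapply(cells, function(s) s$centroid, numeric(3)))
  claims <- data.frame(nucleus_idx = integer(), cell = integer(),
                       dist = numeric())
  for (ni in seq_along(nuclei)) {
    nc <- nuclei[[ni]]$centroid
    vox_key <- paste(floor(nc[1]), floor(nc[2]), floor(nc[3]))
    inside <- which(vapply(cell_keys, function(k) vox_key %in% k, logical(1)))
    if (length(inside) >= 1) {
      target <- inside[1]
    } else {
      d <- sqrt(rowSums(sweep(cell_cent, 2, nc)^2))
      if (min(d) > cfg$max_centroid_distance_units) next
      target <- which(d == min(d))
      if (length(target) > 1)
        message(sprintf("nucleus %d equidistant from cells %s; assigning to cell %d",
                        ni, paste(target, collapse = ", "), min(target)))
      target <- min(target)
    }
    dist <- sqrt(sum((cell_cent[target, ] - nc)^2))
    claims <- rbind(claims, data.frame(nucleus_idx = ni, cell = target,
                                       dist = dist))
  }
  out <- data.frame(cell_id = vapply(cells, function(s) s$cell_id, numeric(1)),
                    nucleus_idx = NA_integer_, distance_units = NA_real_)
  for (ci in seq_along(cells)) {
    cl <- claims[claims$cell == ci, , drop = FALSE]
    if (!nrow(cl)) next
    cl <- cl[order(cl$dist, cl$nucleus_idx), , drop = FALSE]
    out$nucleus_idx[ci] <- cl$nucleus_idx[1]
    out$distance_units[ci] <- cl$dist[1]
  }
  out
}

#' Aspect ratio: maximum Y range over maximum X range
#' @param cell a [segmented_cell()].
#' @return dimensionless ratio.
#' @export
aspect_ratio <- function(cell) cell$range_y / cell$range_x

#' Circularity of a cell
#'
#' With semi-axes `X = range_x / 2` and `Y = range_y / 2`, the fitted
#' ellipse has area `pi * X * Y` and perimeter
#' `2 * pi * sqrt((X^2 + Y^2) / 2)`, giving
#' `C = 4 * pi * A / P^2 = 2 X Y / (X^2 + Y^2)` in `"ellipse"` mode.
#' `"projected_area"` mode keeps the ellipse perimeter but uses the true XY
#' projected area.
#'
#' @param cell a [segmented_cell()].
#' @param cfg a [morph_config()] (selects the mode).
#' @return dimensionless circularity, 1 for `X == Y` in ellipse mode.
#' @export
circularity <- function(cell, cfg = morph_config()) {
  X <- cell$range_x / 2; Y <- cell$range_y / 2
  if (cfg$circularity_mode == "ellipse") {
    2 * X * Y / (X^2 + Y^2)
  } else {
    Pe <- 2 * pi * sqrt((X^2 + Y^2) / 2)
    4 * pi * cell$projections$xy$area / Pe^2
  }
}

#' Euclidean distance between cell-body and nucleus centroids
#'
#' @param cell,nucleus matched [segmented_cell()] objects.
#' @param cfg a [morph_config()] (provides the unit-to-um conversion).
#' @return distance in units, with the um value as attribute `"um"`.
#' @export
centroid_distance <- function(cell, nucleus, cfg = morph_config()) {
  d <- sqrt(sum((cell$centroid - nucleus$centroid)^2))
  structure(d, um = d * cfg$unit_to_um)
}

#' Solidity: convex hull volume over body volume
#'
#' Kept in the hull-over-body orientation, so values are always >= 1 and
#' equal 1 (up to voxelisation) for convex bodies. This is the reciprocal of
#' the more common area-fraction convention.
#'
#' @param cell a [segmented_cell()].
#' @return dimensionless ratio >= 1.
#' @export
solidity <- function(cell) cell$hull_volume_units / cell$volume_units

#' Ramification index of the maximum-area projection
#'
#' `R = (P / A) / (2 * sqrt(pi / A))` where A is the area of the largest
#' axis-aligned 2D projection and P the perimeter of that projection's
#' convex hull; R = 1 for a disk.
#'
#' @param cell a [segmented_cell()].
#' @return dimensionless index.
#' @export
ramification <- function(cell) {
  areas <- vapply(cell$projections, function(p) p$area, numeric(1))
  p <- cell$projections[[which.max(areas)]]  # ties: first of xy, xz, yz
  (p$hull_perimeter / p$area) / (2 * sqrt(pi / p$area))
}

#' Score matched cells into morphology records
#'
#' One row per cell with the five shape descriptors, unit and um centroid
#' distances, and QC flags accumulated so far (`no_nucleus`,
#' `centroid_out_of_range`, `boundary_abnormal` for non-finite metrics or
#' degenerate geometry).
#'
#' @param cells,nuclei filtered lists of [segmented_cell()] objects.
#' @param matches output of [match_nuclei()].
#' @param cfg a [morph_config()].
#' @return data.frame of morphology records.
#' @export
score_morphology <- function(cells, nuclei, matches, cfg = morph_config()) {
  rows <- lapply(seq_along(cells), function(i) {
    cell <- cells[[i]]
    m <- matches[matches$cell_id == cell$cell_id, , drop = FALSE]
    flags <- character(0)
    nid <- if (nrow(m)) m$nucleus_idx[1] else NA_integer_
    if (is.na(nid)) {
      flags <- c(flags, "no_nucleus")
      cd <- NA_real_
    } else {
      cd <- as.numeric(centroid_distance(cell, nuclei[[nid]], cfg))
      if (cd > cfg$max_centroid_distance_units)
        flags <- c(flags, "centroid_out_of_range")
    }
    metrics <- c(aspect_ratio = aspect_ratio(cell),
                 circularity = circularity(cell, cfg),
                 centroid_distance_units = cd,
                 solidity = solidity(cell),
                 ramification = ramification(cell))
    finite_needed <- metrics[setdiff(names(metrics), "centroid_distance_units")]
    if (any(!is.finite(finite_needed)) ||
        any(c(cell$range_x, cell$range_y, cell$range_z) < 1))
      flags <- c(flags, "boundary_abnormal")
    data.frame(cell_id = cell$cell_id,
               volume_units = cell$volume_units,
               hull_volume_units = cell$hull_volume_units,
               aspect_ratio = metrics[["aspect_ratio"]],
               circularity = metrics[["circularity"]],
               centroid_distance_units = cd,
               centroid_distance_um = cd * cfg$unit_to_um,
               solidity = metrics[["solidity"]],
               ramification = metrics[["ramification"]],
               nucleus_idx = nid,
               qc_flags = paste(flags, collapse = ";"))
  })
  do.call(rbind, rows)
}

#' Quality-control exclusion of morphology records
#'
#' Records carrying any flag are excluded outright; the iterative two-sided
#' Grubbs screen (at `grubbs_alpha`) is then applied per metric across the
#' remaining records, flagging at most one record per iteration until none
#' is significant. With fewer than 3 clean records the Grubbs step is
#' skipped with a warning. Zero-variance metrics are a no-op.
#'
#' @param records data.frame from [score_morphology()].
#' @param cfg a [morph_config()].
#' @return list with `kept` and `excluded` data.frames.
#' @export
apply_qc <- function(records, cfg = morph_config()) {
  flagged <- nzchar(records$qc_flags)
  clean <- records[!flagged, , drop = FALSE]
  metrics <- c("aspect_ratio", "circularity", "centroid_distance_units",
               "solidity", "ramification")
  if (nrow(clean) < 3) {
    if (nrow(clean) > 0)
      warning("fewer than 3 clean records: Grubbs outlier screen skipped")
  } else {
    for (m in metrics) {
      v <- clean[[m]]
      out_idx <- grubbs_test(v, alpha = cfg$grubbs_alpha)$outlier_indices
      if (length(out_idx)) {
        clean$qc_flags[out_idx] <- vapply(clean$qc_flags[out_idx], function(f)
          paste(c(if (nzchar(f)) f, "grubbs_outlier"), collapse = ";"), "")
      }
    }
    records[match(clean$cell_id, records$cell_id), "qc_flags"] <- clean$qc_flags
  }
  keep <- !nzchar(records$qc_flags)
  list(kept = records[keep, , drop = FALSE],
       excluded = records[!keep, , drop = FALSE])
}

#' Full morphometry pipeline on one stack
#'
#' Preprocess, segment both channels, filter by volume, match nuclei, score
#' the five descriptors, and apply QC.
#'
#' @param stack a `volumetric_image`.
#' @param cfg a [morph_config()].
#' @return list with `records` (kept), `excluded`, `cells`, `nuclei`,
#'   `matches`.
#' @export
analyze_morphology <- function(stack, cfg = morph_config()) {
  clouds <- preprocess_stack(stack, cfg)
  cells <- segment_cells(clouds$cell_cloud, cfg)
  nuclei <- segment_cells(clouds$nucleus_cloud, cfg)
  filt <- filter_components(cells, nuclei, cfg)
  matches <- match_nuclei(filt$cells, filt$nuclei, cfg)
  records <- score_morphology(filt$cells, filt$nuclei, matches, cfg)
  qc <- if (is.null(records) || !nrow(records))
    list(kept = records, excluded = records) else apply_qc(records, cfg)
  list(records = qc$kept, excluded = qc$excluded,
       cells = filt$cells, nuclei = filt$nuclei, matches = matches)
}
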