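#' Volume of the 3D convex hull of a point set
#'
#' Incremental quickhull with farthest-point insertion. The hull volume is
#' accumulated from signed tetrahedra between an interior point and each
#' facet, so the result is exact (to floating point) for the polytope spanned
#' by the input points.
#'
#' @param pts numeric matrix with 3 columns (one point per row).
#' @return hull volume (numeric scalar).
#' @export
convex_hull_volume <- function(pts) {
  pts <- unique(as.matrix(pts))
  storage.mode(pts) <- "double"
  if (ncol(pts) != 3) stop("pts must have 3 columns")
  if (nrow(pts) < 4) stop("need at least 4 non-degenerate points for a 3D hull")
  scale <- max(abs(pts), 1)
  eps <- 1e-9 * scale

  ## initial simplex: extremes along x, farthest from that segment, then plane
  i1 <- which.min(pts[, 1]); i2 <- which.max(pts[, 1])
  if (i1 == i2) { i1 <- which.min(pts[, 2]); i2 <- which.max(pts[, 2]) }
  d <- pts[i2, ] - pts[i1, ]
  rel <- sweep(pts, 2, pts[i1, ])
  cross_norm2 <- function(v, w) {
    cx <- v[, 2] * w[3] - v[, 3] * w[2]
    cy <- v[, 3] * w[1] - v[, 1] * w[3]
    cz <- v[, 1] * w[2] - v[, 2] * w[1]
    cx^2 + cy^2 + cz^2
  }
  i3 <- which.max(cross_norm2(rel, d))
  n0 <- cross3(pts[i2, ] - pts[i1, ], pts[i3, ] - pts[i1, ])
  if (sqrt(sum(n0^2)) < eps) stop("degenerate (collinear) point set")
  i4 <- which.max(abs(rel %*% n0))
  if (abs(sum((pts[i4, ] - pts[i1, ]) * n0)) < eps)
    stop("degenerate (coplanar) point set")

  interior <- colMeans(pts[c(i1, i2, i3, i4), ])
  facets <- list(c(i1, i2, i3), c(i1, i2, i4), c(i1, i3, i4), c(i2, i3, i4))
  facets <- lapply(facets, orient_facet, pts = pts, interior = interior)

  remaining <- setdiff(seq_len(nrow(pts)), c(i1, i2, i3, i4))
  repeat {
    if (length(remaining) == 0) break
    geo <- facet_geometry(facets, pts)
    dists <- pts[remaining, , drop = FALSE] %*% t(geo$normals) -
      rep(geo$offsets, each = length(remaining))
    maxd <- apply(dists, 1, max)
    inside <- maxd <= eps
    remaining <- remaining[!inside]
    if (length(remaining) == 0) break
    dists <- dists[!inside, , drop = FALSE]
    pick <- which.max(apply(dists, 1, max))
    p_idx <- remaining[pick]
    visible <- which(dists[pick, ] > eps)
    ## horizon = edges used by exactly one visible facet
    edges <- do.call(rbind, lapply(facets[visible], function(f)
      rbind(sort(f[c(1, 2)]), sort(f[c(2, 3)]), sort(f[c(1, 3)]))))
    key <- paste(edges[, 1], edges[, 2])
    horizon <- edges[key %in% names(which(table(key) == 1)), , drop = FALSE]
    facets <- facets[-visible]
    new_facets <- lapply(seq_len(nrow(horizon)), function(k)
      orient_facet(c(horizon[k, ], p_idx), pts, interior))
    facets <- c(facets, new_facets)
    remaining <- setdiff(remaining, p_idx)
  }

  vol <- 0
  for (f in facets) {
    a <- pts[f[1], ] - interior
    b <- pts[f[2], ] - interior
    c3 <- pts[f[3], ] - interior
    vol <- vol + det(rbind(a, b, c3)) / 6
  }
  abs(vol)
}

cross3 <- function(u, v) {
  c(u[2] * v[3] - u[3] * v[2], u[3] * v[1] - u[1] * v[3], u[1] * v[2] - u[2] * v[1])
}

## flip vertex order so the facet normal points away from the interior point
orient_facet <- function(f, pts, interior) {
  n <- cross3(pts[f[2], ] - pts[f[1], ], pts[f[3], ] - pts[f[1], ])
  if (sum(n * (interior - pts[f[1], ])) > 0) f[c(1, 3)] <- f[c(3, 1)]
  f
}

facet_geometry <- function(facets, pts) {
  normals <- t(vapply(facets, function(f) {
    n <- cross3(pts[f[2], ] - pts[f[1], ], pts[f[3], ] - pts[f[1], ])
    n / sqrt(sum(n^2))
  }, numeric(3)))
  offsets <- vapply(seq_along(facets), function(i)
    sum(normals[i, ] * pts[facets[[i]][1], ]), numeric(1))
  list(normals = normals, offsets = offsets)
}

#' Corner points of a set of unit voxels, thinned to hull candidates
#'
#' Treats each voxel index (z, y, x) as the unit cube [z, z+1] x [y, y+1] x
#' [x, x+1] and returns the cube corners that can appear on the convex hull:
#' for every (y, x) column only the lowest and highest z-corners are kept,
#' which is a superset of the hull vertices (any other corner lies strictly
#' inside a vertical segment between two corners of the set).
#'
#' @param vox integer matrix of voxel indices, columns (z, y, x).
#' @return numeric matrix of corner coordinates, columns (z, y, x).
#' @export
voxel_corner_points <- function(vox) {
  vox <- as.matrix(vox)
  offs <- as.matrix(expand.grid(dz = 0:1, dy = 0:1, dx = 0:1))
  corners <- do.call(rbind, lapply(seq_len(nrow(offs)), function(k)
    sweep(vox, 2, offs[k, ], "+")))
  corners <- unique(corners)
  key <- paste(corners[, 2], corners[, 3])
  zmin <- tapply(corners[, 1], key, min)
  zmax <- tapply(corners[, 1], key, max)
  keep <- (corners[, 1] == zmin[key]) | (corners[, 1] == zmax[key])
  unname(corners[keep, , drop = FALSE])
}

#' Convex hull volume of a voxel cloud (voxels as unit cubes)
#'
#' @param vox integer matrix of voxel indices, columns (z, y, x).
#' @return hull volume in cubic voxel units.
#' @export
voxel_hull_volume <- function(vox) {
  convex_hull_volume(voxel_corner_points(vox))
}

#' Convex hull perimeter of a set of unit pixels
#'
#' Pixels (a, b) are treated as unit squares; the hull is taken over the
#' square corner points so single-row shapes have nonzero extent.
#'
#' @param pix integer matrix of pixel indices, 2 columns.
#' @return perimeter of the 2D convex hull.
#' @export
pixel_hull_perimeter <- function(pix) {
  pix <- as.matrix(pix)
  corners <- unique(rbind(pix, sweep(pix, 2, c(1, 0), "+"),
                          sweep(pix, 2, c(0, 1), "+"), sweep(pix, 2, c(1, 1), "+")))
  h <- grDevices::chull(corners[, 1], corners[, 2])
  poly <- corners[h, , drop = FALSE]
  sum(sqrt(rowSums((poly - poly[c(2:nrow(poly), 1), , drop = FALSE])^2)))
}
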