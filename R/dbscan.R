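#' DBSCAN clustering of voxel coordinates
#'
#' Density-based clustering specialised to integer lattice points. Neighbour
#' queries are exact: for the finite set of integer offsets with Euclidean
#' norm <= eps, membership is resolved by hashed coordinate lookup, so the
#' result is identical to a general DBSCAN with a Euclidean eps-ball.
#' A point's own position counts towards `min_samples` (the scikit-learn
#' convention). Clusters are the connected components of core points under
#' eps-adjacency; border points join the cluster of their lowest-index core
#' neighbour, which makes the labelling independent of input order up to the
#' lexicographic sort applied first.
#'
#' @param coords integer matrix, one voxel per row, columns (z, y, x).
#' @param eps neighbourhood radius in voxel units.
#' @param min_samples minimum neighbours (including self) for a core point.
#' @return integer vector of cluster labels aligned with the (sorted) rows;
#'   0 marks noise. The sorted coordinates are attached as attribute
#'   `"coords"`.
#' @export
dbscan_voxels <- function(coords, eps, min_samples) {
  coords <- as.matrix(coords)
  storage.mode(coords) <- "integer"
  if (nrow(coords) == 0) return(structure(integer(0), coords = coords))
  ord <- order(coords[, 1], coords[, 2], coords[, 3])
  coords <- coords[ord, , drop = FALSE]

  r <- as.integer(floor(eps))
  offs <- as.matrix(expand.grid(dz = -r:r, dy = -r:r, dx = -r:r))
  offs <- offs[rowSums(offs^2) <= eps^2, , drop = FALSE]

  ## collision-free integer keys (doubles are exact well past these ranges)
  mins <- apply(coords, 2, min) - r - 1L
  dims <- apply(coords, 2, max) - mins + 2L * (r + 1L)
  enc <- function(m) {
    (m[, 1] - mins[1]) * (dims[2] * dims[3]) + (m[, 2] - mins[2]) * dims[3] +
      (m[, 3] - mins[3])
  }
  keys <- enc(coords)
  off_keys <- offs[, 1] * (dims[2] * dims[3]) + offs[, 2] * dims[3] + offs[, 3]

  n <- nrow(coords)
  ncount <- integer(n)
  neighbor_idx <- vector("list", nrow(offs))
  for (k in seq_len(nrow(offs))) {
    m <- match(keys + off_keys[k], keys)
    neighbor_idx[[k]] <- m
    ncount <- ncount + !is.na(m)
  }
  core <- ncount >= min_samples

  ## components of core points under eps-adjacency
  labels <- integer(n)
  if (any(core)) {
    edges <- list()
    for (k in seq_len(nrow(offs))) {
      if (off_keys[k] <= 0) next  # each undirected pair once
      i <- which(core & !is.na(neighbor_idx[[k]]))
      j <- neighbor_idx[[k]][i]
      keep <- core[j]
      if (any(keep)) edges[[length(edges) + 1L]] <- cbind(i[keep], j[keep])
    }
    core_ids <- which(core)
    g <- igraph::make_empty_graph(n = length(core_ids), directed = FALSE)
    if (length(edges)) {
      e <- do.call(rbind, edges)
      g <- igraph::add_edges(g, t(cbind(match(e[, 1], core_ids),
                                        match(e[, 2], core_ids))))
    }
    comp <- igraph::components(g)$membership
    ## relabel components by their smallest member index for determinism
    first_member <- tapply(core_ids, comp, min)
    relabel <- rank(first_member)
    labels[core_ids] <- relabel[comp]

    ## border points: lowest-index core neighbour decides
    border_owner <- rep(NA_integer_, n)
    for (k in seq_len(nrow(offs))) {
      m <- neighbor_idx[[k]]
      cand <- which(!core & !is.na(m) & core[ifelse(is.na(m), 1L, m)])
      if (length(cand)) {
        owner <- m[cand]
        upd <- is.na(border_owner[cand]) | owner < border_owner[cand]
        border_owner[cand[upd]] <- owner[upd]
      }
    }
    has_owner <- !is.na(border_owner)
    labels[has_owner & !core] <- labels[border_owner[has_owner & !core]]
  }
  structure(labels, coords = coords)
}
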