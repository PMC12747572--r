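#' Configuration for live/dead counting
#'
#' @param blur_sigma_px Gaussian blur applied before nucleus thresholding.
#' @param min_spot_px components below this area (px) are discarded as
#'   debris; the default passes nothing smaller than a ~3 px-radius spot.
#' @param dead_radius_px disk radius around each nucleus centroid over which
#'   the dead-channel intensity is averaged; keep it near the nuclear spot
#'   core (about one spot sigma) so the disk mean is not diluted by
#'   background.
#' @param split_touching if TRUE (default) touching nuclei are separated by
#'   watershed on the distance transform.
#' @return object of class `viability_config`.
#' @export
viability_config <- function(blur_sigma_px = 2, min_spot_px = 25,
                             dead_radius_px = 2, split_touching = TRUE) {
  stopifnot(blur_sigma_px >= 0, min_spot_px >= 0, dead_radius_px > 0)
  structure(list(blur_sigma_px = blur_sigma_px, min_spot_px = min_spot_px,
                 dead_radius_px = dead_radius_px,
                 split_touching = split_touching),
            class = "viability_config")
}

#' Count nuclei in a Hoechst channel
#'
#' Gaussian blur, Otsu threshold, connected components, size filter, and
#' distance-transform watershed splitting of touching pairs.
#'
#' @param nucleus_channel 2D intensity matrix.
#' @param cfg a [viability_config()].
#' @return list with `count` and `centroids` (data.frame `x_px`, `y_px`,
#'   0-based).
#' @export
count_nuclei <- function(nucleus_channel, cfg = viability_config()) {
  img <- as.matrix(nucleus_channel)
  rng <- range(img)
  if (rng[1] == rng[2])
    stop("degenerate input: nucleus channel is single-valued")
  norm <- (img - rng[1]) / (rng[2] - rng[1])
  if (cfg$blur_sigma_px > 0) norm <- EBImage::gblur(norm, cfg$blur_sigma_px)
  norm[norm < 0] <- 0; norm[norm > 1] <- 1
  bin <- norm > EBImage::otsu(norm, range = c(0, 1))
  labels <- if (cfg$split_touching)
    EBImage::watershed(EBImage::distmap(bin), tolerance = 1)
  else
    EBImage::bwlabel(bin)
  labels <- as.matrix(EBImage::imageData(labels))
  areas <- tabulate(labels[labels > 0])
  keep <- which(areas >= cfg$min_spot_px)
  if (!length(keep))
    return(list(count = 0L,
                centroids = data.frame(x_px = numeric(0), y_px = numeric(0))))
  idx <- which(labels > 0 & matrix(labels %in% keep, nrow(labels)),
               arr.ind = TRUE)
  lab <- labels[labels > 0 & labels %in% keep]
  cy <- tapply(idx[, 1] - 1, lab, mean)
  cx <- tapply(idx[, 2] - 1, lab, mean)
  list(count = length(keep),
       centroids = data.frame(x_px = as.numeric(cx), y_px = as.numeric(cy)))
}

#' Count dead cells by colocalisation with nuclei
#'
#' A nucleus is dead iff the mean dead-channel intensity in a disk around
#' its centroid exceeds an Otsu-derived cutoff on that channel. Dead signal
#' without a matching nucleus is ignored. A near-constant dead channel
#' (nothing stained) yields zero.
#'
#' @param dead_channel 2D intensity matrix.
#' @param nuclei_centroids data.frame `x_px`, `y_px` from [count_nuclei()].
#' @param cfg a [viability_config()].
#' @return integer count, with the per-nucleus logical as attribute
#'   `"is_dead"`.
#' @export
count_dead <- function(dead_channel, nuclei_centroids,
                       cfg = viability_config()) {
  n <- nrow(nuclei_centroids)
  if (n == 0) return(structure(0L, is_dead = logical(0)))
  img <- as.matrix(dead_channel)
  rng <- range(img)
  if (rng[2] - rng[1] < .Machine$double.eps * max(abs(rng), 1))
    return(structure(0L, is_dead = rep(FALSE, n)))
  norm <- (img - rng[1]) / (rng[2] - rng[1])
  cutoff <- rng[1] + EBImage::otsu(norm, range = c(0, 1)) * (rng[2] - rng[1])
  H <- nrow(img); W <- ncol(img)
  is_dead <- vapply(seq_len(n), function(i) {
    cols <- disk_pixel_columns(nuclei_centroids$x_px[i],
                               nuclei_centroids$y_px[i],
                               cfg$dead_radius_px, H, W)
    mean(img[cols]) > cutoff
  }, logical(1))
  structure(sum(is_dead), is_dead = is_dead)
}

#' Viability percentage from total and dead counts
#'
#' `viability = 100 * (total - dead) / total`; live cells are the
#' difference between total and dead.
#'
#' @param total total (nucleus) count, >= 1.
#' @param dead dead count, `0 <= dead <= total`.
#' @return viability percentage.
#' @export
compute_viability <- function(total, dead) {
  if (total < 1) stop("total must be >= 1")
  if (dead > total) stop("dead count exceeds total")
  if (dead < 0) stop("dead count negative")
  100 * (total - dead) / total
}

#' Full live/dead quantification of a three-channel field
#'
#' @param image list with `nuclei`, `live`, `dead` matrices (live is carried
#'   for inspection only; the viability formula needs total and dead).
#' @param cfg a [viability_config()].
#' @return list with `total`, `dead`, `live`, `viability_pct`, `centroids`.
#' @export
analyze_viability <- function(image, cfg = viability_config()) {
  nuc <- count_nuclei(image$nuclei, cfg)
  if (nuc$count == 0)
    stop("no nuclei detected: viability undefined for an empty field")
  dead <- count_dead(image$dead, nuc$centroids, cfg)
  list(total = nuc$count, dead = as.integer(dead),
       live = nuc$count - as.integer(dead),
       viability_pct = compute_viability(nuc$count, as.integer(dead)),
       centroids = cbind(nuc$centroids, dead = attr(dead, "is_dead")))
}
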