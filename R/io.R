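#' Write an image object to TIFF with a YAML sidecar
#'
#' Pages are 16-bit; intensities are scaled into [0, 1] by the recorded
#' `intensity_max`, and the sidecar (`<path>.yaml`) carries the axis order,
#' dimensions, channel names, and physical metadata (voxel pitch, frame
#' rate, pixel pitch) that plain TIFF tags cannot hold reliably.
#'
#' Page order: `ZCYX` stacks interleave channels within each z-plane,
#' `TYX` movies write one page per frame, `CYX` images one page per channel.
#'
#' @param x a `volumetric_image`, `calcium_movie`, or a named list of 2D
#'   channel matrices (written as CYX).
#' @param path output TIFF path.
#' @return invisibly, the sidecar metadata list.
#' @export
write_stack <- function(x, path) {
  if (inherits(x, "volumetric_image")) {
    chs <- x$channels
    gs <- dim(chs[[1]])
    vals <- unlist(chs)
    m <- max(vals, 1e-12)
    pages <- list()
    for (z in seq_len(gs[1]))
      for (ci in seq_along(chs))
        pages[[length(pages) + 1L]] <- pmin(pmax(chs[[ci]][z, , ] / m, 0), 1)
    meta <- list(axes = "ZCYX", n_z = gs[1], n_c = length(chs),
                 height = gs[2], width = gs[3], channels = names(chs),
                 voxel_pitch_um = x$voxel_pitch_um, intensity_max = m)
  } else if (inherits(x, "calcium_movie")) {
    d <- dim(x$frames)
    m <- max(x$frames, 1e-12)
    pages <- lapply(seq_len(d[1]), function(t)
      pmin(pmax(x$frames[t, , ] / m, 0), 1))
    meta <- list(axes = "TYX", n_t = d[1], height = d[2], width = d[3],
                 frame_rate_hz = x$frame_rate_hz,
                 pixel_pitch_um = x$pixel_pitch_um, intensity_max = m)
  } else if (is.list(x) && all(vapply(x, is.matrix, logical(1)))) {
    m <- max(unlist(x), 1e-12)
    pages <- lapply(x, function(ch) pmin(pmax(ch / m, 0), 1))
    meta <- list(axes = "CYX", n_c = length(x), height = nrow(x[[1]]),
                 width = ncol(x[[1]]), channels = names(x), intensity_max = m)
  } else stop("unsupported image object")
  tiff::writeTIFF(pages, path, bits.per.sample = 16L)
  yaml::write_yaml(meta, paste0(path, ".yaml"))
  invisible(meta)
}

#' Read a TIFF + sidecar written by [write_stack()]
#'
#' @param path TIFF path (sidecar expected at `<path>.yaml`).
#' @param expected_axes one of `"ZCYX"`, `"TYX"`, `"CYX"`; a mismatch with
#'   the sidecar is an error.
#' @return a `volumetric_image`, `calcium_movie`, or named channel list.
#' @export
read_stack <- function(path, expected_axes = c("ZCYX", "TYX", "CYX")) {
  expected_axes <- match.arg(expected_axes)
  if (!file.exists(path)) stop("no such file: ", path)
  sidecar <- paste0(path, ".yaml")
  if (!file.exists(sidecar)) stop("missing sidecar metadata: ", sidecar)
  meta <- yaml::read_yaml(sidecar)
  if (!identical(meta$axes, expected_axes))
    stop(sprintf("axis mismatch: file is %s, expected %s",
                 meta$axes, expected_axes))
  pages <- tiff::readTIFF(path, all = TRUE)
  m <- meta$intensity_max
  if (expected_axes == "ZCYX") {
    chs <- lapply(seq_len(meta$n_c), function(ci) {
      a <- array(0, dim = c(meta$n_z, meta$height, meta$width))
      for (z in seq_len(meta$n_z))
        a[z, , ] <- pages[[(z - 1) * meta$n_c + ci]] * m
      a
    })
    names(chs) <- meta$channels
    structure(list(channels = chs, voxel_pitch_um = meta$voxel_pitch_um),
              class = "volumetric_image")
  } else if (expected_axes == "TYX") {
    fr <- array(0, dim = c(meta$n_t, meta$height, meta$width))
    for (t in seq_len(meta$n_t)) fr[t, , ] <- pages[[t]] * m
    structure(list(frames = fr, frame_rate_hz = meta$frame_rate_hz,
                   pixel_pitch_um = meta$pixel_pitch_um),
              class = "calcium_movie")
  } else {
    chs <- lapply(pages, function(p) p * m)
    names(chs) <- meta$channels
    chs
  }
}

#' Write records to CSV (lossless round-trip)
#'
#' UTF-8, '.' decimal separator, stable column order, NA serialised as an
#' empty field. Doubles are written with a shortest round-trip
#' representation so [read_records()] restores identical values.
#'
#' @param records data.frame.
#' @param path output path.
#' @param required_columns optional character vector; missing columns are a
#'   schema error.
#' @export
write_records <- function(records, path, required_columns = NULL) {
  if (!is.data.frame(records)) stop("records must be a data.frame")
  if (!is.null(required_columns)) {
    missing <- setdiff(required_columns, names(records))
    if (length(missing))
      stop("records violate schema; missing columns: ",
           paste(missing, collapse = ", "))
  }
  readr::write_csv(records, path, na = "")
  invisible(path)
}

#' @rdname write_records
#' @export
read_records <- function(path) {
  as.data.frame(readr::read_csv(path, show_col_types = FALSE, na = ""))
}
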