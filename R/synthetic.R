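#' Calcium transient waveform
#'
#' Rise-then-decay kinetics `A * (1 - exp(-(t - t0)/tau_r)) * exp(-(t - t0)/tau_d)`
#' for `t >= t0` and 0 before onset. Note the peak of the shape factor is
#' below 1, so the series maximum is below `amplitude`; see
#' [transient_peak()] for the attained peak.
#'
#' @param t numeric vector of times (s).
#' @param onset_s onset time t0 (s).
#' @param amplitude amplitude multiplier A (dF/F units).
#' @param rise_tau_s,decay_tau_s rise and decay time constants (s), > 0.
#' @return numeric vector of dF/F values.
#' @export
ca_transient <- function(t, onset_s, amplitude, rise_tau_s, decay_tau_s) {
  stopifnot(amplitude > 0, rise_tau_s > 0, decay_tau_s > 0)
  u <- t - onset_s
  out <- numeric(length(t))
  on <- u >= 0
  out[on] <- amplitude * (1 - exp(-u[on] / rise_tau_s)) * exp(-u[on] / decay_tau_s)
  out
}

#' Peak value of the transient waveform
#'
#' Closed form: the shape `(1 - e^(-u/a)) e^(-u/b)` is maximal at
#' `u* = a log((a + b)/a)`.
#'
#' @inheritParams ca_transient
#' @return list with `peak_value` (includes the amplitude factor) and
#'   `peak_time_s` (relative to onset).
#' @export
transient_peak <- function(amplitude, rise_tau_s, decay_tau_s) {
  u <- rise_tau_s * log((rise_tau_s + decay_tau_s) / rise_tau_s)
  list(peak_value = amplitude * (1 - exp(-u / rise_tau_s)) * exp(-u / decay_tau_s),
       peak_time_s = u)
}

#' Cell ground-truth descriptor for the morphology simulator
#'
#' All positional vectors are in micrometres and ordered (x, y, z); voxel
#' arrays use (Z, Y, X) index order. Ellipsoid bodies are axis-aligned with
#' the given semi-axes; stellate bodies add `arm_count` box-shaped arms
#' radiating in the XY plane from an ellipsoid core.
#'
#' @param center_um body centre (x, y, z) in um.
#' @param semi_axes_um ellipsoid semi-axes (x, y, z) in um.
#' @param nucleus_offset_um nucleus centre offset from the body centre (um).
#' @param nucleus_radius_um nucleus sphere radius (um).
#' @param intensity membrane-channel intensity of the body (> background).
#' @param body_type `"ellipsoid"` (default) or `"stellate"`.
#' @param arm_count,arm_length_um,arm_width_um stellate arm geometry.
#' @return object of class `cell_truth`.
#' @export
cell_truth <- function(center_um, semi_axes_um,
                       nucleus_offset_um = c(0, 0, 0), nucleus_radius_um,
                       intensity = 1, body_type = c("ellipsoid", "stellate"),
                       arm_count = 4, arm_length_um = 10, arm_width_um = 2) {
  body_type <- match.arg(body_type)
  stopifnot(length(center_um) == 3, length(semi_axes_um) == 3,
            all(semi_axes_um > 0), nucleus_radius_um > 0, intensity > 0)
  if (any(semi_axes_um <= nucleus_radius_um))
    stop("nucleus radius must be smaller than every semi-axis")
  # sufficient containment: nucleus centre inside the ellipsoid shrunk by r
  if (sum((nucleus_offset_um / (semi_axes_um - nucleus_radius_um))^2) > 1)
    stop("nucleus not fully inside the cell body")
  structure(list(center_um = as.numeric(center_um),
                 semi_axes_um = as.numeric(semi_axes_um),
                 nucleus_offset_um = as.numeric(nucleus_offset_um),
                 nucleus_radius_um = nucleus_radius_um,
                 intensity = intensity, body_type = body_type,
                 arm_count = arm_count, arm_length_um = arm_length_um,
                 arm_width_um = arm_width_um),
            class = "cell_truth")
}

cell_bbox_um <- function(cell) {
  half <- cell$semi_axes_um
  if (cell$body_type == "stellate")
    half <- pmax(half, c(cell$arm_length_um, cell$arm_length_um, half[3]))
  rbind(lo = cell$center_um - half, hi = cell$center_um + half)
}

bboxes_overlap <- function(a, b) {
  all(a["lo", ] < b["hi", ] & b["lo", ] < a["hi", ])
}

#' Specification of a synthetic two-channel morphology stack
#'
#' @param grid_shape integer (Z, Y, X) voxel counts.
#' @param voxel_pitch_um isotropic voxel edge length in um.
#' @param cells list of [cell_truth()] objects; their bounding boxes must be
#'   pairwise disjoint so ground-truth segmentation is unambiguous.
#' @param background_level,noise_sd background intensity and additive
#'   Gaussian noise sd.
#' @param blur_sigma_um in-plane Gaussian blur applied per z-slice (um).
#' @param shell_thickness_um if non-NULL, render the membrane channel as a
#'   hollow shell of this thickness instead of a filled body.
#' @param poisson_noise if TRUE, add scaled Poisson shot noise as well.
#' @param seed RNG seed; identical spec + seed gives bit-identical stacks.
#' @return object of class `morph_stack_spec`.
#' @export
morph_stack_spec <- function(grid_shape, voxel_pitch_um, cells,
                             background_level = 0.05, noise_sd = 0,
                             blur_sigma_um = 0.5, shell_thickness_um = NULL,
                             poisson_noise = FALSE, seed = 1L) {
  stopifnot(length(grid_shape) == 3, all(grid_shape >= 1), voxel_pitch_um > 0,
            noise_sd >= 0, background_level >= 0)
  if (!length(cells)) stop("at least one cell required")
  if (!all(vapply(cells, inherits, logical(1), "cell_truth")))
    stop("cells must be cell_truth objects")
  for (cl in cells)
    if (cl$intensity <= background_level)
      stop("cell intensity must exceed the background level")
  boxes <- lapply(cells, cell_bbox_um)
  if (length(cells) > 1)
    for (i in seq_len(length(cells) - 1)) for (j in (i + 1):length(cells))
      if (bboxes_overlap(boxes[[i]], boxes[[j]]))
        stop(sprintf("cells %d and %d overlap", i, j))
  extent <- grid_shape[c(3, 2, 1)] * voxel_pitch_um  # (x, y, z) um
  for (cl in cells) {
    b <- cell_bbox_um(cl)
    if (any(b["lo", ] < 0) || any(b["hi", ] > extent))
      stop("cell extends outside the grid")
  }
  structure(list(grid_shape = as.integer(grid_shape),
                 voxel_pitch_um = voxel_pitch_um, cells = cells,
                 background_level = background_level, noise_sd = noise_sd,
                 blur_sigma_um = blur_sigma_um,
                 shell_thickness_um = shell_thickness_um,
                 poisson_noise = poisson_noise, seed = as.integer(seed)),
            class = "morph_stack_spec")
}

#' Randomly place non-overlapping ellipsoid cells in a grid
#'
#' Rejection sampling with a bounded retry budget; placement that still
#' overlaps after `max_tries` attempts raises a placement error.
#'
#' @param n number of cells.
#' @param grid_shape,voxel_pitch_um grid geometry as in [morph_stack_spec()].
#' @param semi_axes_range_um range from which each semi-axis is drawn (um).
#' @param nucleus_radius_um nucleus radius (um).
#' @param nucleus_jitter_um max |offset| of the nucleus per axis (um).
#' @param intensity cell intensity.
#' @param seed RNG seed.
#' @param max_tries retry budget per cell.
#' @return list of [cell_truth()] objects.
#' @export
random_cell_truths <- function(n, grid_shape, voxel_pitch_um,
                               semi_axes_range_um = c(4, 8),
                               nucleus_radius_um = 1.5, nucleus_jitter_um = 1,
                               intensity = 1, seed = 1L, max_tries = 1000L) {
  set.seed(seed)
  extent <- grid_shape[c(3, 2, 1)] * voxel_pitch_um
  cells <- list()
  for (i in seq_len(n)) {
    placed <- FALSE
    for (try in seq_len(max_tries)) {
      ax <- stats::runif(3, semi_axes_range_um[1], semi_axes_range_um[2])
      margin <- ax + voxel_pitch_um
      if (any(extent <= 2 * margin)) next
      ctr <- stats::runif(3, margin, extent - margin)
      off <- stats::runif(3, -nucleus_jitter_um, nucleus_jitter_um)
      if (sum((off / (ax - nucleus_radius_um))^2) > 1) off <- c(0, 0, 0)
      cand <- cell_truth(ctr, ax, off, nucleus_radius_um, intensity)
      ok <- !any(vapply(cells, function(cl)
        bboxes_overlap(cell_bbox_um(cl), cell_bbox_um(cand)), logical(1)))
      if (ok) { cells[[i]] <- cand; placed <- TRUE; break }
    }
    if (!placed) stop(sprintf("could not place cell %d in %d tries", i, max_tries))
  }
  cells
}

## voxel-centre coordinate vectors (um) for a (Z, Y, X) grid
grid_axes_um <- function(grid_shape, pitch) {
  lapply(grid_shape, function(nv) (seq_len(nv) - 0.5) * pitch)
}

render_ellipsoid <- function(arr, axes_um, center_xyz, semi_xyz, value) {
  # axes_um: list of z, y, x voxel-centre coordinates
  zin <- which(abs(axes_um[[1]] - center_xyz[3]) <= semi_xyz[3])
  yin <- which(abs(axes_um[[2]] - center_xyz[2]) <= semi_xyz[2])
  xin <- which(abs(axes_um[[3]] - center_xyz[1]) <= semi_xyz[1])
  if (!length(zin) || !length(yin) || !length(xin)) return(arr)
  dz2 <- ((axes_um[[1]][zin] - center_xyz[3]) / semi_xyz[3])^2
  dy2 <- ((axes_um[[2]][yin] - center_xyz[2]) / semi_xyz[2])^2
  dx2 <- ((axes_um[[3]][xin] - center_xyz[1]) / semi_xyz[1])^2
  r2 <- outer(outer(dz2, dy2, "+"), dx2, "+")
  sub <- arr[zin, yin, xin, drop = FALSE]
  sub[r2 <= 1] <- pmax(sub[r2 <= 1], value)
  arr[zin, yin, xin] <- sub
  arr
}

render_box <- function(arr, axes_um, lo_xyz, hi_xyz, value) {
  zin <- which(axes_um[[1]] >= lo_xyz[3] & axes_um[[1]] <= hi_xyz[3])
  yin <- which(axes_um[[2]] >= lo_xyz[2] & axes_um[[2]] <= hi_xyz[2])
  xin <- which(axes_um[[3]] >= lo_xyz[1] & axes_um[[3]] <= hi_xyz[1])
  if (length(zin) && length(yin) && length(xin))
    arr[zin, yin, xin] <- pmax(arr[zin, yin, xin], value)
  arr
}

## per-slice 2D Gaussian blur of a (Z, Y, X) array
blur_stack <- function(arr, sigma_px) {
  if (sigma_px <= 0) return(arr)
  for (z in seq_len(dim(arr)[1]))
    arr[z, , ] <- EBImage::gblur(arr[z, , ], sigma = sigma_px)
  arr
}

#' Generate a two-channel 3D morphology stack with ground truth
#'
#' Renders each cell body into the membrane channel (filled, or a hollow
#' shell when `shell_thickness_um` is set) and each nucleus sphere into the
#' nucleus channel, applies per-slice Gaussian blur and additive noise, and
#' returns the stack together with the exact analytic truth of every body.
#'
#' @param spec a [morph_stack_spec()].
#' @return list with `stack` (class `volumetric_image`: channel arrays in
#'   (Z, Y, X) order plus pitch metadata) and `truth` (data.frame of
#'   analytic per-cell volume, ranges and centroid in um).
#' @export
generate_morphology_stack <- function(spec) {
  stopifnot(inherits(spec, "morph_stack_spec"))
  set.seed(spec$seed)
  gs <- spec$grid_shape
  axes <- grid_axes_um(gs, spec$voxel_pitch_um)
  mem <- array(spec$background_level, dim = gs)
  nuc <- array(spec$background_level, dim = gs)
  for (cl in spec$cells) {
    if (cl$body_type == "ellipsoid") {
      if (is.null(spec$shell_thickness_um)) {
        mem <- render_ellipsoid(mem, axes, cl$center_um, cl$semi_axes_um,
                                cl$intensity)
      } else {
        body <- render_ellipsoid(array(0, gs), axes, cl$center_um,
                                 cl$semi_axes_um, 1)
        inner <- pmax(cl$semi_axes_um - spec$shell_thickness_um,
                      spec$voxel_pitch_um / 2)
        core <- render_ellipsoid(array(0, gs), axes, cl$center_um, inner, 1)
        mem[body > 0 & core == 0] <- pmax(mem[body > 0 & core == 0],
                                          cl$intensity)
      }
    } else {
      mem <- render_ellipsoid(mem, axes, cl$center_um, cl$semi_axes_um,
                              cl$intensity)
      ang <- 2 * pi * (seq_len(cl$arm_count) - 1) / cl$arm_count
      for (a in ang) {
        dir <- c(cos(a), sin(a), 0)
        tip <- cl$center_um + dir * cl$arm_length_um
        lo <- pmin(cl$center_um, tip) - cl$arm_width_um / 2
        hi <- pmax(cl$center_um, tip) + cl$arm_width_um / 2
        mem <- render_box(mem, axes, lo, hi, cl$intensity)
      }
    }
    nc <- cl$center_um + cl$nucleus_offset_um
    nuc <- render_ellipsoid(nuc, axes, nc, rep(cl$nucleus_radius_um, 3),
                            cl$intensity)
  }
  sigma_px <- spec$blur_sigma_um / spec$voxel_pitch_um
  mem <- blur_stack(mem, sigma_px)
  nuc <- blur_stack(nuc, sigma_px)
  if (spec$poisson_noise) {
    mem <- mem + (stats::rpois(length(mem), pmax(mem, 0) * 100) / 100 - pmax(mem, 0))
    nuc <- nuc + (stats::rpois(length(nuc), pmax(nuc, 0) * 100) / 100 - pmax(nuc, 0))
  }
  if (spec$noise_sd > 0) {
    mem <- mem + stats::rnorm(length(mem), sd = spec$noise_sd)
    nuc <- nuc + stats::rnorm(length(nuc), sd = spec$noise_sd)
  }
  truth <- do.call(rbind, lapply(seq_along(spec$cells), function(i) {
    cl <- spec$cells[[i]]
    nc <- cl$center_um + cl$nucleus_offset_um
    data.frame(cell_id = i, body_type = cl$body_type,
               volume_um3 = 4 / 3 * pi * prod(cl$semi_axes_um),
               range_x_um = 2 * cl$semi_axes_um[1],
               range_y_um = 2 * cl$semi_axes_um[2],
               range_z_um = 2 * cl$semi_axes_um[3],
               centroid_x_um = cl$center_um[1], centroid_y_um = cl$center_um[2],
               centroid_z_um = cl$center_um[3],
               nucleus_x_um = nc[1], nucleus_y_um = nc[2], nucleus_z_um = nc[3],
               nucleus_radius_um = cl$nucleus_radius_um,
               centroid_distance_um = sqrt(sum(cl$nucleus_offset_um^2)))
  }))
  stack <- structure(list(channels = list(membrane = mem, nucleus = nuc),
                          voxel_pitch_um = spec$voxel_pitch_um),
                     class = "volumetric_image")
  list(stack = stack, truth = truth)
}

#' Specification of a synthetic calcium time-lapse movie
#'
#' @param frame_rate_hz acquisition rate (Hz), default 10.
#' @param duration_s recording length (s), default 300.
#' @param frame_shape (H, W) pixels.
#' @param cells data.frame with columns `center_x_px`, `center_y_px`
#'   (0-based), `radius_px`, `baseline_F`.
#' @param events data.frame with columns `cell_index`, `onset_s`,
#'   `amplitude_dff`, `rise_tau_s`, `decay_tau_s` (may have zero rows).
#' @param bleach_tau_s photobleaching time constant (s) of the multiplicative
#'   exponential decay, or NULL for no bleaching.
#' @param noise_sd additive Gaussian noise sd (intensity units).
#' @param background_F background fluorescence; every `baseline_F` must
#'   exceed it and it must be positive.
#' @param pixel_pitch_um physical pixel size (um); default 0.65 matches a
#'   1331.2 um field imaged at 2048 px.
#' @param seed RNG seed.
#' @return object of class `calcium_movie_spec`.
#' @export
calcium_movie_spec <- function(frame_rate_hz = 10, duration_s = 300,
                               frame_shape, cells, events = NULL,
                               bleach_tau_s = NULL, noise_sd = 0,
                               background_F = 100, pixel_pitch_um = 0.65,
                               seed = 1L) {
  stopifnot(frame_rate_hz > 0, duration_s > 0, length(frame_shape) == 2,
            all(frame_shape >= 8), noise_sd >= 0, background_F > 0)
  cells <- as.data.frame(cells)
  need <- c("center_x_px", "center_y_px", "radius_px", "baseline_F")
  if (!all(need %in% names(cells))) stop("cells lacks required columns")
  if (any(cells$baseline_F <= background_F))
    stop("baseline_F must exceed background_F")
  if (is.null(events))
    events <- data.frame(cell_index = integer(), onset_s = numeric(),
                         amplitude_dff = numeric(), rise_tau_s = numeric(),
                         decay_tau_s = numeric())
  events <- as.data.frame(events)
  if (nrow(events)) {
    if (any(!events$cell_index %in% seq_len(nrow(cells))))
      stop("event references a cell that does not exist")
    if (any(events$onset_s >= duration_s))
      stop("event onset beyond the recording duration")
    stopifnot(all(events$amplitude_dff > 0), all(events$rise_tau_s > 0),
              all(events$decay_tau_s > 0))
  }
  structure(list(frame_rate_hz = frame_rate_hz, duration_s = duration_s,
                 frame_shape = as.integer(frame_shape), cells = cells,
                 events = events, bleach_tau_s = bleach_tau_s,
                 noise_sd = noise_sd, background_F = background_F,
                 pixel_pitch_um = pixel_pitch_um, seed = as.integer(seed)),
            class = "calcium_movie_spec")
}

#' Generate a calcium movie with ground-truth events and ROI centres
#'
#' Pixels inside cell `c` follow
#' `baseline_F_c * (1 + sum of that cell's transients) * bleach(t) + noise`;
#' background pixels follow `background_F * bleach(t) + noise`.
#'
#' @param spec a [calcium_movie_spec()].
#' @return list with `movie` (class `calcium_movie`: frames array (T, H, W),
#'   frame rate, pixel pitch), `events` (the ground-truth event table) and
#'   `centers` (data.frame `roi_id`, `x_px`, `y_px` for ROI placement).
#' @export
generate_calcium_movie <- function(spec) {
  stopifnot(inherits(spec, "calcium_movie_spec"))
  set.seed(spec$seed)
  n_frames <- round(spec$frame_rate_hz * spec$duration_s)
  H <- spec$frame_shape[1]; W <- spec$frame_shape[2]
  t_s <- (seq_len(n_frames) - 1) / spec$frame_rate_hz
  bleach <- if (is.null(spec$bleach_tau_s)) rep(1, n_frames) else
    exp(-t_s / spec$bleach_tau_s)
  flat <- matrix(spec$background_F * bleach, nrow = n_frames, ncol = H * W)
  for (ci in seq_len(nrow(spec$cells))) {
    cell <- spec$cells[ci, ]
    s_t <- numeric(n_frames)
    ev <- spec$events[spec$events$cell_index == ci, , drop = FALSE]
    for (k in seq_len(nrow(ev)))
      s_t <- s_t + ca_transient(t_s, ev$onset_s[k], ev$amplitude_dff[k],
                                ev$rise_tau_s[k], ev$decay_tau_s[k])
    cols <- disk_pixel_columns(cell$center_x_px, cell$center_y_px,
                               cell$radius_px, H, W)
    flat[, cols] <- cell$baseline_F * (1 + s_t) * bleach
  }
  if (spec$noise_sd > 0)
    flat <- flat + stats::rnorm(length(flat), sd = spec$noise_sd)
  movie <- structure(list(frames = array(flat, dim = c(n_frames, H, W)),
                          frame_rate_hz = spec$frame_rate_hz,
                          pixel_pitch_um = spec$pixel_pitch_um),
                     class = "calcium_movie")
  centers <- data.frame(roi_id = seq_len(nrow(spec$cells)),
                        x_px = spec$cells$center_x_px,
                        y_px = spec$cells$center_y_px)
  list(movie = movie, events = spec$events, centers = centers)
}

## column indices (into a T x (H*W) frame matrix, column-major (y, x))
## of the disk of given radius around a 0-based (x, y) centre, clipped.
disk_pixel_columns <- function(cx, cy, radius, H, W) {
  cx <- round(cx); cy <- round(cy)  # lattice disk around the nearest pixel
  r <- floor(radius)
  g <- expand.grid(dy = -r:r, dx = -r:r)
  g <- g[g$dx^2 + g$dy^2 <= radius^2, ]
  x <- cx + g$dx; y <- cy + g$dy
  keep <- x >= 0 & x < W & y >= 0 & y < H
  structure(sort((y[keep] + 1) + H * x[keep]), clipped = any(!keep))
}

#' Generate a pure dF/F trace from ground-truth events
#'
#' Fast unit-test path that bypasses imagery: a sampled sum of transient
#' waveforms plus Gaussian noise.
#'
#' @param events data.frame as in [calcium_movie_spec()] (all rows used; the
#'   `cell_index` column is optional for this path).
#' @param frame_rate_hz,duration_s sampling grid.
#' @param noise_sd Gaussian noise sd in dF/F units.
#' @param seed RNG seed.
#' @return list with `dff` (numeric series), `t_s` and `events`.
#' @export
generate_trace <- function(events, frame_rate_hz = 10, duration_s = 300,
                           noise_sd = 0, seed = 1L) {
  events <- as.data.frame(events)
  n_frames <- round(frame_rate_hz * duration_s)
  t_s <- (seq_len(n_frames) - 1) / frame_rate_hz
  if (nrow(events) && any(events$onset_s >= duration_s))
    stop("event onset beyond the recording duration")
  dff <- numeric(n_frames)
  for (k in seq_len(nrow(events)))
    dff <- dff + ca_transient(t_s, events$onset_s[k], events$amplitude_dff[k],
                              events$rise_tau_s[k], events$decay_tau_s[k])
  if (noise_sd > 0) {
    set.seed(seed)
    dff <- dff + stats::rnorm(n_frames, sd = noise_sd)
  }
  list(dff = dff, t_s = t_s, events = events)
}

#' Sample a random set of ground-truth calcium events
#'
#' Events are spaced at least `min_gap_s` apart so detections are
#' unambiguous. `amplitude` values give the attained dF/F peak of each
#' transient: because the peak of `(1 - e^(-u/tau_r)) e^(-u/tau_d)` is below
#' 1, the stored `amplitude_dff` multiplier is scaled up by the inverse
#' shape-factor so the waveform actually reaches the requested peak. Default
#' kinetics (rise 1-2.5 s, decay 2-4 s) emulate somatic astrocyte
#' transients of a few seconds.
#'
#' @param n_events number of events.
#' @param duration_s recording length the onsets must fit (with margins).
#' @param amplitudes pool of attained-peak amplitudes sampled uniformly.
#' @param rise_range_s,decay_range_s uniform sampling ranges of the time
#'   constants (s).
#' @param min_gap_s minimum onset-to-onset spacing (s); the default 45 s
#'   matches recordings with a few large events per 5 minutes and keeps the
#'   high-pass undershoot of one event from biting into the next.
#' @param cell_index value for the `cell_index` column.
#' @param seed RNG seed.
#' @return event data.frame as accepted by [calcium_movie_spec()], with an
#'   extra `peak_dff` column recording the true attained peak.
#' @export
random_event_truths <- function(n_events, duration_s = 300,
                                amplitudes = c(0.3, 0.5, 1.0),
                                rise_range_s = c(1, 2.5),
                                decay_range_s = c(2, 4),
                                min_gap_s = 45, cell_index = 1L, seed = 1L) {
  set.seed(seed)
  lo <- 10; hi <- duration_s - 30
  if (n_events > 0 && hi - lo < (n_events - 1) * min_gap_s)
    stop("duration too short for the requested events at this spacing")
  repeat {
    onsets <- sort(stats::runif(n_events, lo, hi))
    if (n_events < 2 || all(diff(onsets) >= min_gap_s)) break
  }
  peak <- sample(amplitudes, n_events, replace = TRUE)
  rise <- stats::runif(n_events, rise_range_s[1], rise_range_s[2])
  decay <- stats::runif(n_events, decay_range_s[1], decay_range_s[2])
  shape <- vapply(seq_len(n_events), function(i)
    transient_peak(1, rise[i], decay[i])$peak_value, numeric(1))
  data.frame(cell_index = cell_index, onset_s = onsets,
             amplitude_dff = peak / shape, rise_tau_s = rise,
             decay_tau_s = decay, peak_dff = peak)
}

#' Match detected events against ground truth by onset proximity
#'
#' Greedy one-to-one matching: each truth event claims the nearest unclaimed
#' detection whose onset lies within `tol_s` of the true onset.
#'
#' @param detected data.frame from [detect_events()] (1-based `onset_idx`).
#' @param truth data.frame with `onset_s`.
#' @param frame_rate_hz sampling rate (Hz).
#' @param tol_s matching tolerance (s).
#' @return list with counts `tp`, `fn`, `fp` and a `pairs` data.frame
#'   (`truth_row`, `detected_row`, `onset_error_frames`).
#' @export
match_events <- function(detected, truth, frame_rate_hz = 10, tol_s = 2) {
  used <- rep(FALSE, nrow(detected))
  pairs <- data.frame(truth_row = integer(), detected_row = integer(),
                      onset_error_frames = numeric())
  for (k in seq_len(nrow(truth))) {
    t_on <- truth$onset_s[k] * frame_rate_hz + 1
    if (!nrow(detected)) next
    d <- abs(detected$onset_idx - t_on)
    d[used] <- Inf
    j <- which.min(d)
    if (is.finite(d[j]) && d[j] <= tol_s * frame_rate_hz) {
      used[j] <- TRUE
      pairs <- rbind(pairs, data.frame(truth_row = k, detected_row = j,
                                       onset_error_frames = d[j]))
    }
  }
  list(tp = nrow(pairs), fn = nrow(truth) - nrow(pairs), fp = sum(!used),
       pairs = pairs)
}

#' Specification of a synthetic live/dead field
#'
#' @param n_total total nucleus count; `n_dead` of them are marked dead.
#' @param n_dead dead-cell count, `0 <= n_dead <= n_total`.
#' @param frame_shape (H, W) pixels.
#' @param spot_radius_px nuclear spot radius (Gaussian sigma = radius/2).
#' @param min_separation_px minimum centre-to-centre spacing; default 4x the
#'   spot radius.
#' @param noise_sd additive Gaussian noise sd.
#' @param seed RNG seed.
#' @return object of class `viability_field_spec`.
#' @export
viability_field_spec <- function(n_total, n_dead, frame_shape,
                                 spot_radius_px = 4,
                                 min_separation_px = 4 * spot_radius_px,
                                 noise_sd = 0, seed = 1L) {
  stopifnot(n_total >= 0, n_dead >= 0, length(frame_shape) == 2,
            spot_radius_px > 0, min_separation_px > 0, noise_sd >= 0)
  if (n_dead > n_total) stop("n_dead cannot exceed n_total")
  structure(list(n_total = as.integer(n_total), n_dead = as.integer(n_dead),
                 frame_shape = as.integer(frame_shape),
                 spot_radius_px = spot_radius_px,
                 min_separation_px = min_separation_px,
                 noise_sd = noise_sd, seed = as.integer(seed)),
            class = "viability_field_spec")
}

gaussian_spot <- function(img, cx, cy, sigma, amplitude) {
  H <- nrow(img); W <- ncol(img)
  r <- ceiling(3 * sigma)
  ys <- max(1, round(cy) + 1 - r):min(H, round(cy) + 1 + r)
  xs <- max(1, round(cx) + 1 - r):min(W, round(cx) + 1 + r)
  d2 <- outer((ys - 1 - cy)^2, (xs - 1 - cx)^2, "+")
  img[ys, xs] <- img[ys, xs] + amplitude * exp(-d2 / (2 * sigma^2))
  img
}

#' Generate a three-channel live/dead field with known counts
#'
#' The nucleus channel holds `n_total` Gaussian spots; a seeded random subset
#' of `n_dead` positions is marked in the dead channel; the live channel
#' marks cytoplasm disks around the remaining cells.
#'
#' @param spec a [viability_field_spec()].
#' @return list with `image` (list of `nuclei`, `live`, `dead` H x W
#'   matrices) and `truth` (`n_total`, `n_dead`, centre table with a
#'   `dead` flag).
#' @export
generate_viability_field <- function(spec) {
  stopifnot(inherits(spec, "viability_field_spec"))
  set.seed(spec$seed)
  H <- spec$frame_shape[1]; W <- spec$frame_shape[2]
  margin <- 2 * spec$spot_radius_px
  centers <- matrix(numeric(0), 0, 2)
  for (i in seq_len(spec$n_total)) {
    ok <- FALSE
    for (try in seq_len(1000)) {
      cand <- c(stats::runif(1, margin, W - 1 - margin),
                stats::runif(1, margin, H - 1 - margin))
      if (!nrow(centers) ||
          min(sqrt(rowSums(sweep(centers, 2, cand)^2))) >= spec$min_separation_px) {
        centers <- rbind(centers, cand); ok <- TRUE; break
      }
    }
    if (!ok) stop(sprintf("could not place spot %d with the required separation", i))
  }
  nuclei <- matrix(0, H, W); live <- matrix(0, H, W); dead <- matrix(0, H, W)
  dead_idx <- if (spec$n_dead > 0) sort(sample.int(spec$n_total, spec$n_dead))
              else integer(0)
  sigma <- spec$spot_radius_px / 2
  for (i in seq_len(spec$n_total)) {
    nuclei <- gaussian_spot(nuclei, centers[i, 1], centers[i, 2], sigma, 1)
    if (i %in% dead_idx)
      dead <- gaussian_spot(dead, centers[i, 1], centers[i, 2], sigma, 1)
    else
      live <- gaussian_spot(live, centers[i, 1], centers[i, 2],
                            2 * sigma, 0.8)
  }
  if (spec$noise_sd > 0) {
    nuclei <- nuclei + stats::rnorm(length(nuclei), sd = spec$noise_sd)
    live <- live + stats::rnorm(length(live), sd = spec$noise_sd)
    dead <- dead + stats::rnorm(length(dead), sd = spec$noise_sd)
  }
  truth_centers <- data.frame(
    cell_id = seq_len(spec$n_total),
    x_px = if (spec$n_total) centers[, 1] else numeric(0),
    y_px = if (spec$n_total) centers[, 2] else numeric(0),
    dead = seq_len(spec$n_total) %in% dead_idx)
  list(image = list(nuclei = nuclei, live = live, dead = dead),
       truth = list(n_total = spec$n_total, n_dead = spec$n_dead,
                    centers = truth_centers))
}
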