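#' Configuration for the calcium-imaging chain
#'
#' Defaults follow the processing chain: a 5-pixel ROI radius, a 6th-order
#' Butterworth low-pass at 1 Hz, a 2nd-order Butterworth high-pass at
#' 0.01 Hz, zero-phase (forward-backward) application, and a fixed event
#' threshold of 0.1 dF/F applied to the filtered trace.
#'
#' @param roi_radius_px ROI disk radius in working pixels.
#' @param lp_order,lp_cutoff_hz low-pass Butterworth order and cutoff.
#' @param hp_order,hp_cutoff_hz high-pass Butterworth order and cutoff.
#' @param event_threshold_dff detection threshold on the filtered dF/F.
#' @param min_component_px components below this area are removed from the
#'   segmentation mask as debris.
#' @param dilation_radius_px disk radius of the binary dilation refining the
#'   mask.
#' @param downsample_factor spatial block-mean downsampling applied to the
#'   movie before analysis (1 = none); ROI centres are rescaled, the ROI
#'   radius is interpreted in working pixels.
#' @param zero_phase forward-backward filtering (default); FALSE gives a
#'   single causal pass.
#' @param baseline_mode `"background"` references dF/F to the per-frame mean
#'   background (F0 = B_t); `"roi"` uses the ROI's own mean F as a constant
#'   baseline instead.
#' @return object of class `calcium_config`.
#' @export
calcium_config <- function(roi_radius_px = 5, lp_order = 6, lp_cutoff_hz = 1,
                           hp_order = 2, hp_cutoff_hz = 0.01,
                           event_threshold_dff = 0.1, min_component_px = 50,
                           dilation_radius_px = 3, downsample_factor = 2,
                           zero_phase = TRUE,
                           baseline_mode = c("background", "roi")) {
  baseline_mode <- match.arg(baseline_mode)
  stopifnot(roi_radius_px > 0, lp_order >= 1, hp_order >= 1,
            lp_cutoff_hz > 0, hp_cutoff_hz > 0, event_threshold_dff > 0,
            min_component_px >= 0, dilation_radius_px >= 0,
            downsample_factor >= 1)
  structure(list(roi_radius_px = roi_radius_px, lp_order = lp_order,
                 lp_cutoff_hz = lp_cutoff_hz, hp_order = hp_order,
                 hp_cutoff_hz = hp_cutoff_hz,
                 event_threshold_dff = event_threshold_dff,
                 min_component_px = min_component_px,
                 dilation_radius_px = dilation_radius_px,
                 downsample_factor = as.integer(downsample_factor),
                 zero_phase = zero_phase, baseline_mode = baseline_mode),
            class = "calcium_config")
}

movie_flat <- function(movie) {
  matrix(movie$frames, nrow = dim(movie$frames)[1])
}

#' Maximum-intensity projection of a calcium movie
#' @param movie a `calcium_movie`.
#' @return H x W matrix of per-pixel maxima over time.
#' @export
max_projection <- function(movie) {
  d <- dim(movie$frames)
  mip <- movie$frames[1, , ]
  for (t in seq_len(d[1])[-1]) mip <- pmax(mip, movie$frames[t, , ])
  mip
}

#' Build a binary cell mask from a calcium movie
#'
#' Otsu threshold on the maximum-intensity projection, then binary dilation
#' (disk), hole filling, and removal of connected components smaller than
#' `min_component_px`.
#'
#' @param movie a `calcium_movie`.
#' @param cfg a [calcium_config()].
#' @return object of class `cell_mask`: logical `mask`, integer `labels`,
#'   component `areas`.
#' @export
build_mask <- function(movie, cfg = calcium_config()) {
  mip <- max_projection(movie)
  rng <- range(mip)
  if (rng[1] == rng[2])
    stop("degenerate input: maximum projection is single-valued")
  norm <- (mip - rng[1]) / (rng[2] - rng[1])
  bin <- norm > EBImage::otsu(norm, range = c(0, 1))
  if (cfg$dilation_radius_px > 0) {
    brush <- EBImage::makeBrush(2 * cfg$dilation_radius_px + 1, shape = "disc")
    bin <- EBImage::dilate(bin, brush)
  }
  bin <- EBImage::fillHull(bin)
  labels <- EBImage::bwlabel(bin)
  areas <- tabulate(labels[labels > 0])
  drop <- which(areas < cfg$min_component_px)
  if (length(drop)) {
    labels[labels %in% drop] <- 0L
    keep <- sort(unique(labels[labels > 0]))
    labels <- array(match(labels, keep, nomatch = 0L), dim = dim(labels))
    areas <- areas[keep]
  }
  structure(list(mask = labels > 0, labels = labels, areas = areas),
            class = "cell_mask")
}

#' Extract an ROI fluorescence trace and its background series
#'
#' F_t is the mean intensity over the disk of lattice pixels with
#' `dx^2 + dy^2 <= radius^2` around the (0-based) centre; B_t is the mean
#' over all pixels outside the mask. ROIs extending beyond the frame are
#' clipped with a warning.
#'
#' @param movie a `calcium_movie`.
#' @param center_px numeric (x, y), 0-based pixel coordinates.
#' @param mask a [build_mask()] result (or logical H x W matrix).
#' @param cfg a [calcium_config()].
#' @return object of class `roi_trace` with per-frame `F` and `B`.
#' @export
extract_trace <- function(movie, center_px, mask, cfg = calcium_config()) {
  d <- dim(movie$frames); H <- d[2]; W <- d[3]
  if (center_px[1] < 0 || center_px[1] >= W ||
      center_px[2] < 0 || center_px[2] >= H)
    stop("ROI centre outside the frame")
  m <- if (inherits(mask, "cell_mask")) mask$mask else mask
  if (all(m)) stop("mask covers the entire frame: no background pixels")
  cols <- disk_pixel_columns(center_px[1], center_px[2], cfg$roi_radius_px, H, W)
  if (isTRUE(attr(cols, "clipped")))
    warning("ROI clipped to the frame boundary")
  flat <- movie_flat(movie)
  Fv <- rowMeans(flat[, cols, drop = FALSE])
  Bv <- rowMeans(flat[, which(!as.vector(m)), drop = FALSE])
  structure(list(center_px = center_px, radius_px = cfg$roi_radius_px,
                 F = Fv, B = Bv, frame_rate_hz = movie$frame_rate_hz),
            class = "roi_trace")
}

#' Compute dF/F0 for an ROI trace
#'
#' In the default `"background"` mode `dff_t = (F_t - B_t) / B_t` with the
#' time-varying mean background as F0. In `"roi"` mode F0 is the trace's own
#' mean F (a conventional change-from-baseline normalisation).
#'
#' @param trace an [extract_trace()] result.
#' @param cfg a [calcium_config()].
#' @return numeric dF/F series.
#' @export
compute_dff <- function(trace, cfg = calcium_config()) {
  if (cfg$baseline_mode == "background") {
    if (any(trace$B <= 0)) stop("invalid background: B_t <= 0")
    (trace$F - trace$B) / trace$B
  } else {
    f0 <- mean(trace$F)
    if (f0 <= 0) stop("invalid baseline: mean F <= 0")
    (trace$F - f0) / f0
  }
}

#' Band-filter a dF/F trace
#'
#' 6th-order Butterworth low-pass then 2nd-order high-pass (orders and
#' cutoffs from the config), applied forward-backward (zero-phase) by
#' default so event kinetics are not phase-shifted.
#'
#' @param dff numeric dF/F series.
#' @param cfg a [calcium_config()].
#' @param frame_rate_hz sampling rate (Hz).
#' @return filtered series of the same length.
#' @export
filter_trace <- function(dff, cfg = calcium_config(), frame_rate_hz = 10) {
  nyq <- frame_rate_hz / 2
  if (cfg$lp_cutoff_hz >= nyq || cfg$hp_cutoff_hz >= nyq)
    stop("filter cutoff at or above the Nyquist frequency")
  if (length(dff) < 10 * max(cfg$lp_order, cfg$hp_order))
    stop("trace too short for the configured filter orders")
  lp <- signal::butter(cfg$lp_order, cfg$lp_cutoff_hz / nyq, type = "low")
  hp <- signal::butter(cfg$hp_order, cfg$hp_cutoff_hz / nyq, type = "high")
  ## the mean is pure DC: the high-pass removes it exactly in steady state,
  ## so subtracting it up front only suppresses edge transients (and keeps
  ## the whole operation linear)
  x <- dff - mean(dff)
  pad <- function(cutoff) ceiling(3 * frame_rate_hz / cutoff)
  if (cfg$zero_phase) {
    x <- filtfilt_padded(lp, x, pad(cfg$lp_cutoff_hz))
    x <- filtfilt_padded(hp, x, pad(cfg$hp_cutoff_hz))
  } else {
    x <- as.numeric(signal::filter(lp, x))
    x <- as.numeric(signal::filter(hp, x))
  }
  x
}

## zero-phase (forward-backward) filtering with odd-symmetric reflection
## padding so the filter state has settled before the data proper begins
filtfilt_padded <- function(flt, x, padlen) {
  n <- length(x)
  p <- min(padlen, n - 1)
  left <- 2 * x[1] - x[seq(p + 1, 2)]
  right <- 2 * x[n] - x[seq(n - 1, n - p)]
  y <- c(left, x, right)
  y <- rev(as.numeric(signal::filter(flt, y)))
  y <- rev(as.numeric(signal::filter(flt, y)))
  y[(p + 1):(p + n)]
}

## indices of local minima; plateaus are credited to their first frame
local_minima <- function(x) {
  r <- rle(x)
  v <- r$values
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  n <- length(v)
  if (n < 3) return(integer(0))
  j <- which(v[-c(1, n)] < v[-c(n - 1, n)] & v[-c(1, n)] < v[-c(1, 2)]) + 1L
  starts[j]
}

#' Detect calcium events on a filtered trace
#'
#' Candidate events are maximal runs above `event_threshold_dff`; each run
#' is extended outward to the nearest zero-crossings and the boundaries are
#' then refined inward to the nearest local minima within that span.
#' Overlapping candidates are merged; events are returned temporally
#' ordered and non-overlapping.
#'
#' @param filtered filtered dF/F series.
#' @param cfg a [calcium_config()].
#' @param frame_rate_hz sampling rate (Hz).
#' @return data.frame with `onset_idx`, `peak_idx`, `offset_idx` (1-based
#'   frame indices); zero rows when nothing crosses threshold.
#' @export
detect_events <- function(filtered, cfg = calcium_config(), frame_rate_hz = 10) {
  n <- length(filtered)
  above <- filtered > cfg$event_threshold_dff
  empty <- data.frame(onset_idx = integer(), peak_idx = integer(),
                      offset_idx = integer())
  if (!any(above)) return(empty)
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  runs <- cbind(starts[r$values], ends[r$values])
  nonpos <- which(filtered <= 0)
  minima <- local_minima(filtered)
  bounds <- t(apply(runs, 1, function(se) {
    s <- se[1]; e <- se[2]
    zc_l <- nonpos[nonpos <= s]
    zc_l <- if (length(zc_l)) max(zc_l) else 1L
    zc_r <- nonpos[nonpos >= e]
    zc_r <- if (length(zc_r)) min(zc_r) else n
    lm_l <- minima[minima >= zc_l & minima <= s]
    lm_r <- minima[minima >= e & minima <= zc_r]
    onset <- if (length(lm_l)) max(lm_l) else zc_l
    offset <- if (length(lm_r)) min(lm_r) else zc_r
    c(onset, offset)
  }))
  ## merge strictly overlapping candidates; neighbours may abut at the
  ## separating local minimum (that split is the point of the refinement)
  ord <- order(bounds[, 1])
  bounds <- bounds[ord, , drop = FALSE]
  merged <- list(bounds[1, ])
  for (i in seq_len(nrow(bounds))[-1]) {
    last <- merged[[length(merged)]]
    if (bounds[i, 1] < last[2])
      merged[[length(merged)]] <- c(last[1], max(last[2], bounds[i, 2]))
    else merged[[length(merged) + 1L]] <- bounds[i, ]
  }
  out <- do.call(rbind, lapply(merged, function(b) {
    peak <- b[1] + which.max(filtered[b[1]:b[2]]) - 1L
    data.frame(onset_idx = b[1], peak_idx = peak, offset_idx = b[2])
  }))
  out
}

#' Fill in event kinetics
#'
#' Amplitude is the maximum filtered value over [onset, offset]; AUC the
#' trapezoidal integral over the same span (dF/F x s); duration, rise and
#' decay are the onset-offset, onset-peak and peak-offset spans in seconds.
#'
#' @param event one-row data.frame (or list) with `onset_idx`, `peak_idx`,
#'   `offset_idx`.
#' @param filtered the filtered series the indices refer to.
#' @param frame_rate_hz sampling rate (Hz).
#' @return the event as a one-row data.frame with `amplitude`, `auc`,
#'   `duration_s`, `rise_s`, `decay_s` added.
#' @export
compute_kinetics <- function(event, filtered, frame_rate_hz = 10) {
  on <- event$onset_idx; pk <- event$peak_idx; off <- event$offset_idx
  if (on == off) stop("degenerate event: onset equals offset")
  stopifnot(on <= pk, pk <= off)
  seg <- filtered[on:off]
  t_s <- (seq(on, off) - 1) / frame_rate_hz
  data.frame(onset_idx = on, peak_idx = pk, offset_idx = off,
             amplitude = max(seg),
             auc = pracma::trapz(t_s, seg),
             duration_s = (off - on) / frame_rate_hz,
             rise_s = (pk - on) / frame_rate_hz,
             decay_s = (off - pk) / frame_rate_hz)
}

#' Summarise activity across ROIs
#'
#' @param events_by_roi data.frame of events with a `roi_id` column (or a
#'   named list of event data.frames).
#' @param n_rois number of ROIs examined (>= 1).
#' @return object of class `activity_summary`: `n_rois`, `n_active`,
#'   `proportion_active`, and the per-active-cell event-count distribution
#'   (a table keyed by event count).
#' @export
summarize_activity <- function(events_by_roi, n_rois) {
  if (n_rois < 1) stop("n_rois must be >= 1")
  if (is.data.frame(events_by_roi)) {
    counts <- if (nrow(events_by_roi)) table(events_by_roi$roi_id) else
      table(integer(0))
  } else {
    nev <- vapply(events_by_roi, nrow, integer(1))
    counts <- table(rep(names(nev), nev))
  }
  per_cell <- as.integer(counts)
  structure(list(n_rois = n_rois, n_active = length(per_cell),
                 proportion_active = length(per_cell) / n_rois,
                 events_per_active_cell = table(per_cell)),
            class = "activity_summary")
}

## block-mean spatial downsampling of a (T, H, W) movie
downsample_movie <- function(movie, f) {
  if (f == 1) return(movie)
  d <- dim(movie$frames)
  H <- (d[2] %/% f) * f; W <- (d[3] %/% f) * f
  fr <- movie$frames[, seq_len(H), seq_len(W), drop = FALSE]
  a <- array(fr, dim = c(d[1], f, H %/% f, f, W %/% f))
  movie$frames <- apply(a, c(1, 3, 5), mean)
  movie$pixel_pitch_um <- movie$pixel_pitch_um * f
  movie
}

#' Full calcium analysis of one movie
#'
#' Optionally downsamples the movie, builds the segmentation mask, and for
#' every annotated centre extracts the ROI trace, computes dF/F0, filters,
#' detects events and their kinetics, and summarises activity.
#'
#' @param movie a `calcium_movie`.
#' @param centers data.frame with `roi_id`, `x_px`, `y_px` (0-based, native
#'   resolution; rescaled if the movie is downsampled).
#' @param cfg a [calcium_config()].
#' @return list with `traces` (per-ROI list of F/B/dff/filtered), `events`
#'   (data.frame with `roi_id` and kinetics) and `summary`.
#' @export
analyze_calcium <- function(movie, centers, cfg = calcium_config()) {
  stopifnot(inherits(movie, "calcium_movie"))
  f <- cfg$downsample_factor
  movie <- downsample_movie(movie, f)
  mask <- build_mask(movie, cfg)
  traces <- list()
  all_events <- list()
  for (i in seq_len(nrow(centers))) {
    ctr <- c(centers$x_px[i], centers$y_px[i]) / f
    tr <- extract_trace(movie, ctr, mask, cfg)
    dff <- compute_dff(tr, cfg)
    filt <- filter_trace(dff, cfg, movie$frame_rate_hz)
    ev <- detect_events(filt, cfg, movie$frame_rate_hz)
    if (nrow(ev)) {
      ev <- do.call(rbind, lapply(seq_len(nrow(ev)), function(k)
        compute_kinetics(ev[k, ], filt, movie$frame_rate_hz)))
      ev$roi_id <- centers$roi_id[i]
      all_events[[length(all_events) + 1L]] <- ev
    }
    traces[[as.character(centers$roi_id[i])]] <-
      list(center_px = ctr, F = tr$F, B = tr$B, dff = dff, filtered = filt)
  }
  events <- if (length(all_events)) do.call(rbind, all_events) else
    data.frame(onset_idx = integer(), peak_idx = integer(),
               offset_idx = integer(), amplitude = numeric(), auc = numeric(),
               duration_s = numeric(), rise_s = numeric(), decay_s = numeric(),
               roi_id = integer())
  list(traces = traces, events = events,
       summary = summarize_activity(events, nrow(centers)))
}

#' @export
print.activity_summary <- function(x, ...) {
  cat(sprintf("Activity summary: %d/%d ROIs active (%.1f%%)\n",
              x$n_active, x$n_rois, 100 * x$proportion_active))
  if (x$n_active > 0) {
    cat("events per active cell:\n")
    print(x$events_per_active_cell)
  }
  invisible(x)
}
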