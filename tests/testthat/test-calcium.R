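make_static_movie <- function(frame, n_frames = 20, fs = 10) {
  fr <- array(rep(frame, each = n_frames),
              dim = c(n_frames, nrow(frame), ncol(frame)))
  structure(list(frames = fr, frame_rate_hz = fs, pixel_pitch_um = 0.65),
            class = "calcium_movie")
}

disk_frame <- function(H, W, cx, cy, r, inside = 10, outside = 1) {
  f <- matrix(outside, H, W)
  for (y in seq_len(H)) for (x in seq_len(W))
    if ((x - 1 - cx)^2 + (y - 1 - cy)^2 <= r^2) f[y, x] <- inside
  f
}

test_that("mask building keeps the cell, removes debris, rejects flats", {
  cfg <- fast_calcium_config(min_component_px = 50, dilation_radius_px = 2)
  fr <- disk_frame(80, 80, 40, 40, 20)
  movie <- make_static_movie(fr)
  m <- build_mask(movie, cfg)
  expect_equal(length(m$areas), 1)
  expect_true(all(m$mask[disk_frame(80, 80, 40, 40, 20, TRUE, FALSE) == 1]))
  # 3-px speck vanishes under the component-area filter
  fr2 <- fr; fr2[5, 5:7] <- 10
  m2 <- build_mask(make_static_movie(fr2), cfg)
  expect_equal(length(m2$areas), 1)
  expect_error(build_mask(make_static_movie(matrix(3, 40, 40)), cfg),
               "degenerate")
})

test_that("mask of a movie equals mask of its own max projection", {
  sim <- generate_calcium_movie(small_movie_spec(
    events = data.frame(cell_index = 1, onset_s = 10, amplitude_dff = 0.5,
                        rise_tau_s = 2, decay_tau_s = 5),
    noise_sd = 2, seed = 3))
  cfg <- fast_calcium_config()
  m_movie <- build_mask(sim$movie, cfg)
  mip_movie <- make_static_movie(max_projection(sim$movie), n_frames = 2)
  m_mip <- build_mask(mip_movie, cfg)
  expect_identical(m_movie$mask, m_mip$mask)
})

test_that("ROI extraction: disk size, uniform values, clipping, errors", {
  fr <- matrix(2, 60, 60)
  mask <- matrix(FALSE, 60, 60)
  for (y in 1:60) for (x in 1:60)
    if ((x - 31)^2 + (y - 31)^2 <= 12^2) { mask[y, x] <- TRUE }
  fr[mask] <- 7
  movie <- make_static_movie(fr)
  cfg <- fast_calcium_config()
  tr <- extract_trace(movie, c(30, 30), mask, cfg)
  expect_equal(unique(tr$F), 7)
  expect_equal(unique(tr$B), 2)
  # radius-5 lattice disk has exactly 81 pixels
  expect_equal(length(gliascope:::disk_pixel_columns(30, 30, 5, 60, 60)), 81)
  expect_warning(extract_trace(movie, c(0, 0), mask, cfg), "clipped")
  expect_error(extract_trace(movie, c(30, 30), matrix(TRUE, 60, 60), cfg),
               "background")
  expect_error(extract_trace(movie, c(600, 30), mask, cfg), "outside")
})

test_that("dF/F0 uses the per-frame background exactly as defined", {
  tr <- structure(list(F = c(2, 2, 3), B = c(1, 1, 1), frame_rate_hz = 10),
                  class = "roi_trace")
  expect_equal(compute_dff(tr, fast_calcium_config()), c(1, 1, 2))
  tr_eq <- structure(list(F = c(5, 5), B = c(5, 5)), class = "roi_trace")
  expect_equal(compute_dff(tr_eq, fast_calcium_config()), c(0, 0))
  tr_bad <- structure(list(F = c(2, 2), B = c(1, 0)), class = "roi_trace")
  expect_error(compute_dff(tr_bad, fast_calcium_config()), "background")
})

test_that("band filter removes DC and matches Butterworth gains", {
  cfg <- fast_calcium_config()
  expect_equal(max(abs(filter_trace(rep(2.5, 3000), cfg, 10))), 0)
  # designed low-pass magnitude at the 1 Hz cutoff: within 5% of 1/sqrt(2)
  lp <- signal::butter(cfg$lp_order, cfg$lp_cutoff_hz / 5, type = "low")
  fr <- signal::freqz(lp, n = 2^14, Fs = 10)
  g1 <- abs(fr$h[which.min(abs(fr$f - 1))])
  expect_equal(g1, 1 / sqrt(2), tolerance = 0.05)
  # 0.001 Hz sinusoid through the single-pass high-pass: ~1% passes
  t <- (0:149999) / 10
  x <- sin(2 * pi * 0.001 * t)
  causal <- fast_calcium_config(zero_phase = FALSE, lp_cutoff_hz = 4.9)
  y <- filter_trace(x, causal, 10)
  steady <- y[100000:150000]
  gain <- (max(steady) - min(steady)) / 2
  analog <- 0.1^2 / sqrt(1 + 0.1^4)
  expect_equal(gain, analog, tolerance = 0.05 * analog + 2e-4)
  expect_lte(gain, 0.02)
})

test_that("filtering is linear", {
  cfg <- fast_calcium_config()
  set.seed(14)
  x <- rnorm(1500); y <- rnorm(1500)
  lhs <- filter_trace(2 * x - 3 * y, cfg, 10)
  rhs <- 2 * filter_trace(x, cfg, 10) - 3 * filter_trace(y, cfg, 10)
  expect_equal(lhs, rhs, tolerance = 1e-9)
})

test_that("event detection: thresholds, zero-crossings, local minima", {
  cfg <- fast_calcium_config()
  expect_equal(nrow(detect_events(numeric(3000), cfg, 10)), 0)
  t <- seq(0, 299.9, by = 0.1)
  bump <- function(c0, a) a * exp(-((t - c0) / 5)^2)
  one <- bump(150, 0.5) - 0.01
  ev1 <- detect_events(one, cfg, 10)
  expect_equal(nrow(ev1), 1)
  expect_equal(nrow(detect_events(bump(150, 0.05), cfg, 10)), 0)
  # two bumps with a dip below zero in between: two events, ordered,
  # disjoint (reference: both peaks exceed threshold, separator <= 0)
  two <- bump(100, 0.5) + bump(200, 0.4) - 0.02
  ev2 <- detect_events(two, cfg, 10)
  expect_equal(nrow(ev2), 2)
  expect_lt(ev2$offset_idx[1], ev2$onset_idx[2])
  expect_true(all(ev2$onset_idx <= ev2$peak_idx &
                    ev2$peak_idx <= ev2$offset_idx))
  # boundaries refined to local minima: a shoulder dip above zero between
  # merged threshold crossings
  shoulder <- bump(140, 0.5) + bump(158, 0.45) - 0.02
  ev3 <- detect_events(shoulder, cfg, 10)
  expect_equal(nrow(ev3), 2)  # dip between peaks stays above 0 but is a minimum
  expect_equal(ev3$offset_idx[1], ev3$onset_idx[2])
})

test_that("raising the threshold never increases the event count", {
  # holds for well-separated smooth transients (noise wiggles can split a
  # complex at higher thresholds via the local-minima refinement)
  set.seed(31)
  for (rep in 1:5) {
    tr <- generate_trace(random_event_truths(3, seed = 400 + rep), 10, 300,
                         noise_sd = 0, seed = rep)
    f <- filter_trace(tr$dff, fast_calcium_config(), 10)
    counts <- vapply(c(0.05, 0.1, 0.2, 0.4), function(thr)
      nrow(detect_events(f, fast_calcium_config(event_threshold_dff = thr), 10)),
      numeric(1))
    expect_true(all(diff(counts) <= 0))
  }
})

test_that("kinetics of a triangular event are exact by the trapezoid rule", {
  filt <- c(0, 0.25, 0.5, 0.25, 0, 0, 0, 0, 0, 0)
  ev <- data.frame(onset_idx = 1, peak_idx = 3, offset_idx = 5)
  k <- compute_kinetics(ev, filt, frame_rate_hz = 1)
  expect_equal(k$amplitude, 0.5)
  expect_equal(k$duration_s, 4)
  expect_equal(k$rise_s, 2)
  expect_equal(k$decay_s, 2)
  expect_equal(k$auc, 1.0)
  expect_equal(k$rise_s, k$decay_s)  # symmetric event
  expect_error(compute_kinetics(data.frame(onset_idx = 3, peak_idx = 3,
                                           offset_idx = 3), filt, 1),
               "degenerate")
})

test_that("every returned event amplitude exceeds the threshold", {
  cfg <- fast_calcium_config()
  set.seed(55)
  for (rep in 1:4) {
    tr <- generate_trace(random_event_truths(3, seed = 500 + rep), 10, 300,
                         noise_sd = 0.03, seed = rep)
    f <- filter_trace(tr$dff, cfg, 10)
    ev <- detect_events(f, cfg, 10)
    if (!nrow(ev)) next
    kin <- do.call(rbind, lapply(seq_len(nrow(ev)), function(i)
      compute_kinetics(ev[i, ], f, 10)))
    expect_true(all(kin$amplitude > cfg$event_threshold_dff))
    expect_true(all(abs(kin$duration_s - (kin$rise_s + kin$decay_s)) < 1e-9))
  }
})

test_that("activity summaries count active ROIs and their event totals", {
  ev <- data.frame(roi_id = c(1, 1, 2, 5))
  s <- summarize_activity(ev, 10)
  expect_equal(s$proportion_active, 0.3)
  expect_equal(s$n_active, 3)
  ev2 <- data.frame(roi_id = c(1, 1, 2, 3))
  s2 <- summarize_activity(ev2, 10)
  d <- s2$events_per_active_cell
  expect_equal(as.integer(d[c("1", "2")]), c(2, 1))
  s0 <- summarize_activity(data.frame(roi_id = integer()), 7)
  expect_equal(s0$proportion_active, 0)
  expect_equal(s0$n_active, 0)
  expect_error(summarize_activity(ev, 0), "n_rois")
})

test_that("movie events are recovered with amplitude and onset fidelity", {
  shape <- transient_peak(1, 2, 5)$peak_value
  for (A in c(0.3, 0.5, 1.0)) {
    ev <- data.frame(cell_index = 1, onset_s = 60, amplitude_dff = A,
                     rise_tau_s = 2, decay_tau_s = 5)
    sim <- generate_calcium_movie(small_movie_spec(events = ev,
                                                   duration_s = 180))
    res <- analyze_calcium(sim$movie, sim$centers, fast_calcium_config())
    expect_equal(nrow(res$events), 1)
    # baseline/background ratio 2 scales the dF/F transient
    expect_equal(res$events$amplitude, 2 * A * shape, tolerance = 0.2)
    expect_lte(abs(res$events$onset_idx - (60 * 10 + 1)), 3)
  }
})
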