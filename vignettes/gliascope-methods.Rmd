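---
title: "Methods: astrocyte morphometry, calcium events, and viability in gliascope"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: astrocyte morphometry, calcium events, and viability in gliascope}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gliascope)
```

## What this package computes

Studies of how cultured astrocytes respond to a treatment (here, exposure to
2D nanomaterial flakes) typically quantify three things from fluorescence
microscopy: cell shape (is the morphology altered?), spontaneous somatic
calcium activity (is function altered?), and live/dead viability (is the
treatment cytotoxic?). `gliascope` implements that computational pipeline as
reusable, tested R functions: 3D morphometry from membrane/nucleus confocal
stacks, calcium event detection and kinetics from time-lapse movies,
live/dead counting from three-channel images, and the statistical battery
used to compare conditions. Because such studies rarely deposit raw imagery,
the package also ships a seeded synthetic-data generator that produces
microscopy-like inputs with exact ground truth, so every stage can be
validated by recovery rather than by eyeballing.

## 3D morphometry

### Reconstruction and segmentation

Each channel of a `(Z, Y, X)` stack is min-max normalised, blurred in-plane
(Gaussian, `blur_sigma_px = 2` by default), thresholded (Otsu on the full
volume histogram), and pooled into a coarser "unit" grid by majority vote
over `downsample_factor^3` blocks (default factor 4; one downsampled voxel
edge is the *unit*, `unit_to_um = 0.62` by default, so 100 units is about
62 um and a 50-unit volume about 12 um^3). Cells and nuclei are then
segmented by DBSCAN on the voxel coordinates (`eps = 2` units,
`min_samples = 10`; a point counts itself, the scikit-learn convention).
DBSCAN is attractive here because it needs no seed points and labels
low-density stragglers as noise instead of gluing them to a cell. No
installed R package provides DBSCAN, so the package implements it exactly on
the integer lattice (hashed neighbour lookup over the finite offset set with
norm <= eps); clusters are connected components of core points, border
points join their lowest-index core neighbour, and cells are sorted by
centroid so output is independent of input order.

Components below 50 units (cells) or 5 units (nuclei) are discarded as
fragments; the boundary value itself is kept (the rule is a strict
"below"). Each nucleus is matched to the cell containing its centroid,
falling back to the nearest cell centroid within 100 units; ties go to the
lower cell id and are logged. Cells without a nucleus are flagged and
excluded.

### The five descriptors

With `range_x`, `range_y` the inclusive voxel extents of a cell and
`X = range_x/2`, `Y = range_y/2`:

* **Aspect ratio** = `range_y / range_x`.
* **Circularity**: `C = 4*pi*A / P^2` evaluated on an ellipse fitted from
  the ranges, `A_e = pi*X*Y`, `P_e = 2*pi*sqrt((X^2+Y^2)/2)`, which
  simplifies to `C = 2XY/(X^2+Y^2)`; equal ranges give exactly 1. A second
  mode (`circularity_mode = "projected_area"`) uses the true projected area
  over the ellipse perimeter. Both are provided because published
  circularity values near 0.2 with aspect ratios near 1.4 cannot arise from
  the pure-ellipse form (it would give ~0.95), so the exact area/perimeter
  combination used in any given paper is ambiguous; neither mode is claimed
  to reproduce any particular published number.
* **Centroid distance**: Euclidean distance between body and nucleus
  centroids, reported in units and um. Distances above 100 units are a QC
  exclusion.
* **Solidity**: convex hull volume over body volume. This is the
  *reciprocal* of the common area-fraction convention; it is kept in the
  hull-over-body orientation (always >= 1, equal to 1 for convex bodies)
  because that is the orientation under which published astrocyte solidity
  means of 3-4 make sense.
* **Ramification**: `R = (P/A) / (2*sqrt(pi/A))` on the axis-aligned 2D
  projection of maximum area, with `P` the perimeter of that projection's
  convex hull; `R = 1` for a disk, `2/sqrt(pi) ~ 1.13` for a square.

### Numerical choices for the hull

Convex hulls are computed over the *corner points* of voxel cubes, not voxel
centres, via an incremental quickhull written for this package (no qhull
binding is installed). Corners guarantee every voxel set spans at least one
unit per axis, so single-layer bodies have nonzero hull volume, degenerate
(coplanar) hulls cannot occur, and the flat "plus-sign" test body gets the
exact hull volume 7 that makes its solidity oracle 7/5 = 1.4. The cost of
the corner convention is that hulls circumscribe: a voxelized ball of
radius r behaves like a polyhedral ball of radius ~r + 0.5, so its solidity
converges to 1 only as ~1 + 1.5/r. Axis-aligned convex bodies (boxes) are
exact at every size; tests bound the sphere case explicitly rather than
pretending it converges faster.

### Quality control

Records with non-finite metrics or degenerate geometry are flagged
deterministically (`boundary_abnormal`) — the package replaces a manual,
blinded inspection step with reproducible rules. An iterative two-sided
Grubbs test (alpha = 0.05) is then applied per metric across the clean
records of a condition, removing at most one record per iteration until no
value is significant. Grubbs is skipped with a warning below n = 3, and is
a no-op at zero variance.

## Calcium imaging

### Trace extraction and normalisation

A segmentation mask is built from the movie's maximum-intensity projection:
Otsu threshold, binary dilation (disk radius 3), hole filling, and removal
of components below `min_component_px` (debris). Fluorescence is averaged
over a lattice disk of radius 5 pixels (`dx^2 + dy^2 <= 25`; exactly 81
pixels) around each annotated cell centre, and the background `B_t` is the
mean over all pixels outside the mask, per frame.

The default normalisation is `dff_t = (F_t - B_t)/B_t`, i.e. F0 is the
*time-varying mean background*. This is unusual — it measures cell-over-
background contrast rather than change from the cell's own baseline, and it
leaves a large DC offset in the trace — but it has a useful side effect:
multiplicative photobleaching cancels exactly, because both F and B decay by
the same factor. A conventional per-ROI baseline mode
(`baseline_mode = "roi"`) is available but off by default.

### Filtering

Traces are filtered with a 6th-order Butterworth low-pass at 1 Hz and a
2nd-order Butterworth high-pass at 0.01 Hz, applied zero-phase
(forward-backward) by default so that event timing is not phase-shifted; a
causal single-pass mode exists for completeness. Two implementation details
matter:

* The trace mean is subtracted before filtering. The mean is pure DC — the
  high-pass removes it exactly in steady state — so this changes nothing in
  the passband but suppresses the large edge transients a DC step would
  otherwise excite. The operation remains linear.
* Forward-backward filtering uses odd-symmetric reflection padding (about
  3/cutoff seconds per side) so the filter state settles before the data
  proper begins. Without padding, the 0.01 Hz high-pass rings over tens of
  seconds at both ends of a 5-minute trace and fabricates edge "events".

Zero-phase application squares the magnitude response. A consequence worth
knowing: transients whose spectral mass approaches the 0.01 Hz corner are
attenuated noticeably. For rise/decay constants of 1-2.5 s / 2-4 s the peak
attenuation stays below ~16%; by tau_decay = 10 s it exceeds 30%. This is a
property of the specified filter chain itself, not of this implementation,
and any amplitude statistics downstream are post-filter values.

### Event detection and kinetics

Candidate events are maximal runs of the filtered trace above the fixed
threshold of 0.1 dF/F. Each run is extended outward to the nearest
zero-crossings, then the boundaries are refined inward to the nearest local
minima (plateaus credited to their earlier frame). Strictly overlapping
candidates are merged; neighbours may abut at a shared separating minimum —
that split is the point of the refinement. Events report amplitude (max
filtered value), trapezoidal AUC, and duration / rise / decay defined as the
onset-offset, onset-peak, and peak-offset spans. Under these definitions
duration = rise + decay identically; published kinetics tables in this area
are often internally inconsistent with any such partition, so the
definitions are config-documented rather than claimed to match any
particular paper. One caveat is documented and tested as such: raising the
threshold is *not* strictly monotone in event count for multi-peaked
complexes, because a higher threshold can split what a lower threshold saw
as one event. For well-separated smooth transients monotonicity holds.

An ROI is *active* if it has at least one event; summaries report the
proportion of active ROIs and the event-count distribution across active
cells.

### Calibration conditions

The detection calibration study (also run by `scripts/acceptance.R`) uses
100 seeded traces at 10 Hz for 300 s, Gaussian noise of 0.02 dF/F, and 1-4
events per trace with attained peaks in {0.3, 0.5, 1.0}, rise 1-2.5 s,
decay 2-4 s, onsets at least 45 s apart. The spacing matches recordings
with a few large events per 5 minutes and keeps the high-pass undershoot of
one event from biting into its successor (at 30 s spacing the worst-case
amplitude error grows from ~16% to ~21%). Event "amplitude" here means the
attained dF/F peak: the generator's waveform
`A*(1 - exp(-u/tau_r))*exp(-u/tau_d)` peaks below `A`, so the multiplier is
scaled so the waveform actually reaches the nominal peak. Under these
conditions recall and precision are 1.00 and ~0.99, onsets are recovered
within ~2 frames, amplitudes within ~16%, and 0.05-peak events are never
detected.

## Live/dead viability

Nuclei (total cells) are counted from the nuclear channel by blur, Otsu,
connected components, a size filter (default 25 px), and watershed on the
distance transform to split touching pairs. A nucleus is dead when the mean
dead-channel intensity in a small disk around its centroid (default radius
2 px, about one nuclear-spot sigma — a wider disk dilutes the spot below
any sensible cutoff) exceeds an Otsu-derived cutoff on that channel; dead
signal without a nucleus is ignored, and a blank dead channel yields zero.
Viability is `100*(total - dead)/total`; the live (calcein) channel is
carried for inspection but plays no role in the formula. On zero-noise
synthetic fields with spot separation at least 4x the spot radius, counts
are recovered exactly across seeds.

## Statistics

The battery mirrors standard practice in this literature: one-way ANOVA
with Tukey's HSD (viability across doses; base R `aov`/`TukeyHSD`),
pooled-variance two-sample t-tests (morphology metrics, calcium kinetics,
proportion active; base R `t.test`), the two-sample Kolmogorov-Smirnov test
with asymptotic p (event-rate distributions; base R `ks.test`), and an
iterative two-sided Grubbs outlier test implemented from the t-quantile
closed form `G_crit = (n-1)/sqrt(n) * sqrt(t^2/(n-2+t^2))`,
`t = qt(1 - alpha/(2n), n-2)`. Degrees of freedom are reported unadjusted.
Zero pooled variance with equal means returns t = 0, p = 1; with unequal
means it is an error rather than an infinity. The Tukey-vs-unadjusted
dominance property (`p_adj >= p_unadjusted`) holds when both use the same
pooled error term, which is how the test suite checks it; comparing against
a two-group t-test with its own error term can violate it legitimately.

A 10,000-replicate null simulation at the typical design size (n = 3 per
group) confirms the t-test's type-I error is 5% within Monte-Carlo margin.

## The synthetic-data generator

The generator emulates exactly the statistical structure each stage
assumes, with exact truth:

* **Morphology stacks**: axis-aligned ellipsoid bodies (optionally hollow
  shells, optionally stellate with box arms) with offset nucleus spheres,
  per-slice Gaussian blur, additive Gaussian noise (Poisson shot noise
  optional). Placement is reject-and-retry with disjoint bounding boxes
  (bounded at 1000 tries) so truth segmentation is unambiguous. Truth
  vectors are (x, y, z) um; voxel arrays are (Z, Y, X), 0-based.
* **Calcium movies**: pixels inside cell c follow
  `baseline_F_c * (1 + sum of transients) * bleach(t) + noise`, background
  follows `background_F * bleach(t) + noise`; bleaching is a single
  multiplicative exponential. Note the background-referenced dF/F0 then
  carries the baseline/background ratio as a gain on the transient.
* **Live/dead fields**: Gaussian nuclear spots with a minimum separation, a
  seeded random subset marked dead, cytoplasm disks for live cells.

Every generator is bit-reproducible for a fixed spec + seed. What the
generator does *not* emulate — real point-spread functions, camera noise
calibration, overlapping and touching cells, GFAP filament texture,
process-level (non-somatic) calcium microdomains, nanomaterial flakes in
the imagery — bounds what passing tests prove: recovery results show the
pipeline's computations are correct under their stated assumptions, not
that the pipeline would segment arbitrarily crowded real cultures.

## Problem sizes and determinism

The test suite and acceptance script run, by choice, at desk scale: a
44 x 150 x 150-voxel stack of five cells at 0.62 um pitch for morphometry
recovery, 100 traces of 3000 frames for detection calibration, 512 x 512
live/dead fields with 100 cells, and 10,000 null replicates for test
calibration. All randomness flows through explicit integer seeds; identical
inputs and configuration give identical outputs, including cluster and cell
ordering.

## Known limitations

* The corner-point hull convention inflates solidity for small curved
  bodies (see above); comparisons should be within-pipeline, not across
  conventions.
* Background-referenced dF/F0 makes amplitudes depend on staining contrast
  (the baseline/background ratio); the conventional per-ROI mode is
  available when absolute amplitudes matter.
* Event rise/decay definitions are one defensible partition of an event;
  they are not canonical.
* Morphometry assumes non-touching cells; DBSCAN will merge cells whose
  processes contact at high density.
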