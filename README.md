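# gliascope

Quantitative image analysis for astrocyte culture experiments: 3D
morphometry, spontaneous calcium activity, and live/dead viability, with the
statistics used to compare treatment conditions and a seeded synthetic-data
generator that provides exact ground truth for every stage.

## The problem

When cultured astrocytes are exposed to a treatment — here, dispersions of a
2D nanomaterial — three questions are asked of the microscopy: did cell
*shape* change, did spontaneous *calcium signalling* change, and did cells
*die*? Answering them reproducibly requires a pipeline, not a collection of
one-off scripts: segmentation of membrane/nucleus confocal stacks into
single cells, shape descriptors with exact definitions, event detection on
noisy fluorescence traces, counting rules for live/dead assays, and a
defined statistical battery. `gliascope` packages that pipeline as tested R
functions for researchers who need to run or audit such analyses.

## What it computes

**3D morphometry** (`analyze_morphology`): channels are normalised,
blurred, Otsu-thresholded, and majority-vote downsampled into a unit grid;
cells and nuclei are segmented by DBSCAN on voxel coordinates, filtered by
volume (cells < 50 units and nuclei < 5 units are fragments), and matched.
Five descriptors per cell, with `X = range_x/2`, `Y = range_y/2`:

| descriptor | definition |
|---|---|
| aspect ratio | `range_y / range_x` |
| circularity | `4πA/P²` on the range-fitted ellipse, = `2XY/(X²+Y²)` |
| centroid distance | ‖body centroid − nucleus centroid‖₂ (units and µm) |
| solidity | convex-hull volume / body volume (≥ 1; hull-over-body orientation) |
| ramification | `(P/A) / (2√(π/A))` on the max-area projection, hull perimeter |

QC removes cells without nuclei, centroid distances > 100 units (≈ 62 µm),
degenerate geometry, and per-metric iterative Grubbs outliers (α = 0.05).

**Calcium events** (`analyze_calcium`): Otsu mask from the
maximum-intensity projection (dilation, hole filling, debris removal);
fluorescence from 5-pixel-radius ROIs (exactly 81 pixels); per-frame
background-referenced ΔF/F₀ `(F_t − B_t)/B_t`; 6th-order Butterworth
low-pass (1 Hz) plus 2nd-order high-pass (0.01 Hz), zero-phase; events are
threshold crossings (0.1 ΔF/F) extended to zero-crossings and refined to
local minima, with amplitude, trapezoidal AUC, duration, rise, and decay;
activity summaries report the proportion of ROIs with ≥ 1 event.

**Viability** (`analyze_viability`): total cells from the nuclear channel
(blur, Otsu, size filter, watershed splitting of touching nuclei); dead
cells by dead-channel colocalisation with a nucleus; `viability (%) =
100 · (total − dead)/total`.

**Statistics** (`one_way_anova_tukey`, `two_sample_t`, `ks_two_sample`,
`grubbs_test`): one-way ANOVA with Tukey HSD, pooled-variance two-tailed t,
two-sample Kolmogorov–Smirnov, and iterative Grubbs outlier testing.

**Synthetic data** (`generate_morphology_stack`, `generate_calcium_movie`,
`generate_trace`, `generate_viability_field`): seeded generators emitting
ellipsoid cells with offset nuclei, calcium movies with
`A(1−e^{−u/τ_r})e^{−u/τ_d}` transients, bleaching and noise, and live/dead
fields — each with exact analytic ground truth.

## Worked example

```r
library(gliascope)

# two synthetic cells: a 5 µm sphere and a 5x10x5 µm ellipsoid
cells <- list(
  cell_truth(center_um = c(15, 15, 12), semi_axes_um = c(5, 5, 5),
             nucleus_offset_um = c(1, 0, 0), nucleus_radius_um = 2),
  cell_truth(center_um = c(45, 15, 12), semi_axes_um = c(5, 10, 5),
             nucleus_offset_um = c(0, 2, 0), nucleus_radius_um = 2))
sim <- generate_morphology_stack(
  morph_stack_spec(grid_shape = c(24, 64, 64), voxel_pitch_um = 1,
                   cells = cells, seed = 1))
res <- analyze_morphology(sim$stack,
                          morph_config(downsample_factor = 1,
                                       blur_sigma_px = 1, unit_to_um = 1))
res$records
#>   cell_id aspect_ratio circularity centroid_distance_um solidity ramification
#> 1       1            1         1.0                    1     1.26         1.07
#> 2       2            2         0.8                    2     1.23         1.13
```

The sphere scores aspect ratio 1 and circularity 1; the 2:1 ellipsoid
scores aspect ratio 2 and circularity `2·2·1/(2²+1²) = 0.8`. Centroid
distances recover the planted 1 µm and 2 µm nucleus offsets; solidity is
slightly above 1 because voxelized curved bodies are not perfectly convex.

```r
ev <- data.frame(cell_index = 1, onset_s = 30, amplitude_dff = 0.5,
                 rise_tau_s = 2, decay_tau_s = 5)
movie <- generate_calcium_movie(calcium_movie_spec(
  frame_shape = c(48, 48),
  cells = data.frame(center_x_px = 24, center_y_px = 24, radius_px = 8,
                     baseline_F = 200),
  events = ev, background_F = 100, duration_s = 120, seed = 1))
out <- analyze_calcium(movie$movie, movie$centers,
                       calcium_config(downsample_factor = 1))
out$events
#>   roi_id onset_idx amplitude  auc duration_s rise_s decay_s
#> 1      1       302     0.354 2.19         13    2.4    10.6
```

One event is detected, onset within 2 frames of the planted 30 s. The raw
ΔF/F transient peaks at `2 × 0.5 × 0.433 = 0.43` (the baseline/background
ratio 2 scales the waveform peak); the reported 0.354 is the post-filter
amplitude — the 1 Hz/0.01 Hz zero-phase chain attenuates transients of
these time constants by ~17%, a property of the filter chain discussed in
the methods vignette.

```r
field <- generate_viability_field(
  viability_field_spec(n_total = 100, n_dead = 12, frame_shape = c(512, 512),
                       seed = 1))
analyze_viability(field$image)[c("total", "dead", "viability_pct")]
#> total 100, dead 12, viability 88.0%

two_sample_t(c(1, 2, 3), c(2, 3, 4))
#> two_sample_t: statistic = -1.2247, df = 4, p = 0.2879
```

## Command-line interface

A thin CLI over the same functions ships at `inst/cli/gliascope.R`:

```sh
CLI=$(Rscript -e 'cat(system.file("cli/gliascope.R", package = "gliascope"))')
Rscript $CLI simulate morph --spec spec.yaml --seed 3 --out sim/
Rscript $CLI morph     --in sim/stack.tif --config morph.yaml --out records.csv
Rscript $CLI calcium   --movie mov.tif --centers centers.csv --out out/
Rscript $CLI viability --in field.tif --out counts.csv
Rscript $CLI stats     --design design.yaml --out report.json
```

Every run echoes its resolved configuration next to the outputs; all
randomness flows through `--seed`.

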