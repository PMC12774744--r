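---
title: "Quantifying mitochondrial dynamics in islet cells: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying mitochondrial dynamics in islet cells: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(isletmito)
```

## The measurement problem

Mitochondria in intact pancreatic islets cannot be tracked object by
object: the cells sit in a three-dimensional tissue and organelles drift
through the roughly 1 µm optical section faster than they can be
reidentified. The motility quantifier implemented here therefore works
at the pixel level. Over a short time series (by default 18 frames, 5 s
apart, about 1.5 min), a pixel crossed by moving mitochondria shows
large intensity fluctuations, while a pixel over a stationary
mitochondrion — or over empty cytosol — does not. The temporal standard
deviation per pixel is the motility proxy; the temporal mean is kept
alongside it as the control for intensity-driven artifacts.

## The motility statistic, step by step

1. **SD projection.** `temporal_sd_projection()` computes the per-pixel
   sample standard deviation (denominator `T − 1`, the usual z-project
   convention) and the temporal mean.
2. **Nucleus and classification.** The nucleus is segmented by Otsu
   thresholding of the temporal-mean nuclear-marker channel within the
   cell outline (largest component, holes filled). Cells without the
   marker fall back to the largest dark region of the mitochondrial
   channel — an inference flagged as such: in sparse synthetic cells
   this region can extend beyond the true nucleus, which is why
   marker-negative cells are classified reliably (their marker intensity
   is near zero regardless of the mask) but profiled less reliably.
   Classification thresholds the per-cell mean marker intensity (Otsu
   over cells by default, fixed cutoff optionally).
3. **Normalization.** The SD image is divided by its maximum within the
   cell mask, nucleus included, making values unitless in [0, 1] and
   cancelling intensity scale exactly (a property the test suite checks
   to 1e-10). The pre-normalization maximum is reported as the cell's
   maximal motility. A cell with identically zero SD is flagged
   degenerate and yields zeros, never NaN.
4. **Radial profiles.** `360/θ` rays (θ = 10° by default; 1° supported)
   are cast from the nucleus centroid; if the centroid falls outside a
   pathologically shaped mask, the most interior mask pixel is used
   instead, with a warning. Each profile starts at the ray's last
   crossing of the nucleus boundary and samples the normalized SD by
   bilinear interpolation at pixel-size steps out to the 7 µm cytosolic
   fraction. Rays whose nucleus-to-membrane span is below 7 µm are
   excluded rather than truncated, so every retained profile has the
   same length and distance bins stay balanced across cells; a
   `truncate_short` switch provides the other convention for sensitivity
   analysis.
5. **Summary.** Retained profiles are averaged into 0.5 µm distance bins
   and into one overall mean normalized motility per cell. The QC value
   `qc_sd_mean_r` is the Pearson correlation between SD and mean images
   over the cell.

The 7 µm fraction, θ, bin width, and the normalization scope (whole-cell
versus sampled-lines maximum) are all explicit parameters recorded in
the output metadata.

## What the synthetic generator emulates

`simulate_movie()` produces the study conditions the analysis expects:
round islet cells (radius 12 µm, nucleus 4 µm — large enough that every
ray spans the 7 µm fraction), a MitoTracker-like channel summing
elongated Gaussian blobs, and a nuclear channel bright only in
marker-positive ("alpha") cells. Defaults: 18 frames at 5 s, 0.25 µm
pixels, 50 mitochondria per cell with apparent (PSF-convolved) axes of
2 × 1 µm, peak intensity 200 counts, Poisson noise followed by Gaussian
read noise (σ = 0.5), and 3% bleaching per frame — a realistic
spinning-disk regime with visible but not dominant photobleaching.

Motile blobs follow a random walk with per-frame, per-axis step σ
(default 0.3 µm) in x, y **and z**: in-plane excursions reflect at the
cell and nucleus boundaries, and the axial coordinate modulates blob
intensity through a Gaussian optical-section profile (σ = 0.5 µm,
excursions reflected at ±2σ). The axial component matters: it is the
in/out-of-plane fluctuation that makes whole-islet recordings
untrackable in the first place, and it spreads temporal variance over
entire blob footprints instead of only their edges. Without it (and with
unrealistically sharp sub-diffraction blobs) the normalized statistic is
not monotone in the step size, because at zero motion the per-cell
maximum SD is only a noise extreme while any motion inflates the maximum
faster than the mean. With the defaults above, condition-mean motility
increases strictly over step σ ∈ {0, 0.1, 0.3, 0.6} µm and the static
condition separates from 0.6 µm by well over 5 SEM (10 seeds of 2-cell,
all-alpha fields; the acceptance script re-derives this).

What the generator does **not** emulate: real point-spread-function
optics beyond the Gaussian blob shapes, intercellular background,
organelle shapes other than ellipses, fission/fusion, directed
(motor-driven) transport, and axial structure beyond the single-section
attenuation. Passing tests therefore demonstrate that the pipeline
measures what it claims on data with known ground truth — not that any
particular biological effect size will reproduce in real islets.

## Morphometry conventions

Polygon area uses the shoelace formula and perimeter the vertex-chain
length. "Length" and "width" are the major/minor axes of the
moment-matched ellipse (the common Fit-Ellipse convention; a
minimum-area bounding-box alternative is available), so AR = 1 for any
centrally symmetric shape. Form factor and circularity are computed from
their defining formulas and are exact algebraic reciprocals — asserted
to 1e-12 on every computed polygon rather than assumed. Minimum
distances are boundary-to-boundary, zero on contact or overlap,
component-minimum over multi-part Golgi, and `NA` ("absent") when no
Golgi is annotated, which keeps sections without visible Golgi out of
distance statistics instead of contributing spurious zeros. The distance
to the plasma membrane is computed but carries a 2D-section caveat in
the metadata: a single section systematically overestimates the distance
to a large, gently curved boundary, so it is deliberately not a headline
metric.

Shortest-distance ground truth in the TEM generator comes from dense
boundary sampling (10⁴ points per polygon, two-stage pruned brute
force), a deliberately independent oracle for the analytic
segment-to-segment computation; the two agree within twice the sampling
step.

## Ratiometric analysis

The R476/405 ratio is formed per pixel where the denominator clears a
floor (default: 1% of the denominator's 99th percentile — high enough to
suppress divide-by-noise, low enough to keep dim cytosol). No background
subtraction precedes the ratio by default; a constant-offset option
exists but is off. The sub-membrane shell is defined by the Euclidean
distance transform of the rasterized cell at 4 µm; on a 10 µm disk at
0.1 µm pixels the shell area matches the analytic annulus within a
fraction of a percent. Microdomain detection (shell mean + 2 SD,
≥ 0.5 µm²) is an explicit operationalization of what was a visual call
in the source experiments; both thresholds are parameters, and the
defaults are conventions, not published constants.

Rolling-ball background estimation uses the classical ball structuring
element (grey erosion then dilation with ball heights). Radii above
16 px run on a min-reduced grid with the radius scaled down, then the
background is bilinearly upsampled and clipped to never exceed the
image — the standard large-radius practice; the reduced and
full-resolution computations agree within a few percent of the intensity
range in the tests, and a constant image yields exactly zero correction.

## Statistics and determinism

The only data filter applied is the stated mean ± 2 SD rule: a single
pass with the sample SD computed once on the full input. It is
deliberately not iterated — re-applying it to the kept values can remove
more, and the tests pin that behaviour down as a contract. Group
summaries report mean ± SEM after per-group filtering. Inference beyond
a plain Welch two-sample summary is out of scope; those comparisons
belong in dedicated statistics software.

All simulation and analysis paths are deterministic given a seed:
identical configurations produce byte-identical CSV outputs (no
timestamps are written), which the acceptance script verifies
end-to-end.

## Numerical choices and edge cases

* Pixel convention: 0-based indices, x = column, y = row, pixel centers
  at integer coordinates; a pixel belongs to a polygon when its center
  is inside under the even-odd rule, boundary ties counting as inside.
  Label-mask polygonization traces pixel cracks at half-integer
  coordinates, so rasterizing the traced polygon reproduces the mask
  pixel for pixel.
* Profile sampling clamps interpolated values into [0, 1]; outside-cell
  neighbours of boundary pixels are treated as zero, which can only
  touch the last sample of a profile that ends exactly at the membrane.
* Otsu thresholds are computed on 256-bin histograms of the masked pixel
  values (a mask-aware reimplementation of the standard criterion, since
  whole-image thresholders cannot be restricted to a cell ROI).
* Degenerate inputs fail loudly and specifically: uniform nuclear
  channels ("nucleus not found"), empty shells, cells too small for the
  7 µm fraction, non-positive calibration values, self-intersecting
  polygons (reported with their cell id).

## Problem sizes

The shipped tests and the acceptance script run entirely on simulated
data sized for interactive use: 2-cell fields of 112 × 224 px × 18
frames for the motility recovery experiment (4 step conditions × 10
seeds), 9 TEM cells for the distance oracle, and 10 seeds for
microdomain recovery. The full acceptance run takes about a minute on a
single CPU; the test suite under two minutes.
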