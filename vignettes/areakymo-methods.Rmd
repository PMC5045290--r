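---
title: "Methods: quantifying rapid growth and apoplastic pH dynamics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantifying rapid growth and apoplastic pH dynamics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(areakymo)
```

## Scope

Etiolated hypocotyl segments respond to auxin within tens of minutes: the
segment elongates, the apoplast (cell-wall space) acidifies, and
transcriptional auxin reporters light up, all after a lag of roughly
20 minutes. `areakymo` implements the measurement chain used to quantify
these responses from time-lapse imaging: ratiometric area-kymograph analysis
of a dual-fluorophore apoplastic pH sensor, drift stabilization,
silhouette morphometry, lag-phase (onset) estimation, luminescence
region-of-interest kinetics, and gravitropic angle/flank quantification.
It also ships a synthetic-data generator that emulates each input modality
with known ground truth, so that every stage can be verified by parameter
recovery rather than by eye.

Conventions used throughout: pixel coordinates are 0-based with x rightward
and y downward; time is minutes since treatment; angles are degrees with 0
horizontal and +90 vertical (up).

## The ratiometric pH model

The apoplastic sensor pairs a pH-insensitive reference fluorophore (mRFP-type,
channel `ref`) with a pH-sensitive one (GFP-type, channel `sense`) that is
quenched by protonation. We model the sense brightness with the standard
single-site protonation sigmoid

$$B(\mathrm{pH}) = \frac{1}{1 + 10^{\,pK_a - \mathrm{pH}}},$$

with default apparent $pK_a = 6.0$, typical for GFP-derived sensors. $B$ is
strictly increasing in pH, so the per-pixel ratio `sense/ref` drops as the
wall acidifies; at $\mathrm{pH} = pK_a$ the noiseless ratio is exactly 0.5.
No published calibration ties the sensor's ratio to absolute pH in planta,
so the package never reports absolute pH: ratios are the observable, and pH
is only a latent variable of the synthetic generator.

The generator's pH time course is a step onset followed by an exponential
approach: constant `ph_initial` before `onset_min`, then relaxation toward
`ph_final` with time constant `tau_min`. The onset is a slope discontinuity
(the "sudden" drop); `tau_min` sets how fast the new steady state is
approached. The default is `tau_min = 50` min over a 55-minute imaged window
(12 frames every 5 min): the decline is still in progress when imaging
stops, as in real ratio traces, and — importantly for onset estimation —
the post-onset arm of the trace is then close to linear (see *Onset
estimation* below).

## The AreaKymo algorithm

Per frame:

1. **Wall selection** (`wall_mask`): pixels with reference intensity
   *strictly above* a user-chosen threshold. Strict `>` rather than `>=` is
   an arbitrary but fixed convention. The threshold is a user input set to
   isolate the bright wall signal, not an estimated quantity; raising it can
   only shrink the mask. An empty frame is a warning and is reported as
   `n = 0`, never an error.
2. **Ratios** (`pixel_ratios`): `sense/ref` at every masked pixel, oriented
   so that lower = more acidic. The threshold being positive guarantees a
   positive denominator.
3. **Rendering** (`area_kymograph`): each timepoint's ratios are packed into
   a fixed-width rectangle, rectangles stacked top-to-bottom in time. The
   original description leaves the packing order unspecified; we use raster
   order of the mask coordinates, filling each block row-major, and drop
   overflow beyond `rect_width * rows_per_block` from the tail, recording
   the drop count. This makes the image deterministic and auditable:
   placed + dropped always equals the mask size. Unfilled cells are `NA`,
   which no ratio can take.
4. **Summaries** (`frame_summary`): five-number summary plus two mean
   variants per frame. Quartiles interpolate linearly between order
   statistics (`quantile(type = 5)`; for ratios {0.2, 0.4, 0.6, 0.8} this
   gives Q1 = 0.3, Q3 = 0.7). `mean_of_ratios` averages per-pixel ratios;
   `ratio_of_means` divides mean sense by mean reference over the mask —
   the manual ROI protocol. The two agree exactly whenever the reference is
   uniform over the mask, which the tests exercise.

No background subtraction is applied by default (none is part of the
original protocol). Multiple segments can be pooled by concatenating their
mask pixels per timepoint before summarizing.

## Drift stabilization

Time series are stabilized by translation only (`estimate_translation`,
`apply_shifts`), matching the translation-mode registration used for
confocal stacks. Shifts are integer pixels chosen to maximize circular
cross-correlation (via FFT) on the pH-insensitive reference channel — the
channel that is stable under the biology. Integer shifts mean retained
pixel values are never interpolated, so downstream ratio statistics are
untouched; vacated margins become `NA` and drop out of wall masks. The
estimator is exact for integer circular shifts of any non-degenerate frame,
which is what the closed-loop drift-injection tests assert. Sub-pixel
refinement is deliberately absent: at the assay's sampling it would buy
nothing and would force interpolation into the ratios.

## Morphometry

**Segment length** is the Feret diameter (maximum caliper) of the
thresholded silhouette. Pixels are modelled as unit squares: the diameter is
the maximum pairwise distance between corner points of boundary pixels,
computed over the convex hull. This makes the degenerate cases well defined
(a single pixel measures $\sqrt 2$; a 3 × 4-pixel rectangle measures 5) and
matches the common Feret convention. An O(n²) brute-force oracle over all
corner pairs backs the implementation in the tests. Growth traces normalize
to the first frame, which is *exactly* 100 % by construction, making the
percentage trace calibration-free; `px_per_mm` is optional metadata for
millimetre output only.

**Auto-thresholding** uses Otsu's criterion (the original protocol
thresholded manually without stating a rule); a seed point can select a
specific connected component, otherwise the largest is taken.

**Tip angle** skeletonizes the mask (Zhang–Suen thinning, written here
because no installed image package provides 2-D thinning), finds the free
end, and reports the principal-axis direction of the skeleton points within
`tip_window_px` of that end (default 20 % of the skeleton length), oriented
toward it. The free end is the endpoint farthest from a user-supplied basal
point when given; otherwise the uppermost endpoint (smallest row, ties
toward larger x) — hypocotyls grow upward, so in the default assay the
apical end is the top one. Recovery is within 2° of the generator's angle
across ±80° when the basal end is identified; without it, a rod pointing
below the horizon is reported by its upper end, which flips the sign — the
reason the basal point exists.

## Onset (lag-phase) estimation

How "the response could be detected after ~20 min" was originally measured
is not specified; this package *defines* the lag operationally as the
breakpoint of a continuous two-segment piecewise-linear least-squares fit
(`detect_onset`). The breakpoint is searched exhaustively over the observed
sample times (no sub-sample interpolation — the 5-minute sampling dominates
precision anyway), each candidate fit solved through the hinge basis
$(1,\; t,\; \max(t - t_c, 0))$. A direction constraint (post-slope greater
than pre-slope for growth and luminescence, smaller for acidification)
rejects degenerate fits; if no candidate satisfies it the result is a
diagnostic "no onset", not an error — a flat trace is a legitimate outcome
of a control assay. SSE ties break toward the earliest candidate
(conservative lag). An optional residual-resampling bootstrap (200
replicates, seeded) gives a half-width, since the original statistics are
between-replicate standard deviations, not per-trace intervals.

Two numerical details matter. First, the direction constraint uses a
relative slope tolerance scaled to the trace, so an exactly flat trace is
never promoted to an onset by floating-point noise. Second — and this is a
genuine property of two-segment fitting, not an implementation artifact —
the model assumes the response is approximately *linear after onset within
the fitted window*. If the window extends far into a post-response plateau
(a sigmoid seen in full), the best two-segment fit locks onto the *end* of
the transition instead of its start, or fails the direction constraint
altogether. The practical rule, encoded in the generator defaults and
stated here as analysis guidance: end the fitted window soon after the
response is established, or restrict `detect_onset` to that window. The
55-minute pH window with `tau_min = 50` and the 2-hour elongation window
with linear growth both satisfy this; the closed-loop recovery tests
(12 replicates each) recover the generating mean onset within 1.5 sampling
steps.

## Transit-time arithmetic

`transit_time` converts a transport velocity into the time for auxin to
reach the midpoint of an excised segment. With bilateral entry (both cut
ends), the path is half the segment length: a 1.2 mm segment at 8 mm/hr
gives (0.6 mm)/(8 mm/hr) · 60 = 4.5 min.

## The synthetic generators: what they emulate and what they do not

* `generate_ph_series`: a two-channel confocal-like series of a bright
  cell-wall lattice. Cell sizes are jittered around `wall_spacing_px`
  (default 16 px at 0.5 µm/px, i.e. ~8 µm cells in cross-section) — real
  tissue is irregular, and the aperiodicity also keeps drift estimation
  well-posed. Wall reference intensity 1000, background 50, additive
  Gaussian noise sd 20 (≈2 % of signal), clipped at zero. Optional
  `flank_delta_ph` acidifies the lower half of the frame for
  flank-asymmetry scenarios.
* `generate_elongation_series`: a scanner-like silhouette, lag phase then
  linear growth (default onset 20 min, 30 %/hr, 2-hour window at 5-minute
  frames). The rod is rendered as a *capsule* so its true tip-to-tip length
  equals the nominal length exactly (a rectangle's Feret is its diagonal);
  pose wobble (sd 1°) and length jitter (sd 1 px) emulate repositioning and
  digitization noise, and the recorded ground truth is the noiseless
  schedule.
* `generate_luminescence_trace`: baseline, then a saturating exponential
  rise, continuous at the onset.
* `generate_bending_series`: binary rod masks rotating at a fixed rate and
  saturating at the final angle.

All generators are bit-identical under a fixed seed, and ground truth is
returned alongside the data but never read by analysis code — only the
tests compare against it.

What passing the closed-loop tests does *not* show: performance on real
tissue with uneven reporter expression, z-drift, bleaching, photon
(Poisson) noise, curved or touching organs, or wall geometry beyond a
jittered lattice. The generator validates the algorithms' correctness and
calibration-free conventions, not their robustness to every imaging
pathology.

## Numerical and I/O choices

* TIFF stacks are written as integer counts (8/16/32-bit) — the native form
  of camera and scanner data — pages frame-major with channels in declared
  order, with channel labels and calibration in a JSON sidecar. Round trips
  are bit-identical for integer-valued series; continuous generator output
  is rounded at write time.
* The area-kymograph TIFF is 16-bit, scaled to the recorded LUT range, with
  0 reserved for no-data cells.
* Reports (`run_report`) record thresholds, per-frame mask sizes, dropped
  pixel counts, shifts, file checksums and the package version, so any
  output can be reproduced from its report.
* Problem sizes used by the test-suite and acceptance computations: 96 × 96
  px pH frames (12 per series), 120 × 340 px elongation frames (24 per
  series), 12 replicate series per recovery experiment — small enough to
  re-run everywhere, large enough that mask sizes (~2000 wall pixels per
  frame) make medians stable.

## Known limitations

* Two segments only: multi-phase responses (lag, rise, plateau) are fitted
  piecewise by the user choosing windows, not by a k-segment search.
* Translation-only registration; rotation or deformation must be handled
  upstream.
* The flank analysis assumes the two flanks can be enclosed in user-drawn
  disjoint polygons; it does not segment the organ.
* Absolute pH is out of reach by design; only ratio dynamics and their
  timing are quantified.
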