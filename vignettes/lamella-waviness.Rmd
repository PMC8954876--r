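---
title: "Measuring elastic-lamella waviness with lamwave"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring elastic-lamella waviness with lamwave}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(lamwave)
```

## The measurement model

Elastic lamellae of the arterial media appear on a 2D tomographic slice
as thin bright curves. Their waviness is the physiological reserve
length of the vessel wall: a wavy lamella can unfold before it carries
tensile load, a straightened one cannot. `lamwave` condenses the
waviness of one lamella fragment into the arc–chord ratio

$$ r_{ec} \;=\; \frac{L_{euclid}}{L_{geodesic}} \in (0, 1], $$

where $L_{geodesic}$ is the curvilinear length of the fragment's
centerline polyline and $L_{euclid}$ is the sum of straight chords
between points marked every 100 units of curvilinear length along it
(plus the final vertex). For a straight fragment the chords coincide
with the curve and $r_{ec} = 1$; undulation shortens every chord
relative to its arc, so $r_{ec} < 1$. Working with chords every 100
units rather than a single end-to-end chord keeps the statistic
sensitive to the *local* waviness of long fragments instead of their
global curvature around the vessel lumen.

The per-slice procedure is:

1. **Threshold** the grayscale slice at `otsu_factor` (default 2.0)
   times the Otsu threshold. Lamellae are the brightest structures in a
   wall-dominated histogram; a single Otsu split would also pick up
   bulk wall signal, while twice that value isolates the lamellar
   cross-sections.
2. **Label** connected foreground regions (8-connectivity by default)
   and compute area, bounding-box occupancy (extent) and solidity.
3. **Filter** regions: keep a fragment iff area ≥ `min_area` (100 px,
   discards specks), occupancy < `max_bbox_occupancy` (0.15, discards
   dense patches where several lamellae superimpose) and solidity <
   `max_solidity` (0.36, discards unstructured blob-like zones such as
   adventitia). Following the verbal definitions, the area rule is
   non-strict ("above or equal") while the occupancy and solidity rules
   are strict ("below" / "less than").
4. **Skeletonize** each kept fragment to a one-pixel-wide 8-connected
   centerline and keep the **longest path** of its adjacency graph,
   which removes side branches.
5. **Subsample/oversample**: take every `s`-th path pixel (default
   `s = 3`, final pixel always retained), then linearly interpolate
   vertices back into each gap so the polyline regains the original
   vertex count. This suppresses the 8-connected staircase error, which
   otherwise inflates $L_{geodesic}$ by up to ~8% on oblique segments.
6. **Measure** $L_{geodesic}$, $L_{euclid}$ and their ratio.

Cohorts are compared on **per-stack mean** $r_{ec}$ — one value per
specimen stack — with the two-sided Wilcoxon–Mann–Whitney rank-sum test
with continuity correction; the exact permutation p-value is reported
alongside whenever both groups are small and tie-free. The stack, not
the fragment, is the statistical unit: fragments within a stack are
strongly correlated (same specimen, often the same lamella across
slices), and testing the ~10^4–10^5 fragments directly would make any
difference "significant". Shapiro–Wilk p-values per group are attached
as diagnostics only; they never gate the nonparametric test. No
multiple-testing correction is applied across the regional scopes
(arch/thoracic/abdominal) — each scope is reported as its own
comparison.

## Tunable parameters

| parameter | default | units | role |
|---|---|---|---|
| `otsu_factor` | 2.0 | — | threshold multiplier over Otsu |
| `min_area` | 100 | px | minimal fragment area (non-strict) |
| `max_bbox_occupancy` | 0.15 | fraction | strict upper bound on extent |
| `max_solidity` | 0.36 | fraction | strict upper bound on solidity |
| `connectivity` | 8 | — | labeling connectivity (4 or 8) |
| `s` | 3 | px | subsampling factor of the skeleton path |
| `step` | 100 | px | geodesic spacing of the chord marks |

Connectivity defaults to 8 because thin strokes at oblique angles
fragment into single pixels under 4-connectivity; 4 remains available
for sensitivity checks. `s` and `step` are exposed so the robustness of
any conclusion to the sampling scheme can be verified directly (the
validation suite checks that the cohort verdict is identical for
`s` in 1–3).

## The synthetic-data generator

Real volumes at this resolution are tens of gigabytes and not
redistributable, so validation runs entirely on synthetic stacks with
analytically known truth. `curve_spec()` defines a planar curve —
straight segment, sinusoid along a rotated chord axis, or circular arc —
and `curve_truth()` supplies its arc length (closed form or adaptive
quadrature), chord length, and the step-chord $r_{ec}$ obtained by
applying the same 100-unit chord rule to a dense analytic sampling
(about 8 vertices per pixel of arc). Using the step-chord truth rather
than the pure chord/arc ratio makes recovery tests compare like with
like; both values are stored.

`render_slice()` stamps a disc of diameter `stroke_thickness` along a
dense sampling of each curve (which guarantees an 8-connected stroke),
adds distractor objects, and applies additive Gaussian noise clamped to
[0, 255]. Each distractor kind is constructed to violate exactly one
filter rule: a small disc (*speck*, area < 100), a connected raster of
parallel lines (*dense texture*, occupancy ≈ 0.28 but solidity < 0.36),
and a solid oblique band (*solid blob*, solidity ≈ 1 but, thanks to its
45° orientation, occupancy < 0.15). A compact convex blob could not
serve here: it violates the occupancy rule before the solidity rule, so
the adventitia-style distractor is deliberately elongated and oblique.

Default render levels are background 30, foreground 220, noise sd 10 on
an 8-bit scale. With a background-dominated histogram the Otsu value
settles just above the background noise tail (≈ bg + 4.5 sd), so twice
Otsu (~150) sits far below the foreground distribution and strokes
survive thresholding intact; brighter backgrounds would push 2×Otsu into
or above the foreground and shred thin strokes.

`cohort_spec()`/`generate_cohorts()` assemble seeded two-group datasets.
The group effect is injected through the sinusoid amplitude distribution
only (wavelength held common): wavier control lamellae versus smoother
diabetic ones, the simplest mechanism producing a mean-$r_{ec}$ offset.
`solve_amplitude()` inverts the analytic amplitude → $r_{ec}$ map by
root finding, so a scenario can target exact true group means;
`demo_cohorts()` uses it to build a compact study with true means
0.823 vs 0.889, values typical of healthy versus diabetic murine aorta.

What the generator does **not** emulate: phase-contrast imaging physics,
reconstruction artifacts, curvature of lamellae around the lumen
(synthetic chords are straight axes), lamella branching and contact,
intensity inhomogeneity, and the 3D lattice of inter-lamellar fibers.
Passing validation therefore demonstrates that the *measurement chain*
is correct and calibrated on curves of known length — not that the
biological variability of real vessels is captured.

## Numerical choices

- **Otsu** is computed by exhaustive between-class-variance
  maximization over a 256-bin histogram after min–max rescaling to
  [0, 255], taking the first maximizing bin and mapping it back to the
  original intensity scale. Float inputs thus share one well-defined
  binning convention.
- **Convex hull pixel counting** includes pixels whose centers lie
  inside *or on* the hull of the region's pixel centers; a degenerate
  (collinear) region counts as its own hull, giving solidity 1.
- **Thinning** uses the Guo–Hall two-subiteration scheme. Zhang–Suen
  thinning was rejected after it was observed to erode the open ends of
  oblique strokes pixel by pixel, truncating fragments by tens of
  pixels and biasing $r_{ec}$ upward by up to 0.05.
- **Longest path** is found exactly — by exhaustive search on small
  graphs (≤ 40 pixels) and by a double-sweep farthest-pair search on
  trees, which thinned strokes essentially always are; a cyclic
  skeleton with no endpoints is opened at its lexicographically
  smallest pixel. Path length is counted in vertices; ties resolve
  toward the lexicographically smallest start pixel, making results
  order-independent and reproducible.
- **Subsampling** always retains the final path pixel; a trailing
  partial gap of `r` pixels receives `r − 1` interpolated vertices so
  the vertex count is exactly preserved. Paths shorter than `s + 1`
  pixels fall back to `s = 1`.
- **Chord marks** are placed at geodesic positions 0, 100, 200, … by
  linear interpolation along the polyline, and the final vertex is
  always appended as a mark (otherwise up to 99 units of curve would be
  ignored). Short polylines fall back to a single end-to-end chord
  (length < 100) or to two chords through the existing vertex nearest
  to half the geodesic length, ties to the earlier vertex (length
  < 200). These cutoffs are the natural reading of "shorter lines" and
  are recorded as constants.
- **Degenerate fragments** (skeletons under two pixels, zero-length
  paths) are skipped with a logged reason; a constant slice is an error
  for Otsu, while a threshold above the image maximum yields an empty
  mask with a warning.

## Validation studies and their scale

The test suite and `scripts/acceptance.R` recompute, at fixed seeds:

- straight-stroke identity ($r_{ec} = 1$ within $10^{-3}$ at 0°, 45°,
  90°) and the wavy bound ($r_{ec} < 1$);
- truth recovery within ±0.03 and strict monotonicity of mean $r_{ec}$
  over the amplitude grid {0, 5, 10, 15, 20, 25} px at wavelength
  140 px, baseline 400 px, 50 noise-free curves per level with random
  phase and ±10° orientation. This grid maps onto $r_{ec}$ ≈ 0.84–1.0,
  the range relevant for aortic lamellae; far steeper waves push the
  100-unit chord rule into a regime where it is intrinsically sensitive
  to where marks fall and is no longer a stable per-fragment estimator;
- filter fidelity on slices of five lamella strokes plus the three
  designed distractors over 20 seeds;
- brute-force oracle agreement for the longest-path search (all
  connected 3×3 pixel sets plus random ≤ 15-pixel masks), the Otsu scan
  and component labeling;
- null calibration and power of the *entire* pipeline at reduced scale:
  160×160 px slices, 2 px strokes, wavelength 60 px, 3 curves per
  stack, 10 vs 11 stacks, amplitude sd 1.5 px; 200 null replicates
  (rejection rate expected in 5% ± 2.5%) and 100 replicates with true
  group means 0.823 vs 0.889 (power > 80%). The reduced scale keeps one
  replicate around a second while preserving every pipeline stage;
- s-robustness: the cohort verdict at α = 0.05 is identical for
  `s` = 1, 2, 3.

## Known limitations

- Oblique straight strokes retain a residual staircase bias of about
  0.01 in $r_{ec}$ even after `s = 3` smoothing; axis-aligned and 45°
  strokes measure exactly 1.
- Skeleton endpoints are eroded by roughly half the stroke thickness,
  which shifts all chord marks; for fragments only a few steps long
  this contributes most of the ±0.03 recovery tolerance.
- Stacks in which no fragment survives filtering silently drop out of
  the cohort comparison; the manifest records per-rule rejection counts
  so such stacks can be audited.
- The filters assume lamella fragments are thin, sparse and elongated;
  a truly straight lamella has solidity near 1 and would itself be
  rejected by the blob rule — measurement of deliberately straight
  validation strokes therefore bypasses the filters.
- 2D slices only: no 3D skeletonization, no wavelength/curvature
  spectra, no modeling of fragment-within-slice correlation beyond
  aggregating to stack means.
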