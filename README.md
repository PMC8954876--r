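# lamwave

Quantifies the waviness of elastic lamellae in grayscale tomographic
image stacks of the arterial wall, and compares cohorts of specimens.

In a healthy elastic artery the elastin lamellae of the media are wavy in
cross-section; this undulation is *reserve length* — the excess
curvilinear length the lamella can unfold before it bears load. Several
pathologies (for example type-2 diabetes in db/db mice) straighten the
lamellae and consume that reserve. On a 2D micro-CT slice a lamella
fragment appears as a bright curve, and its waviness is captured by the
arc–chord ratio

```
r_ec = euclidean-like length / geodesic-like length
```

where the geodesic-like length is the curvilinear length of the
fragment's centerline and the Euclidean-like length is the sum of chords
between points marked every 100 length units along it. A perfectly
straight fragment has `r_ec = 1`; waviness pushes `r_ec` below 1, so a
*lower* group mean means *more* reserve length.

## What the package does

- **Fragment extraction** — threshold at a multiple (default 2×) of the
  Otsu value, label connected bright regions, and keep only lamella-like
  fragments: area ≥ 100 px, bounding-box occupancy < 0.15 (removes
  patches of superimposed lamellae) and solidity < 0.36 (removes
  blob-like adventitia-style zones).
- **Waviness geometry** — thin each kept fragment to a one-pixel
  skeleton (Guo–Hall), keep the longest skeleton path, subsample every
  `s` pixels (default 3) and re-oversample to subpixel vertices to
  suppress the staircase discretization error, then compute both lengths
  and `r_ec`.
- **Cohort statistics** — aggregate `r_ec` per stack and compare two
  groups with the Wilcoxon–Mann–Whitney rank-sum test (continuity
  corrected), overall or per anatomical region (arch, thoracic,
  abdominal), with Shapiro–Wilk normality diagnostics.
- **Synthetic data** — parametric lamella-like curves (straight,
  sinusoid, arc) with closed-form or quadrature ground-truth lengths,
  rendered into noisy stacks with rule-specific distractor objects, so
  the whole pipeline can be validated against analytic truth.

## Worked example

```r
library(lamwave)
# a compact two-cohort study: wavy control vs smoother diabetic lamellae
d <- demo_cohorts(seed = 7)
meas <- run_measure(d$stacks)          # threshold -> filter -> skeleton -> r_ec
head(meas[, c("stack_id", "slice_index", "region_id", "geodesic_like",
              "euclid_like", "r_ec")], 3)
#>     stack_id slice_index region_id geodesic_like euclid_like      r_ec
#> 1 control_01           1         1      180.9684    149.9447 0.8285681
#> 2 control_01           1         2      175.9716    149.9707 0.8522441
#> 3 control_01           1         3      205.5687    154.1181 0.7497159

run_compare(meas, d$metadata, scopes = "all")$all
#> Cohort comparison of mean r_ec (scope: all)
#>   control: n = 10, mean = 0.817, sd = 0.015
#>   diabetic: n = 9, mean = 0.873, sd = 0.017
#>   rank-sum U = 0.0, p = 0.0002797 (continuity-corrected)
#>   exact permutation p = 2.165e-05
```

Each measurement row is one lamella fragment: its curvilinear
(geodesic-like) length, its end-to-end (Euclidean-like) chord sum, and
their ratio. The comparison is run on per-stack means (one value per
specimen stack, here 10 vs 9 after two diabetic stacks retained no
fragment): the wavier control group sits at mean r_ec ≈ 0.82, the
smoother diabetic group at ≈ 0.87, and the rank-sum test rejects the
null at p < 0.001.

A command-line front end over the same functions is installed under
`inst/cli/lamwave.R` with subcommands `simulate`, `measure`, `compare`
and `all` (multi-page TIFF in, CSV/JSON out).

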