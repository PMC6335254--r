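---
title: "Methods: planimetric pig floor-area measurement and its synthetic test bed"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: planimetric pig floor-area measurement and its synthetic test bed}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pigspace)
```

## The measurement model

A pig stands (or lies) on the floor of a high-contrast measurement box and
is photographed from directly above, the lens `D = 245` cm over the floor.
The camera is treated as an ideal pinhole with the principal axis through
the image centre and no lens distortion. A planar object parallel to the
floor at height `h` is then imaged with linear magnification

$$m(h) = \frac{D}{D - h},$$

so its imaged area scales with `m(h)^2`. The animal's covered floor area
(its *planform* area) is obtained by counting silhouette pixels and
dividing by a pixel density calibrated from a rectangular reference board
of known area (0.420 m², sized like a pig seen from above) photographed
under identical geometry.

Because the pig's outline is not at floor level, the calibration board is
mounted at a representative back height per posture class: 69 cm for
standing animals, 29 cm for lying ones (field means of 68.5 ± 10.7 cm and
29.4 ± 5.9 cm respectively). This is the pipeline's central approximation:
the three-dimensional animal is treated as a planar outline at one height.
Measuring an object at height `h_obj` with a calibration taken at `h_ref`
biases the area by

$$\frac{\hat a}{a} = \left(\frac{D - h_\mathrm{ref}}{D - h_\mathrm{obj}}\right)^2,$$

about 1.9× between floor and 69 cm. The package does not hide this bias:
`measure_area()` refuses (in strict mode) or warns on a height-mismatched
calibration, and the bias law itself is verified as a test property.

## Segmentation

Detection is contrast-based. The defaults are chosen to be parameter-free
and reproducible:

* channel reduction: Rec.601 luminance for RGB input (the UV/fluorescent
  setup is treated simply as "high contrast", with the darker minority
  side of the histogram taken as the animal; `polarity` can be forced);
* optional linear contrast stretch mapping the 1st/99th intensity
  percentiles to the extremes (`enhance_contrast()`; monotone, so it
  moves the threshold but not the ranking of pixels);
* threshold: the inter-class-variance-maximising (Otsu) threshold by
  default, with a `fixed` override for regression testing;
* connected components with 8-connectivity; the largest component is
  kept, plus any component at least `min_component_fraction` (default
  0.5) of its size — this is what rejects small contamination blobs;
* enclosed holes are filled by default: a pig viewed from above is simply
  connected, and specular or dark patches inside the body must not
  subtract area.

Where the original workflow retouched shadows and contamination by hand,
the package uses deterministic exclusion masks: a supplied mask zeroes
pixels before component analysis. An exclusion mask can only remove
pixels, never add them. The reported fraction of images that needed
manual adaptation in the field ("about two thirds") has no computable
analog here and is treated as documentation only.

Areas are kept unrounded internally and rounded only at the reporting
layer with `round_half_up()` (3 decimals for m², 2 where the source
prints 2), because R's default half-to-even rounding disagrees with the
printed tables exactly in the half-way cases.

## The synthetic scene generator

No imagery from the original study is available, so the package generates
its own test scenes with *analytic* ground truth. The generator is a
first-class, tested component, and its defaults encode the study
conditions: lens at 245 cm, 0.420 m² board, reference heights 69/29 cm,
weights 75–133 kg, 13 postures.

A silhouette is a star-shaped polygon: a body ellipse expressed as a
radius function `r(θ)` with a head/snout lobe (longer for head-raised
postures), two leg lobes for lying postures, an area-preserving sideways
shear for the curved `S` postures, and three low-order random harmonics
(±3% amplitude) for outline individuality. Star-shapedness guarantees a
simple polygon; the shear is a unit-Jacobian map, so it preserves that
area. The polygon is finally rescaled so its shoelace area equals

$$a = k_g\, W^{0.66}\,(1 + \varepsilon), \qquad \varepsilon \sim
\mathcal N(0, \sigma_g)\ \text{truncated at } \pm 3\sigma_g,$$

with the per-posture coefficient `k_g = \bar a_g / \bar W_g^{0.66}`
fitted from the packaged tables (`fit_shape_coefficients()`). Truncation
keeps areas positive; with `shape_noise = 0` the planform area is exact,
which is what makes the generator an oracle. Only the planform area is
calibrated to data — the *shape* of the outline is qualitative, because
area is the one quantity the pipeline scores.

Rasterization uses the pixel-centre-inside rule (a pixel is foreground
iff its centre lies inside the projected polygon) via a scanline fill
with half-open spans, so shared edges are counted exactly once. Whether
the original software counted boundary pixels fractionally is unknown;
pixel-centre inclusion is this package's convention, and the rasterized
count converges to `planform_area · s² · m(h)²` (s = floor sampling
density in px/m) with relative error well under 1% at 500 px/m for all
13 postures.

### Cohort weights and noise tuning

`simulate_cohort()` draws per-posture live weights from a normal
distribution at the posture group's recorded mean and SD, truncated to
the group's recorded minimum and maximum (`weight_model = "group"`, the
default). A flat `"uniform"` draw over a weight range is available for
stress tests that want maximal leverage in weight — the exponent-recovery
test uses it over the full 75–133 kg study range. The group model is the
realism default because the observed per-posture distributions are
bell-shaped and much narrower than the overall range (lying postures, for
instance, were never recorded below 86 kg); a flat draw over the full
range would by itself inflate the area spread beyond several postures'
recorded SDs regardless of shape noise.

With area relative spread decomposing (on the log scale, to first order)
into an allometric weight term and independent shape noise,
`tune_shape_noise()` sets

$$\sigma_g = \sqrt{\max\left(\left(\tfrac{s_{a,g}}{\bar a_g}\right)^2 -
\left(0.66\,\tfrac{s_{W,g}}{\bar W_g}\right)^2,\ \sigma_{\min}^2\right)},$$

with a small floor `σ_min = 0.02` so some biological shape variability
remains even where weight explains the whole recorded spread. A cohort of
232 animals per posture generated this way reproduces every posture's
recorded area SD within 30% (most within ~12%) and the means within 2%.

Seeding: one master seed; scene `i` uses seed `(master + i) mod (2^31−1)`,
so cohorts are reproducible and any single scene can be regenerated alone.

### What the generator does and does not emulate

It emulates: the imaging geometry, posture-dependent planform areas with
realistic weight dependence and spread, both reference heights, two-level
contrast, and simple nuisance structure (shadow patches, contamination
specks, exposure changes). It does **not** emulate fur texture,
UV-fluorescence spectra, lens distortion of the physical zoom lens,
partial occlusion, multi-animal scenes, or motion blur. Passing tests
therefore demonstrate that the *measurement chain* is unbiased and
height-consistent on well-posed scenes — not that segmentation would be
robust on arbitrary field imagery.

## Space models

`allometric_area(W, k)` evaluates `k·W^0.66` with the exponent fixed:
the package treats 0.66 as part of the model's identity, and alternative
space-allowance proposals are expressed through `k` alone.
`coefficient_for_posture()` maps `A`–`ES` and `LBC` to 0.019, `LSL` to
0.025, `LL` to 0.047. `legal_min_area(W)` is `W/235`, with an optional
surcharge fraction up to 0.20 (default 0, matching the published
comparison, which is computed without the 20% addition).

`comparison_table()` evaluates both models at each posture group's mean
weight as printed (not hypothetical unrounded values) and reports signed
deviations: `allometric_deviation = allometric − measured` and
`free_space = legal − measured`. Signs preserve the direction that prose
summaries usually carry in words ("calculated below measured", "exceeds
the minimum").

### Known inconsistencies in the source numbers

Recomputing every derived value from the printed group means reproduces
the published comparison numbers exactly — with four documented
exceptions that the package intentionally reports as recomputed rather
than forcing a match:

| quantity | printed | recomputed from the printed means |
|---|---|---|
| free space, posture E | 0.012 m² | 0.127 m² |
| legal shortfall, posture LL | 0.028 m² | 0.029 m² |
| free space, sternal recumbency (printed under code "LSL") | 0.033 m² | 0.032 m² (LBC) / 0.013 m² (LSL) |
| smallest standing allometric deviation | 0.089 m² "(ES)" | 0.088 m² at E (ES itself recomputes to 0.089 m²) |

The first looks like transposed digits; the third compounds a
code–description swap (the sternal-recumbency description belongs to
`LBC` in the posture table; the running text also once writes "LCL" for
`LSL`). `reproduce_comparison()$inconsistencies` carries these four rows.

## Statistics

* `spearman_cor()`: rank correlation on midranks; p-value from the
  t-approximation on `n − 2` df (the conventional default at these group
  sizes), with an exact permutation option for `n ≤ 8`.
* `welch_t_from_summary()`: Welch's unequal-variance t with
  Welch–Satterthwaite df, computed from (n, mean, sd) triples so that
  published summaries can be tested without raw data. Welch is the
  default because the posture groups are strongly unbalanced (30–201
  images); with equal n and sd it coincides with the pooled test.
* `pairwise_group_comparison()`: for a single-factor layout, a GLM with
  Tukey-adjusted least-squares means reduces to one-way fixed effects
  with Tukey–Kramer adjustment; implemented from group summaries on the
  studentized-range distribution, with the Kramer correction for unequal
  n, and a compact letter display assembled by the insert-and-absorb
  algorithm (ties broken in catalog order `A`…`LL`). On weight cohorts
  matched to the study's group sizes this singles out the lightest (E)
  versus heaviest (CS) groups, reproducing the published superscript
  pattern.

## Problem sizes and tolerances

The test suite and reproduction scripts run at desk scale by design:
oracle-equivalence uses 26 noiseless scenes (all 13 postures × 2 weights)
at 500 px/m with a 1% area tolerance and 0.99 IoU; perspective-law checks
use heights {0, 29, 69} cm at 1%; exponent recovery uses 200 animals per
posture with `shape_noise = 0.05` under a fixed seed, asserting the
log–log slope within 0.66 ± 0.03 and per-posture Spearman ρ within
[0.75, 0.98] (bracketing the study's standing range of 0.779–0.923);
population realism uses 232 animals per posture with tuned noise at a 30%
SD tolerance. Printed-value reproduction is exact at printed precision.

## Limitations

* Single-animal scenes only; no occlusion, tracking, or group packing.
* The planar-outline-at-one-height approximation is inherited from the
  measurement design; its bias is quantified but not corrected.
* Lens distortion is unmodelled (and unquantified in the source setup).
* Dynamic and social space — room to move, rise, and keep individual
  distance — are outside the static-space concept measured here; the
  free-space column is an upper bound on what remains for them.
* Per-posture exact p-values for the published correlations cannot be
  reconstructed from summaries and are not targeted.
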