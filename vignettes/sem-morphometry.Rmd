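---
title: "Methods: SEM morphometry of coccoid bacteria"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: SEM morphometry of coccoid bacteria}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The measurement problem

HR-SEM micrographs of coccoid bacteria (e.g. *Streptococcus sanguinis*)
encode two morphological signatures of antimicrobial damage: swelling
(larger projected cell area) and surface roughening (high-frequency
intensity variation on the cell surface). Both are measurable from an
instance segmentation of the micrograph, but only after two nuisance
populations are removed — segmentation artifacts and cells partially hidden
behind others — and only if the intensity signal is separated from smooth
confounds (illumination tilt, the dome-like shading of a curved cell).
`coccimorph` implements that chain as a deterministic, parameter-explicit
pipeline, and ships a synthetic scene generator so that every stage can be
validated against known ground truth.

The package deliberately stops at the segmentation boundary: any external
instance segmenter (a pretrained deep-learning model, manual annotation,
anything that produces an integer label mask on the image grid) plugs in
through `load_pair()`. No segmentation is performed or trained here.

## Pipeline stages and their assumptions

**Preprocessing.** Images are cropped (1-based, inclusive crop boxes — the
natural R convention, used package-wide) to remove scale-bar banners, then
linearly min–max rescaled to [0, 255] per image. Per-image rescaling assumes
the field's dynamic range is dominated by the same tissue/background classes
in every image; its multiplicative effect on texture is documented below. A
single pixel calibration (µm/px) applies to all images of a run.

**Regions.** Each nonzero label becomes one region: area = pixel count,
centroid, and the ordered outer contour of its largest connected component
(multi-component labels are a segmentation pathology; the largest piece is
kept with a warning). Regions touching the image border are flagged and
excluded from group statistics by default, since their areas are truncated.

**Ellipse fit.** The contour is fitted by the numerically stable direct
least-squares conic method constrained to ellipses (Halir & Flusser 1998):
it is non-iterative, always returns an ellipse when one exists, and flags
degenerate (collinear) inputs. Contour points are centers of boundary
pixels, which sit on average half a pixel inside the true object boundary;
`fit_ellipse()` therefore adds 0.5 px to each semi-axis when fitting a
region contour (not when fitting raw point sets). Validation on rendered
ellipses recovers axes well within 2% and orientation within 2°.

**Artifact filter.** Regions with fewer than 5 contour points or area
< 1000 px² are excluded, both inequalities strict. At the calibration
implied by that area cutoff this is 0.183 µm² — far below any intact
coccus — so the rule only removes debris and fragments.

**Background filter.** Two cells are adjacent when the minimum distance
between their fitted ellipse perimeters is < 5 px (0.068 µm), estimated
from 100 points per ellipse at equal parameter spacing
t = 2πk/100. Equal *parameter* (not equal arc-length) spacing is the
conventional, cheap reading; for the moderate eccentricities of ovoid cocci
the worst-case perimeter gap stays below twice the mean arc step, and the
test suite bounds the resulting distance error against dense sampling
(5,000 points/ellipse) at 1%. Candidate pairs are pre-screened with a
uniform-grid spatial index on centroids using the radius
(semi-major)ᵢ + (semi-major)ⱼ + threshold — a guaranteed superset of true
adjacencies — then tested exactly; the tests require exact set equality with
brute-force all-pairs adjacency. A cell is removed iff it has at least one
neighbor and area < 0.7 × the arithmetic mean of its neighbors' areas.
Three deliberate choices:

* *Single pass, original graph.* Removals never trigger re-evaluation, so
  the kept set is independent of processing order.
* *Isolated cells are kept.* "Mean neighbor area" is undefined without
  neighbors, and the filter targets cells obscured by other bacteria.
* *Cell area is the mask pixel count*, not the fitted-ellipse area: a hidden
  cell's *visible* footprint is what makes it locally small, and the
  0.7× rule only makes sense on visible areas. (Fitted-ellipse area is
  available in the cell table for sensitivity analysis.)

**Texture.** The region mask is eroded with a 7×7 all-ones kernel, twice
(equivalently once by 13×13), to exclude edge pixels where shading is
steepest; masks are zero-padded first so erosion arithmetic is exact at the
bounding box. Raw intensities are divided by 255 — a *global* normalization,
chosen over per-region min–max because the latter would destroy cross-cell
comparability of the metric. A full second-order polynomial surface
z = a₀ + a₁x + a₂y + a₃x² + a₄y² + a₅xy is fitted by ordinary least squares
over the eroded pixels (coordinates centered and scaled for conditioning;
residuals are frame-independent), and the **texture value is the rms
residual**. The rms is the natural least-squares companion; the mean
absolute residual is computed alongside as a secondary column. Cells whose
eroded mask has fewer than 50 pixels are flagged invalid — a six-parameter
fit on fewer pixels is noise-dominated. Key properties, all under test:

* any intensity field in the model span (constants, planes, axis-aligned
  quadratics, xy cross-terms — hence also global illumination gradients and
  rotated quadratic domes) leaves the value unchanged;
* uniform noise on [−ε, ε] yields rms → ε/√3;
* the value scales linearly with intensity contrast, so the per-image
  min–max rescale multiplies all texture values of an image by a common
  factor (255/range) — between-group comparisons assume similar dynamic
  range across images.

**Group statistics.** Per-condition n, mean ± sd and quartiles for area
(µm²) and texture; percent change of means versus the control; Cliff's
delta per metric. The delta is computed by sorted-rank counting in
O(n log n), with ties contributing zero, and the tests require exact
equality with the O(n²) pairwise count on hundreds of tied samples.
Category boundaries (0.474 / 0.33 / 0.147 on |δ|) are inclusive. No
parametric tests or multiplicity corrections are applied to morphometrics —
effect sizes are the reported statistic. The statistical unit is the pooled
individual cell; image-level clustering is not modeled.

## The synthetic scene generator

`generate_scene()` is the package's validation instrument. It renders what
the downstream operators assume: ovoid cocci as filled ellipses with

* quadratic dome shading 0.78 − 0.38·r² (r = normalized elliptical radius),
  deliberately inside the texture model's span so zero-roughness cells have
  texture ≈ 0 up to quantization;
* additive i.i.d. Gaussian roughness of amplitude `roughness_amplitude`
  inside each cell — the quantity the texture metric estimates;
* a planar illumination gradient and global Gaussian background noise;
* chains of adjacent cells (2 px gaps) sharing a clonal size (±5% jitter),
  placed with a 7 px margin to everything else so no spurious adjacency can
  arise and no chain member is ever locally small;
* planted occlusions by paint-over z-ordering: the hidden cell is drawn
  first and partially overwritten by a dedicated neighbor, its visible area
  driven into [1000 px², 0.6 × occluder area] by a binary search on the
  occluder offset — so it survives the artifact filter and is removed,
  provably, by the 0.7× rule. Geometries where that window is empty fall
  back to unset occlusion flags.

Default conditions emulate an untreated field at ×20,000: mean area
0.37 µm² with CV 0.29, aspect ratios 1.1–1.7, roughness 0.02, background
noise 0.01, pixel size 0.0136 µm — landing control texture values near
0.022, inside the plausible 0.016–0.033 span for these preparations.

What the generator does **not** emulate, and what that means for the tests:

* No physical SEM image formation (beam/detector effects, charging,
  topographic shadowing); texture recovery results validate the *estimator*,
  not SEM physics.
* Within a group every cell shares one roughness amplitude, so between-group
  texture separation saturates (δ → 1) much faster than in real data, where
  per-cell biological spread dominates. Texture deltas from synthetic runs
  are not comparable to published per-cell deltas.
* Occlusion pairs condition occluder sizes upward (area floors keep the
  visible-area window feasible against the fixed 1000 px² cutoff), so
  occlusion-heavy scenes over-represent large foreground cells and attenuate
  between-group area contrasts. Parameter-recovery studies therefore use
  occlusion-free scenes; occlusion scenes validate the filter itself.
* Cells are placed fully inside the image; border flagging is exercised with
  hand-built masks instead.

## Numerical and engineering choices

* **Calibration constants.** The 5 px = 0.068 µm adjacency statement implies
  0.0136 µm/px; the 1000 px² = 0.183 µm² area statement implies
  0.013528 µm/px. They disagree in the third decimal. The default is
  0.0136; both are exposed by `calibration_constants()` and never averaged.
* **Strict boundaries everywhere**: area < 1000 px² excluded, 1000 kept;
  < 5 contour points excluded; perimeter distance 4.9 px adjacent, 5.0 not;
  area < 0.7 × mean neighbor area removed, exactly 0.7× kept.
* **Determinism.** All randomness flows from one seed; per-image seeds are
  derived arithmetically (kept below 2³¹), and scene generation runs in a
  private RNG stream that restores the caller's state. Identical config +
  seed reproduces byte-identical CSV outputs.
* **Degenerate inputs.** Constant images rescale to zero with a warning;
  collinear contours and rank-deficient surface designs are flagged, never
  fitted; empty masks yield empty region lists; an empty eroded mask is a
  valid "texture invalid" outcome, not an error.
* **Problem sizes.** Validation studies use 200–1000 cells per condition on
  768–1024 px synthetic fields: large enough that a planted +25% area shift
  is several sampling σ wide (cell areas are correlated within clonal
  chains, roughly halving the effective n) and a five-level roughness sweep
  (0–0.08) is strictly ordered, small enough to run routinely.

## Known limitations

* Adjacency is defined on fitted-ellipse perimeters, not mask boundaries;
  for strongly non-elliptical visible crescents the two can differ. The
  occluded-cell guarantee in the generator covers the elliptical case the
  filter was designed for.
* The texture metric inherits a multiplicative factor from per-image
  min–max rescaling; comparing groups across images assumes comparable
  dynamic range.
* Effect sizes carry no confidence intervals, mirroring the reporting style
  the pipeline reproduces; bootstrap intervals would be a natural extension.
* The per-cell table treats cells as independent; six fields per condition
  are pooled without hierarchical modeling.
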