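---
title: "Methods: detecting lymphocyte-infiltrated periportal regions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: detecting lymphocyte-infiltrated periportal regions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Periportal interface hepatitis is graded in part by the fraction of each
portal tract's border that is infiltrated by lymphocytes. Infiltrating
lymphocytes break through the portal border, mix with hepatocytes, and
produce ragged, ambiguous boundaries; portal tracts are also easily
confused with central veins, which look similar but contain no bile ducts.
`periportal` takes per-class segmentation masks of one scene (portal
candidates, bile ducts, bile ductules, hepatocytes, lymphocytes — produced
upstream by whatever segmenter the lab uses) and turns them into
per-portal infiltrated boundary ratios and slide-level statistics suitable
for correlation with severity grades. Segmentation itself, slide tiling
and stain handling are out of scope: masks in, measurements out.

## Pipeline

1. **Portal confirmation.** Candidate components of the portal mask are
   confirmed when at least one bile-duct pixel lies within a 20 µm
   dilation of the component; everything else is treated as a central
   vein and dropped. The tolerance absorbs small misalignment between the
   two segmentation branches, and confirmation is done per whole-scene
   component — ducts occupy only part of a portal, so patch-level checks
   would miss them.
2. **Boundary refinement.** Lymphocyte centroids inside the portal or
   within a 50 µm band of its border are clustered with DBSCAN
   (`eps` = 25 µm ≈ one hepatocyte diameter, `min_pts` = 3 to suppress
   stray sinusoidal lymphocytes). Clusters touching the portal (a member
   inside it or within 7 µm) are pooled and Delaunay-triangulated;
   triangles with any edge longer than 20 µm — the minimum hepatocyte
   size, so a triangle that large cannot be spanned by touching cells —
   are discarded; the rest are filled and OR-ed into the portal mask. The
   refined mask is by construction a superset of the input.
3. **Protrusion proposal.** For every point of the refined contour, the
   50 µm arc centred on it (twice the hepatocyte diameter) is closed with
   a straight chord. The point is *protruding* when the chord cuts deeper
   than 3 µm into the portal. A depth threshold is essential: for a convex
   border the chord always lies slightly inside (a circular portal of
   radius R incurs ≈ 312/R µm over this window, under 3 µm for
   R ≳ 105 µm), so a bare in/out test would flag every point of every
   smooth portal. Maximal quiet runs spanning ≥ 10 µm become
   non-protruding segments; each arc between the midpoints of two adjacent
   quiet runs containing at least one protruding point becomes a
   protruding region, closed by its chord into a polygon.
4. **Features.** Twelve features per protruding region, one per
   non-protruding segment (units chosen to keep values O(1)):
   * `f1` lymphocytes per 1000 µm² of region area;
   * `f2` distinct *enclosing* lymphocytes per 1000 µm² — neighbours (cell
     dilated by 25 µm) of hepatocytes within 25 µm of the border that have
     lymphocytes in more than five of eight 45° sectors;
   * `f3` fraction of the region arc covered by 7 µm footprints of
     lymphocytes projected onto it from within 10 µm;
   * `f4` steepness: max perpendicular distance from the closing chord
     over chord length; `f5` mean Menger curvature on 5 µm-spaced triplets
     (1/µm); `f6` arc length over portal perimeter; `f7` region area over
     portal area — branching or tangentially cut portals protrude too, but
     bigger;
   * `f8`–`f11` contrast, dissimilarity, angular second moment, energy,
     averaged over eight gray-level co-occurrence matrices (32 levels,
     offsets 3 and 5 µm × four angles, symmetric, pairs constrained to the
     region) — fibrosis inside a protrusion shows as high-contrast
     texture;
   * `f12` bile-ductule area fraction — ductular reaction mimics
     infiltration;
   * `f13` projected enclosing lymphocytes per µm of a quiet segment.
5. **Classification.** A 12–16–8–1 multilayer perceptron (ReLU hidden,
   sigmoid output) trained with weighted cross-entropy
   `-w·y·log(ŷ) − (1−y)·log(1−ŷ)`; infiltrated regions are the rare class,
   so the default `w = 3` up-weights them. Threshold 0.5. Quiet segments
   use a rule instead: infiltrated as soon as one enclosing lymphocyte
   projects onto them (`count ≥ 1`; the alternative density-greater-than-
   one reading of `f13` would almost never fire on µm-length segments and
   contradicts the rule's verbal form, so the count reading is
   implemented).
6. **Statistics.** Per portal, infiltrated boundary length over perimeter;
   infiltrated protruding arcs and infiltrated quiet segments both count
   (each kind can be toggled), and the ratio is clipped to [0, 1] because
   protruding arcs absorb half of each flanking quiet run, so the two
   accountings can overlap. Per scene: mode (ratios binned at 0.05, ties
   to the smaller bin — continuous ratios have no mode without binning),
   median, mean `S_avg`, mediant `S_mdt = Σ length / Σ perimeter`, and
   `S_avg25`, the mean over the ⌈n/4⌉ most infiltrated portals. Numerical
   covariates are tested with tie-corrected Spearman correlation, binary
   ones with a two-sided Mann–Whitney U test.

## Key parameters

| parameter | default | unit | role |
|---|---|---|---|
| `microns_per_pixel` | 0.25 (0.5 synthetic) | µm/px | scanner pitch; stamped into all outputs |
| `tolerance_um` | 20 | µm | bile-duct co-occurrence dilation |
| `eps_um`, `min_pts`, `band_um` | 25, 3, 50 | µm | DBSCAN neighbourhood, core size, search band |
| `touch_um` | 7 | µm | cluster–portal contact (one lymphocyte) |
| `max_edge_um` | 20 | µm | Delaunay edge cutoff |
| `window_um`, `depth_min_um` | 50, 3 | µm | chord window and incursion depth |
| `min_nonprotruding_um` | 10 | µm | minimum quiet-run span |
| `enclosure_band_um`, `dilate_um`, `marker_sep_um` | 25, 25, 10 | µm | enclosure test geometry |
| `proj_dist_um`, `footprint_um` | 10, 7 | µm | projection gate and lymphocyte footprint |
| `glcm_levels`, `glcm_dists_um` | 32, (3, 5) | — / µm | texture quantisation and offsets |
| `quantization` | 0.05 | — | mode bin width |
| `w`, hidden, lr, epochs | 3, (16, 8), 1e-3, 500 | — | classifier |

All of them live in `pipeline_config()`, whose hash is stamped into every
result for provenance.

## Numerical choices

* Contours are pixel chains smoothed with a 5 px circular moving average
  before arc lengths are taken; the raw chain staircase otherwise
  overestimates perimeters by several percent, while the smoothed polyline
  tracks analytic circle perimeters within ~1%.
* Chord depth is sampled from the Euclidean distance transform with
  bilinear interpolation, minus 0.5 px: the transform measures to
  background pixel *centres*, half a pixel beyond the true boundary.
  Nearest-pixel lookup without the offset biases depths upward enough to
  flag smooth 120 µm portals.
* Watershed markers for the enclosure test are distance-transform maxima
  merged below 10 µm separation.
* Run midpoints take the floor of the middle arc-length position; quiet
  runs are merged across the contour's index origin, so the partition does
  not depend on where the trace starts.
* A region polygon whose chord crosses its own arc falls back to the
  portal pixels inside the arc's convex hull and is flagged `degenerate`;
  texture features need ≥ 50 px and an intensity image, otherwise they are
  `NA` and the row is dropped from training (at prediction time missing
  values sit at the training mean, z = 0).
* Predictions at exactly 0 or 1 are clamped to `[1e-12, 1−1e-12]` inside
  the loss; training is full-batch Adam from a seeded initialisation, so
  fixed seed and data give bit-identical weights.

## The synthetic generator

Real slides with expert annotations cannot ship with the package, so
validation runs on synthetic scenes with exact ground truth
(`generate_scene()`, `generate_cohort()`). A scene (768×1400 px at
0.5 µm/px) holds one portal — a low-order Fourier-perturbed circle of
~120 µm radius, large enough that its smooth border stays below the chord
depth threshold — and one duct-free central vein. Planted boundary bumps
come in four kinds: *infiltrated* (22–28 µm wide, dense boundary-hugging
lymphocytes plus a hepatocyte enclosed in ≥ 6 of 8 sectors), *branching*
(≥ 2× larger, bare), *ductular* (≥ 30% bile-ductule coverage), and
*fibrotic* (striped high-contrast texture, moderate lymphocyte load).
Grade g plants bumps to hit an infiltrated boundary fraction of
N(0.15 g, 0.05), exactly zero at grade 0. The intensity image renders
per-class mean gray levels plus noise.

The margins between classes are deliberately wide: the point is to verify
the plumbing and the classifier mechanics, not to simulate H&E difficulty.
Passing the cohort tests therefore shows the method recovers planted
structure under clean segmentations; it does not show robustness to
segmentation errors, stain variation, touching nuclei or genuinely
ambiguous morphology, which only real annotated slides could. A
`hard_mode` flag narrows the margins (sparser hugging lymphocytes,
smaller natural bumps) for robustness experiments.

Validation sizes used by the test-suite and the acceptance script: 30-scene
cohorts with uniform grades, two-fold cross-prediction by scene so no
region is scored by a model that saw its own scene; the formula oracles
re-derive every feature on sampled regions with direct loops.

## Known limitations

* The chord depth threshold assumes portals of roughly ≥ 105 µm radius;
  very small portals read as globally protruding. On real material the
  threshold should be tuned against portal calibre.
* Quiet segments flagged by the one-projected-lymphocyte rule contribute
  their whole run length to the infiltrated boundary, which inflates
  ratios in heavily infiltrated slides (they are clipped at 1); the
  per-kind toggles in `portal_ratio()` expose this accounting.
* Texture features are pixel-grid quantities; they are not scale-
  equivariant and should not be compared across scanners with different
  pitches without re-training.
* DBSCAN border points follow the classic first-come assignment; with
  `eps` at one cell diameter this only matters for configurations that
  straddle two clusters at exactly `eps`.
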