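---
title: "Quantifying wall-ingrowth deposition in phloem parenchyma transfer cells"
author: "veinTC"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying wall-ingrowth deposition in phloem parenchyma transfer cells}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(veinTC)
```

## The biological problem

In Arabidopsis leaf minor veins, some phloem parenchyma (PP) cells
transdifferentiate into transfer cells (PP TCs) by depositing localized
*wall ingrowths* — secondary wall material on the inner face of the primary
wall that amplifies the plasma-membrane surface available for sucrose
efflux (via the membrane transporter AtSWEET11) into the apoplasm next to
the sieve element / companion cell (SE/CC) complex. Three quantitative
questions arise from two-channel confocal cross-sections (a general wall
stain such as calcofluor white, plus a membrane marker such as an
AtSWEET11–GFP fusion):

1. **Where** in the vein are PP TCs? (abaxial / middle / adaxial position,
   relative to the bundle-sheath ring)
2. **How much** of each PP/SE and PP/CC interface is covered by ingrowths,
   and which of five canonical deposition classes does a cell belong to?
3. **How much marker** is present, once the strong depth attenuation of
   confocal excitation through tissue is corrected?

veinTC implements the full measurement chain for these questions, plus a
seeded synthetic-vein generator providing exact ground truth, so every
stage is testable without real microscopy data (none is publicly
deposited for this system).

## Data model

* `VeinImage` — a 2-channel pixel grid (`wall`, `marker`) with a pixel
  size in µm. Rows run adaxial (top) to abaxial (bottom); imaging is
  assumed to happen from the abaxial side, so depth increases upward.
* `CellMap` — an integer label map plus a table assigning each label one
  of XY (xylem), SE, CC, PP, BS (bundle sheath), OTHER.
* `Interface` — the shared boundary of two cells as an ordered list of
  pixel faces under 4-connectivity. Its *length* is the face count times
  the pixel size: a Manhattan measure that overstates diagonal boundaries
  by up to √2, chosen because it is exact, unambiguous, and additive
  (`euclideanLength()` provides a chord-based estimator where a physical
  length is needed).

## Position classification

The abaxial axis is inferred as the unit vector from the xylem centroid to
the combined phloem centroid (xylem sits adaxially in a leaf vein).
Bundle-sheath cells are split into abaxial and adaxial halves at the median
of their centroid projections on this axis. A PP cell is *abaxial* iff it
is directly adjacent to, or one cell away from (graph distance ≤ 2), an
abaxial-half BS cell; *adaxial* iff within 2 hops of the adaxial half and
not abaxial; otherwise *middle*. A cell within 2 hops of both halves is
resolved by its own centroid projection. Two points deserve notice:

* the intervening cell may be of any type (the rule does not restrict it);
* in minimal veins (8–15 vascular cells inside a closed BS ring) almost
  every interior cell is within 2 hops of some BS cell, so the *middle*
  class is rarely attainable there — consistent with surveys that group
  middle and adaxial cells together.

## Ingrowth detection

The wall channel is converted to 8 bit (per-frame min–max, half-up
rounding) and binarised with the iterative intermeans (IsoData-type)
threshold — the "default" auto-threshold of common image software. Along
each interface of a PP cell we then measure a *thickness profile*: for
every face, a ray is cast from the face into the cell along the local
boundary normal (estimated from the ordered face midpoints over a ±3-face
window, because the per-face axis-aligned normal points *along* the wall on
staircase-rasterised diagonal boundaries), and the thickness is the deepest
perpendicular penetration of the contiguous wall run (two parallel rays
half a pixel apart, to survive single-pixel rasterisation notches). Rays
count only wall pixels inside the measured cell — deposition is
intracellular, while the walls of foreign cells lie across the boundary —
and a pixel's penetration may exceed its distance to foreign boundaries
only slightly, which stops rays that run along the wall band of an
adjoining interface at cell corners.

The *baseline* (primary-wall thickness) of a cell uses the fact that
deposition occurs only on SE- and CC-facing walls: its BS-, XY- and
PP-facing interfaces are deposition-free references. Because per-face reads
of a uniform wall are multi-modal on pixelated boundaries (diagonal
stretches read about half a pixel thin), the baseline is the upper quartile
of the reference faces plus half a pixel, with the junction-adjacent faces
trimmed; with no reference available it falls back to the 25th percentile
of the cell's own pooled profile.

A face is *covered* iff its thickness exceeds `factor` (default 1.5) times
the baseline; runs shorter than `minRun = 3` faces are despeckled. Two
junction-zone rules make the ends of interfaces behave:

* the outer `endMargin = 10` faces are scored purely by *run continuation*
  under a relaxed `weakFactor = 1.15` threshold (hysteresis): deposition
  genuinely reaching a junction tapers there and would otherwise lose its
  terminal faces, while junction nodes alone — where the walls of three
  cells merge and read thick — can never seed a run;
* faces whose ray cannot reach ingrowth depth for purely geometric reasons
  (it exits the cell at a corner; judged from the label geometry alone,
  never from the wall signal) inherit the state of the nearest measurable
  face.

At the default rendering scale (0.4 µm wall half-width, 0.2 µm pixels) the
1.5× criterion cleanly separates three-fold thickening; two-fold
thickening sits at the detection limit of this raster.

Coverage of an interface is covered length over total length. On an
isolated straight interface the detector recovers a configured arc to
within one face at any coverage; on full synthetic veins, junction zones
couple adjacent interfaces (deposition wraps corners and the hysteresis
may extend a run across a junction margin), so arcs whose ends lie in the
junction zone can be extended by up to roughly the margin. The property
tests assert exactly these two regimes.

## The five-class scheme and scores

With `coverageSE` the covered fraction of the cell's total SE-facing
length and `coverageCC` the per-CC-interface fractions:

| class | rule |
|-------|------|
| I   | no coverage on SE- or CC-facing interfaces |
| II  | 0 < coverageSE < `full` |
| III | coverageSE ≥ `full` and max CC coverage ≤ `smallCC` |
| IV  | coverageSE ≥ `full` and `smallCC` < max CC < `full` |
| V   | coverageSE ≥ `full` and some CC interface ≥ `full` |

`full = 0.95` operationalises "entirely covering" and `smallCC = 0.2` "a
small portion"; both are arguments. A cell with CC coverage but zero SE
coverage is outside the canonical progression (deposition is never
observed to start at CC interfaces) and is returned as class II with a
warning rather than silently binned. The ordinal cell score is the class
index minus one (0–4); the vein score sums the cell scores of all PP
cells, so a typical two-PP-TC vein scores 0–8.

## Fluorescence statistics

**F (internal-standard relative intensity).** Adaxial cells appear darker
purely because excitation and emission traverse more tissue. Since this
attenuation multiplies *both* channels of a region by the same factor, the
wall stain serves as an internal standard:

$$F = \frac{S_2\,C_1}{S_1\,C_2}$$

with \(S\) marker and \(C\) wall-stain sums in the reference region
(subscript 1, a PP TC) and test region (subscript 2). The reference's own
F is 1 by construction. The cancellation is exact when the regions are
depth-translates of each other (the exponential factorises out of every
sum) — the twin-cell phantom (`twinPhantom()`, `fAttenuationStudy()`)
exploits this to verify recovery of the true density ratio to six
significant digits while the raw ratio \(S_2/S_1\) is several-fold off.
Within a single extended cell a continuous depth gradient preserves the
per-pixel channel ratio exactly but per-region sums only approximately;
region-constant dimming restores exactness, and both facts are asserted in
the tests. Measured reads (`measureCellPair()`) use the full path — 8-bit
conversion, default threshold, summed (not mean) intensities over a
membrane-ribbon ROI (boundary ± 2 px; marker is plasma-membrane localised,
so the ribbon is where the signal lives).

**FC (membrane enrichment).** Ingrowths amplify membrane area, hence local
marker abundance per unit wall length:

$$FC = \frac{A_1\,L_2}{A_2\,L_1}$$

with \(A\) marker sums and \(L\) primary-wall lengths of the
ingrowth-bearing (1) and ingrowth-free (2) sides of one cell. When reads
are taken from images (`measureEnrichment()`), the lengths default to the
marker-positive ribbon footprint (above-threshold ROI pixel count scaled
by the nominal ribbon width) — the raster analogue of tracing the visible
membrane. This is deliberate: face-count lengths are Manhattan measures
whose pixels-per-µm density depends on boundary orientation, biasing FC by
up to √2 between differently oriented sides; the footprint estimator is
orientation-free. Chord (`"euclidean"`) and face-count (`"faces"`) modes
are available. ROI end bulges are trimmed (2 terminal faces per side).

## The synthetic generator

`generateVein()` builds a vein as a Voronoi tessellation of structured,
seed-jittered generator points: a BS ring (radius 0.36·S), xylem placed
adaxially, abaxial PP cells just inside the abaxial bundle sheath (0.28·S)
with one SE placed radially inward of each (0.20·S), companion cells on an
interleaved angular grid flanking the PP/SE pairs (0.245·S), remaining SEs
deeper in the phloem. Defaults follow the typical mature minor vein: 3
XY, 4 SE, 5 CC, 2 abaxial PP inside an 8-cell BS ring; 512×512 px at
0.2 µm/px. All randomness flows from the single integer seed; identical
configurations are bit-identical.

Walls are a band of stain (amplitude 180 au) of half-width 0.4 µm around
every boundary. A configured ingrowth arc (a centred contiguous run of
`round(coverage × nFaces)` faces) thickens the wall k-fold on the PP side:
a pixel is deposit iff it lies in the PP cell within k·h of the arc, not
nearer to the uncovered remainder of the same interface (pixel-crisp
partial arcs), and within the junction taper cap (distance to foreign
boundaries plus 1.5 wall half-widths) — deposition wraps cell corners
slightly, which is what produces the "small covered CC section" typical of
class III cells whose SE interface is fully covered. The membrane marker
is drawn on a 1-px-dilated ribbon along PP boundaries at
`markerDensity × pixelSize` au per pixel, multiplied by k where the
nearest boundary pixel belongs to a covered arc (membrane amplification is
encoded in intensity, keeping the summed signal proportional to
k × density × length). Depth attenuation multiplies both channels by
exp(−coef·depth) with depth measured from the abaxial (bottom) edge.
Noise is additive Gaussian (σ = 6 au) clipped at zero; Poisson noise is a
documented omission. No point-spread-function or 3D optics are simulated.

Class presets (`classPreset("I")` … `"V"`) configure the canonical
deposition of each class (0, half the SE interface, the entire SE
interface, plus 0, half, or all of a CC interface, at k = 3).

## Study conditions and problem sizes

The simulation studies are run at these sizes (chosen once as the
package's standard conditions and used identically by the test suite and
`scripts/acceptance.R`):

* class recovery: 20 veins per class preset at 512 px (200 scored PP
  cells), noise-free and at the default noise level;
* FC recovery: 50 veins per k ∈ {1, 2, 3, 5} at 512 px (ingrowths up to
  k·h = 10 px need the room);
* measured F: 50 veins at 256 px (no ingrowths, so smaller images
  suffice);
* cohort position survey: 100 cohorts × 156 veins, geometry-only at 96 px
  (position classification needs no rendered channels), abaxial placement
  probability 200/339, success judged by the exact binomial
  (Clopper–Pearson) 95 % interval covering that probability;
* t-test calibration: 10,000 two-sample nulls of size 10.

## What passing tests do and do not show

The generator emulates polygonal cell geometry, polarized deposition,
membrane-localised marker, shared-channel attenuation and additive noise.
It does not emulate out-of-focus light, chromatic shifts, segmentation
errors (the label map is ground truth), within-wall texture
("bristle-like" substructure), or 3D sectioning artefacts. Passing
recovery tests therefore validates the measurement chain's logic and its
raster robustness, not performance on raw micrographs; on real data the
label map must come from an external segmentation, and the detection
thresholds (`factor`, `smallCC`, `full`) should be inspected against a few
visually scored cells.

## Known limitations

* Two-fold wall thickening is at the detection limit of the default
  raster; three-fold and stronger deposition is detected reliably.
* Per-interface coverage is face-accurate only away from junction zones;
  arcs ending within ~10 faces of a junction may be extended to it.
* "Middle" position requires veins large enough to hold cells ≥ 3 hops
  from both BS halves; minimal 8–15-cell veins have essentially none.
* The Manhattan interface length overstates diagonal boundaries by up to
  √2; use `euclideanLength()` where physical lengths matter.

## A worked example

```{r example, eval = FALSE}
cfg <- classPreset("IV", seed = 7L)
vt <- generateVein(cfg)
meas <- measureVein(vt$image, vt$truth@cellMap)
meas$cells
summarizeVein(vt$truth@cellMap, meas$cells, meas$interfaces)
```
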