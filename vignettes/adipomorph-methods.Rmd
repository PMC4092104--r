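---
title: "Adipocyte morphometry by seeded gradient-vector-flow contours"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Adipocyte morphometry by seeded gradient-vector-flow contours}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", fig.width = 6)
library(adipomorph)
```

## The measurement problem

Sections of adipose tissue prepared with an elastic (Accustain-type)
histochemical stain show three visually distinct compartments: adipocyte
lumina remain unstained and near-white, the collagen septa between cells
stain pink, and elastin fibers inside the septa stain black. Because the
lipid-filled lumen of each adipocyte is bounded on all sides by stained
extracellular matrix (ECM), a single stain supports three quantitative
readouts at once:

* the **cross-sectional area (CSA)** of every adipocyte profile, in um^2;
* the **area fractions** of collagen and elastin, as percent of tissue;
* **densities** of counted objects (mast cells, macrophages, vessels)
  normalized to events per mm^2 of tissue.

Manual sizing of a few hundred cells per section is slow and prone to
field-selection bias; an automated pipeline measures every cell on the
section. `adipomorph` implements such a pipeline in two algorithmic steps —
automated seeding of each cell center, then a gradient-vector-flow (GVF)
deformable contour per seed — wrapped with calibration, stain
classification, morphometry statistics, and a synthetic slide generator
that provides exact ground truth for testing.

## Pixel classification

Classification works in luminance/saturation space rather than raw RGB:
"black" (elastin) and "unstained" (lumen) are brightness concepts, so the
rules survive hue drift of the pink. We use HSL lightness
`L = (max+min)/2` on the 0-255 scale and the chroma ratio
`S = (max-min)/max`. The HSL saturation denominator vanishes for
near-white pixels and would amplify sensor noise exactly where lumina are;
the chroma ratio stays small there, which is why it is used instead.

Within tissue, pixels with `L <= 80` are elastin; pixels with `S <= 0.15`
and `L >= 200` are lumen; everything else is collagen. The three defaults
are configuration values, not constants; they were chosen for typical
elastic-stain renderings (lumen ~246, collagen pink ~(231,146,180), elastin
~(38,32,36) with noise SD of a few counts) and are expected to need
adjustment per scanner. ECM fractions are simple pixel ratios over the
tissue mask, so collagen + elastin + lumen is exactly 100%.

The tissue mask itself thresholds near-saturated white (all channels
> 240 by default), removes connected "tissue" components smaller than 25 px
(sensor-noise speckle on bare glass), and then fills enclosed holes so that
lumina count as tissue. Its area in mm^2 is the denominator of every
density and fraction.

## Seeding

The seed detector computes the Euclidean distance transform of the lumen
class and takes its regional maxima, greedily suppressed to a minimum
separation of 25 um — the diameter of a circular 500 um^2 cell, the
smallest the method is designed to measure, so no real cell is seeded
twice. Because septa bound every adipocyte, a connected unstained region is
one cell; by default at most one seed survives per connected lumen
component, and that seed is relocated to the component's geometric centroid
(the distance peak is the incenter, which in elongated cells can sit far
from the center). Ties between equal-height maxima break lexicographically
by (row, col), making detection fully deterministic.

An optional second stage mirrors a trainable detector: a random forest on
five center-local color features of a patch around each candidate
(luminance and saturation of the central 3x3, ring luminance, center-ring
contrast, dark-pixel fraction), trained on labeled patches, drops
candidates scoring below 0.5. Features are deliberately center-local so
that cells clipped by the image frame still score as cells. The forest uses
a fixed training seed, keeping repeated fits identical.

## Gradient vector flow and the contour

The external energy comes from color gradients: each channel is smoothed
with a Gaussian (sigma 1.5 px), differentiated with central differences
(reflected boundaries), and the edge map is the per-pixel maximum of the
channel gradient magnitudes, rescaled to [0, 1] and zeroed outside tissue.

GVF extends the edge-map gradient into flat regions by the explicit
diffusion

    u <- u + dt * ( mu * lap(u) - (fx^2 + fy^2) * (u - fx) )

initialized at `(u, v) = (fx, fy)`, with `mu = 0.2` and `dt` at half the
explicit stability limit `1/(4 mu)`. The number of iterations sets the
capture range — vectors propagate roughly `sqrt(2 mu dt n)` pixels — and
the default is 2000, reaching ~30 px, comparable to the inradius of the
largest cells at 1 um/px. Far fewer iterations leave the force at an
interior seed numerically zero and the contour stalls; this is why the
default is high, and why the inner loop is compiled (C++). With `mu = 0`
the data term pins the field to the raw gradient exactly, a limit used by
the test suite.

Each seed initializes a circular contour of radius
`max(3, 0.7 x distance-transform value)` — the distance value at the seed
is the lumen inradius, already computed during seeding, so large cells
start within the capture range of their own boundary. Evolution is the
classic implicit-internal / explicit-external scheme with elasticity 0.1,
rigidity 0.05, step 1.0 and force weight 1.0, vertices resampled to uniform
arc length every iteration, and runs in two phases:

1. **Approach** on the *normalized* GVF field (unit vectors, lightly
   smoothed so the direction flip at an edge crest becomes a linear zero
   crossing ~2 px wide). Unit speed frees the contour from weak-force
   interiors; the phase ends when the enclosed (shoelace) area changes by
   less than 0.5% per ten iterations.
2. **Refinement** on the raw GVF field, whose force crosses zero linearly
   at the crest; the contour converges when mean vertex displacement falls
   below 0.05 px. Contours that hit the 500-iteration cap are kept but
   flagged unconverged and excluded from morphometry by default.

The force-weight choice of 1.0 with step 1.0 keeps the crest fixed point of
the approach phase stable (`|1 - gamma*kappa*s| < 1` for a transition of
slope `s ~ 1/px`); a weight of 2 sits on the stability boundary and
oscillates.

## Overlap resolution and measurement

Contours are rasterized by the even-odd rule; a pixel claimed by several
contours goes to the nearest seed (ties to the lower cell id), each
region is reduced to the connected component holding its seed, and cells
that lose their seed are dropped with a message. Finally, by default each
resolved region is intersected with the lumen class (`trim_to_lumen`):
the contour assigns territory, but the cross-sectional area of an
adipocyte is its unstained profile, so stained ECM pixels swept up by a
locally bulging contour are returned to the ECM. On synthetic slides this
trimming removes a systematic half-septum overestimate (contours settle on
the edge ridge, which sits at the lumen/collagen transition, and
occasional vertices latch onto elastin fibers one or two pixels deeper).

Areas are `pixel count x pixel_size^2`. The default inclusion filter is
[500, 10000] um^2: the floor is the smallest adipocyte profile the method
is built to measure, the ceiling is padded above the largest commonly
observed profile (~8700 um^2) so genuine large cells are not truncated.
Histograms use half-open 500 um^2 bins over [500, 10000) and report
relative frequencies that sum to one.

Pre/post comparisons use the per-slide (per-subject) mean as the unit of
analysis — not pooled cells — because subjects, not cells, are the
independent replicates; `paired_t()` wraps the classical paired t-test
(two-sided), with one documented convention: identical pre and post vectors
return p = 1, and a non-zero constant difference (zero variance) is an
error rather than an infinite t. Manual-vs-automated agreement is
summarized by Pearson r on paired per-slide means.

## The synthetic slide generator

`generate_slide()` builds a slide with exact ground truth: per-cell area
targets drawn uniformly from [500, 8700] um^2; centers placed by dart
throwing with a radius-dependent separation (largest first); a power
diagram (additively weighted Voronoi) tessellates the canvas so realized
sizes track targets while regions stay convex and seed-owning; regions
shrink by half the 6 um septum width to form collagen walls; elastin is
planted as random curvilinear strokes inside septa until the target
fraction of tissue (3% by default) is reached; rendering applies a +/-2%
linear illumination gradient and additive Gaussian channel noise
(SD 6 counts), clipped to 8 bits. Septa close along the canvas frame, as
on a real capture taken inside the tissue. The default canvas is
1024 x 1024 px at 1 um/px with 200 cells. A single RNG stream per slide
makes regeneration bit-identical.

What the generator deliberately does *not* model: tissue folds and tears,
stain batch variation, uneven section thickness, chromatic aberration, and
touching lumina through broken septa. Passing tests on synthetic slides
therefore demonstrate the correctness of the algorithms under the stated
image model, not performance on any particular scanner's output; the
color thresholds especially should be re-tuned on real material.

Realized (rendered) cell areas — not the drawn targets — are the ground
truth recorded in `truth_cells`, because tessellation reshapes targets.
Cells touching the frame are flagged `edge` but kept: they are real,
clipped profiles, exactly as on scanned sections.

`simulate_subject_means()` is the generator's statistical companion: it
draws per-subject slide means directly from the same uniform area model
(mean of `n_cells` draws), with the post-treatment range scaled by a
planted percent effect. It exists so that the power of the 9-subject
paired design can be studied over many replicate cohorts without
rendering thousands of images; one cohort is still measured end-to-end
through the full image pipeline in the test suite and acceptance script.

## Matching and evaluation conventions

A detected seed matches the truth cell whose lumen region contains it;
when several seeds land in one cell the nearest-to-centroid wins and the
rest count as spurious. Segmented cells pair with the truth cell holding
their seed, and accuracy is reported as signed relative area error and
intersection-over-union. Problem sizes in the test suite (384-512 px
unit-test slides, the 1024 px default slide, a 12-slide panel, one
9-subject cohort at 320 px) were chosen as the smallest sizes at which
every geometric regime of the method — small and large cells, edge cells,
junctions — is still represented.

## Known limitations

* Touching lumina (broken septa) merge into one seed and one contour by
  design; real sections with extensive septum loss will undercount cells.
* The classifier stage is a stand-in for a trainable detector, not a
  reconstruction of any particular published learner.
* Calibration is taken on trust from the user; no attempt is made to read
  scanner metadata.
* The pipeline is single-threaded; a 1024 x 1024 slide takes tens of
  seconds, dominated by GVF diffusion.
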