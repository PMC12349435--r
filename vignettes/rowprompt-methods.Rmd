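---
title: "Prompt engineering for individual tree segmentation: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Prompt engineering for individual tree segmentation: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rowprompt)
```

## The problem and the model

Phenotyping orchards planted for variety testing must score each tree
separately, but in dense rows the canopies of neighbouring trees
interpenetrate, and supervised instance segmentation needs annotation
volumes that such programmes rarely have. The pipeline implemented here
sidesteps most of the annotation: the only learned component it assumes is
a trunk detector producing a semantic trunk mask (which is *not* bundled —
the package starts from the mask), and everything that turns that mask
into per-tree instance masks is deterministic geometry plus a promptable
segmentation backend.

The geometric core is the five-point *diamond prompt*. For each trunk
instance $A_i$:

* the trunk's axis is the least-squares regression line of pixel column on
  pixel row, $x = a\,y + b$. Regressing $x$ on $y$ rather than $y$ on $x$
  is essential: trunks are near-vertical, so the transposed regression
  would be ill-conditioned. The angle from vertical is $\arctan a$,
  constrained to $(-90^\circ, 90^\circ)$;
* all axes in an image are re-anchored at their trunk centroids with the
  *row-wide mean angle* $\alpha$. Trees in a trellis row lean together
  (wind, training system, camera roll), so the mean is a better estimate
  of each trunk's true orientation than its own noisy fit, particularly
  for trunks partially hidden by grass or foliage. A plain arithmetic mean
  is used — angles are small and sign-consistent in row imagery, so
  circular statistics would be overkill. The constraint can be disabled
  (`shared_angle = FALSE`) for free per-trunk angles;
* **B**, the trunk bottom, is the point of the constrained axis at the
  trunk's maximal pixel row — the mask's own extent is the only available
  definition of "bottom";
* **T**, the summit, comes in two modes. *Supervised*: displace B by a
  user-supplied height $h$ (pixels) along the axis, $\Delta y = -h\cos\alpha$,
  $\Delta x = -h\sin\alpha$; a summit above the frame is clamped to $y = 0$
  with a warning. *Unsupervised*: walk the axis upward from B through a
  foreground-vegetation mask and take the top of the continuous foreground
  run. The scan starts at the *first* foreground pixel at or above B
  rather than at B itself, because the trunk base is bark, not vegetation —
  a literal start-at-B rule would fail on every real image. Breaks up to
  `gap_tolerance_px` (default 10 px, roughly the size of a within-crown
  sky gap at typical row-image resolution) are bridged;
* **C** is the midpoint of B and T, and the lateral points sit at C's
  height, 20% of the way toward each neighbouring border:
  $R = (x_c + 0.2\,(x_{br} - x_c),\, y_c)$ and
  $L = (x_c - 0.2\,(x_c - x_{bl}),\, y_c)$. The 20% factor keeps R
  strictly left of the right border and L strictly right of the left one
  whenever the spans are non-degenerate, so lateral points never cross
  into a neighbour's half of the corridor.

The borders $x_{bl}, x_{br}$ are the nearest trunk centroids left and
right. For boundary trees the missing side is genuinely ambiguous — "the
image edge" and "halfway to the image edge" are both defensible — so both
are implemented behind `edge_policy` (`"edge"`, the default, uses
$x = 0$ / width − 1; `"half"` the midpoint). A second open reading — taking
the neighbour's axis position at C's height instead of its centroid —
would differ only by the axis tilt over half a tree height (a few pixels)
and is not implemented.

Prompt coordinates are kept as floats throughout; rounding to the pixel
grid (half away from zero, `px_round()`) happens only where a consumer
needs an integer pixel, so chained geometry does not accumulate rounding.

## Trunk instancing

The semantic mask is split into instances by DBSCAN over foreground pixel
coordinates with the Euclidean metric. The raster formulation is exact:
neighbour counts are disc-offset sums of the mask, clusters are connected
components of the within-`eps` graph over core pixels, and border pixels
attach to their nearest core neighbour (ties resolved by a fixed offset
scan order). Defaults `eps_px = 5`, `min_pts = 20`, `min_area_px = 200`
assume trunks tens to hundreds of pixels apart, where the result is
insensitive to the exact values; all are exposed on the CLI. An optional
`subsample_stride` trades exactness for speed on very large rasters, with
labels propagated back by nearest-labelled-pixel growth. Surviving
clusters are relabelled 1..k by centroid x so ids read left to right — the
ordering the neighbour search expects.

## Segmentation backends

The backend contract is intentionally minimal — (image, five foreground
points) in, one binary mask out — because that is the interface of
promptable foundation segmenters. All five points carry prompt label 1
(foreground); the diamond defines no background points. Two offline
backends ship with the package:

* the **truth oracle** returns the ground-truth instance holding the
  majority of the points (ties to the instance containing C; empty when
  no point lands on a tree). It is a test instrument: it bounds what a
  perfect segmenter could do with the given prompts, and makes the
  end-to-end identity test possible;
* **seeded region growing** flood-fills from each point over pixels within
  a colour tolerance of the running region mean, optionally confined to
  the corridor between the tree's neighbour axes, unioned over the five
  seeds. It is a deliberately simple reference that exercises the pipeline
  offline; results obtained with it say nothing about any pretrained
  model. A pixel rejected once is not re-tested when the region mean later
  drifts; this keeps the fill deterministic and linear in the grown area.

Per-tree masks may overlap; `assemble_instances()` gives contested pixels
to the tree whose prompt centre C is nearest, ties to the lower id, which
makes assembly deterministic and invariant to tree ordering. No mask
post-processing is applied by default; `keep_largest_component` exists for
callers who want it, without presuming it.

## Evaluation

Dice, signed mean error (positive = over-segmentation), and pixel
precision/recall are defined the standard way; degenerate denominators
(both masks empty; nothing predicted; nothing to find) return 1 with an
explicit flag so aggregates can exclude them. Instance matching uses the
low Dice > 0.1 criterion — the question is "was this tree found", not "was
it delineated perfectly". Among candidate pairs above the threshold the
match is the *exact* optimum: maximum number of matched pairs, then
maximum total Dice, computed per connected component of the candidate
graph by subset dynamic programming. An earlier greedy-by-Dice variant was
dropped after a counterexample: a prediction straddling two adjacent
crowns can make greedy pick the locally best pair and strand a
neighbouring prediction, which changes the per-tree Dice assignment; the
exact optimum is deterministic and was verified against exhaustive
enumeration. Components beyond 24 truths abort rather than silently
degrade — far beyond any realistic row image.

Average precision ranks detections by score (ties keep input order,
documented), marks each as TP against a still-unmatched truth at
Dice > 0.1, and integrates the right-monotonized precision envelope over
all recall points. All-point interpolation was chosen over 11-point
because it is exact for the small detection counts of row images; both
describe the same curve. Detectors without scores pass uniform scores and
get the degenerate single-point curve. Per-image Dice in reports is the
mean over matched trees with unmatched truths contributing 0 — stated in
the report header, since silently dropping misses would flatter the
numbers. Whether precision/recall should be pixel- or instance-level is
left open in the field's reporting conventions, so both are computed and
labelled distinctly.

The paired Student *t* test compares per-image scores of two methods on
the same images: $t = \bar d / (s_d / \sqrt n)$ with the sample standard
deviation, two-sided $p$ from the $t$ distribution with $n - 1$ degrees of
freedom. Zero-variance differences are flagged rather than propagating
NaN: identical methods give $t = 0, p = 1$; a constant nonzero difference
gives infinite $t$, $p = 0$.

## The synthetic scene generator

`generate_scene()` emulates what makes row imagery hard while staying
fully controllable: 1–10 near-vertical trunks at roughly regular spacing
(jittered), per-tree tilts up to ±10°, canopies built as unions of
half-ellipses strung along the trunk axis with independent left/right
half-widths (asymmetry), neighbour overlap, a green-dominant vegetation
colour against a desaturated gradient-plus-noise background, and a brown
trunk ribbon. Ground truth is exact by construction: where two canopies
overlap, the pixel belongs to the tree whose trunk axis is horizontally
nearer (ties to the lower id) — an arbitrary but deterministic convention
that exact tests need. Each tree instance contains its trunk, matching the
annotation convention of whole-tree labelling.

Choices worth recording:

* `overlap_fraction` $f$ sets the canopy half-width to
  $\text{spacing} \times (0.7 + f)/2$: $f = 0$ leaves a 0.3-spacing gap
  (isolated crowns), larger $f$ intertwines neighbours. One parameter thus
  moves the generator between the easy and the hard regime;
* the recorded per-tree height and summit are *measured from the rendered
  mask* (top of the axis run through the tree's own pixels), not echoed
  from the sampled parameters, so truth records stay consistent with the
  raster even after clipping and rounding;
* batches sample a per-scene *row lean* (±8°) plus a small per-tree jitter
  (±2°), mirroring trellis rows where the row leans together far more than
  trees lean against each other. Tilt variation across scenes spans the
  full ±10° range;
* identical (config, seed) pairs are bit-identical, and batch scenes get
  seeds derived from the master seed, so any scene can be regenerated
  alone.

What the generator does **not** emulate: photorealistic texture, harvest
state, support poles and trellis wire, multi-row backgrounds, specular
lighting. Passing tests on synthetic scenes therefore demonstrate the
correctness of the geometry, clustering, contracts and metrics — not field
performance of any particular segmentation backend on real orchards. On
real data the vegetation mask should come from a dedicated
foreground-segmentation tool via the `foreground` argument; the built-in
ExG + Otsu estimate (threshold floored at zero so pixels must actually be
green-dominant, with a sign fallback for constant images) exists so the
unsupervised path runs offline.

## Problem sizes and numerical choices

The batch-level properties in the test suite and the acceptance script use
100 scenes of 480×360 px with 2–4 trees (geometry, clustering recovery,
summit consistency), 30 scenes for the end-to-end oracle identity, and 8
well-separated scenes for the region-growing reference; metric
implementations are checked against brute-force oracles on 50 random
64×64 mask pairs, 200 random small instance cases, and 50 random paired
samples. These sizes give stable rates (hundreds of trees per batch) while
keeping a full run in minutes on one core.

Tolerances: axis recovery is asserted within ±1° per trunk and ±0.5° for
the row mean; C must be the midpoint of B and T within 0.5 px; the
supervised and unsupervised summits must agree within 5% of tree height
for at least 90% of trees; metric implementations match their oracles
exactly (pixel counting) or to 1e−12 (assignment, AP) and 1e−9 (t CDF
against numerical integration).

## Known limitations

* The exact-assignment matcher is exponential in the size of a connected
  candidate component; fine for rows (components of 1–3), unsuitable for
  dense panoptic scenes.
* The region-growing backend leaks through colour-connected canopies when
  neighbours touch and the corridor is disabled; it is a pipeline
  exerciser, not a segmentation method.
* The shared-angle constraint assumes a common row lean; rows with wildly
  divergent trunk tilts (> ~5° spread) should use `shared_angle = FALSE`,
  at the cost of noisier axes for occluded trunks.
* Prompt quality degrades for strongly asymmetric crowns — the diamond is
  symmetric about the axis by construction; a depth-aware lateral-point
  refinement would need information this package does not take as input.
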