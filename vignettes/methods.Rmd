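---
title: "Methods: marker-guided intensity quantification with background subtraction"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: marker-guided intensity quantification with background subtraction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fluorquant)
```

## The measurement model

`fluorquant` quantifies how much of a signal of interest accumulates in
nuclei, using a two-channel immunofluorescence design. The *marker*
channel (a nuclear stain such as Elav that is independent of the
experimental manipulation) defines *where* to measure; the *query* channel
defines *what* is measured. For an image with ROIs $R_1,\dots,R_k$ found
on the marker channel and a selection region $S$ (the tissue outline the
analyst draws), the package reports for each ROI

$$\widehat{I}_j \;=\; \underbrace{\frac{1}{|R_j|}\sum_{p \in R_j} q(p)}_{\text{mean\_raw}}
\;-\; \underbrace{\frac{1}{|B|}\sum_{p \in B} q(p)}_{\text{mean\_bg}},
\qquad B = S \setminus \bigcup_j R_j,$$

where $q(p)$ is the query intensity at pixel $p$. The background mask $B$
is the exact complement of the ROIs within the selection: measurement and
background masks are disjoint and together tile $S$, a property the test
suite asserts on randomised configurations.

The model's assumptions are deliberately minimal:

* background fluorescence is spatially uniform *within the selection* (one
  global background per image, not per-ROI annuli);
* the marker channel is informative enough to segment nuclei by a single
  intensity window;
* imaging settings are constant across the images being compared, so
  differences in corrected means reflect biology.

The central consequence of subtracting a common background is
shift-invariance: adding any constant to the query channel changes no
corrected mean. This is the pipeline's defining property and is tested to
numerical precision (deviation below $10^{-9}$ for shifts of 5, 25 and 50
grey levels).

## Segmentation

Segmentation runs entirely on the marker channel, in five stages.

**Selection.** The analysed region is a simple polygon (or the whole
image). Pixel membership uses the even-odd rule evaluated at pixel
centres, with boundary pixels counted *inside* — an arbitrary but
deterministic convention that makes rasterisation reproducible and
testable against a per-pixel oracle. Vertices outside the image are
clipped with a warning; zero-area polygons are refused. Coordinates are
0-based with the origin at the top-left pixel centre, the usual image
convention. ImageJ `.roi` polygon files are read directly so selections
drawn interactively elsewhere can be reused.

**Thresholding.** The 256-bin histogram of the in-selection pixels (only —
cleared pixels never influence the level) feeds one of two classical
algorithms: the iterative intermeans ("isodata") method, which is the
variant behind ImageJ's default auto threshold and is the package default
for that reason, or Otsu's maximiser of between-class variance. Otsu ties
are broken towards the smallest level. Both return a manual-equivalent
window $[T, 255]$ with the method recorded, so a run is reproducible from
its log regardless of how the level was chosen. Bounds are inclusive at
both ends. A constant in-selection histogram has no meaningful automatic
level and raises an error directing the user to manual mode.

**Binary operations.** Two optional clean-up steps run between
thresholding and particle analysis, in the fixed order *dilate →
watershed*: dilation (3×3 structuring element, $n$ iterations) first
recovers under-segmented nuclei, then the distance-transform watershed
splits touching blobs. Running watershed after dilation means blobs merged
*by* the dilation can still be separated; the reverse order would undo the
split. The watershed erases a one-pixel ridge between adjacent catchment
basins — specifically the pixels of the higher-numbered basin that touch a
lower-numbered one (8-neighbourhood), which guarantees the remaining
basins are not 8-connected to each other while removing as little area as
possible. Foreground never grows, and a blob with a single distance
maximum passes through unchanged.

**Particle analysis.** Components are 8-connected (the ImageJ
analyze-particles convention). Area is the pixel count. The perimeter is a
boundary-walk estimate: a Moore-neighbour trace of the outer boundary
yields a chain code whose straight moves are weighted 0.948 and diagonal
moves 1.340 — the corner-corrected weights ImageJ applies to traced
outlines. Uncorrected weights (1 and $\sqrt 2$) overestimate smooth
perimeters by ~5% and would cap a disk's circularity near 0.90; with the
correction, digitised disks approach circularity 1 from below ~0.97 as the
radius grows, matching the intuition that "circularity near 1 means
round". Values above 1 — possible for particles a few pixels across, where
any perimeter estimator breaks down — are clamped to 1. Particles touching
the image edge are kept by default (`exclude_edge_particles` turns this
off), and surviving particles are numbered in raster-scan order of their
first pixel so labels are stable across runs.

**Manual edits.** The interactive "inspect and correct ROIs" step of
GUI-based workflows becomes an explicit include/exclude label list,
applied after filtering. A label listed on both sides is a configuration
error and is refused rather than resolved by precedence.

## Default parameters

| Parameter | Default | Units | Rationale |
|---|---|---|---|
| `min_area` / `max_area` | 30 / ∞ | px² | reject debris below ~6 px diameter; no upper bound by default |
| `min_circ` / `max_circ` | 0.3 / 1.0 | — | nuclei are roundish; permissive lower bound |
| threshold | auto (isodata) | grey levels | ImageJ-default-compatible |
| `slice_policy` | max projection | — | standard reduction for nuclei in thin tissue |
| background statistic | mean | grey levels | matches ImageJ's Measure; median selectable for skewed backgrounds |
| `dilate_iterations` | 1 | — | gentle recovery when enabled |

These are implementation defaults for motor-neuron-sized nuclei at typical
confocal sampling; they are deliberately documented here rather than
hard-coded folklore, and every run log records the effective values.

Two interface choices depart from pure convention: slice indices are
1-based (the R idiom — documented rather than silently mixed with the
0-based pixel coordinates), and 16-bit TIFFs are accepted by linear
rescale to 8-bit (division by 257 and rounding, reported via a message)
because the downstream contract — histograms, thresholds, the CSV schema —
is 8-bit throughout.

## Group statistics

Image-level summaries are the *unweighted* mean of corrected ROI means:
each nucleus is one biological observation, and area-weighting would let a
few large nuclei dominate. Fold-change is the ratio of group means; its
dispersion is reported as the SD of per-image folds (each experimental
image divided by the control mean), a construction stated in the output
rather than left ambiguous. SDs use the $n-1$ denominator everywhere.
Agreement between paired readings (two users, two methods) is ordinary
least squares of one reading on the other with $R^2$, slope and intercept;
the coefficient of variation is $s/\bar x$. Hypothesis testing is
deliberately out of scope — the CSV outputs feed any statistics tool.

## The synthetic-image generator

`synth_spec()`/`generate_image()` emulate the one feature of the real data
that the pipeline's correctness depends on: disk-shaped nuclei of known
marker and query intensity over a uniform background, with optional
additive Gaussian noise applied before 8-bit quantisation. Marker goes to
the red samples, query to the green, mirroring the RGB input contract.
Nuclei are hard disks with a minimum centre spacing (default: separated by
at least 3 px) so that particle counts have unambiguous ground truth; an
`allow_touching` mode produces merged blobs specifically to exercise the
watershed. Defaults place 10 nuclei of radius 5–8 px in a 128×128 field
with marker 200 over background 20 — crisp staining well inside the
dynamic range, the regime the measurement model assumes.

For two-group experiments the generator draws per-nucleus query means from
$\mathcal N(\mu_g, \sigma_g)$ with $\sigma_g$ set to 15% of the
background-subtracted mean — a realistic biological coefficient of
variation for nuclear signal — and derives per-image seeds from one base
seed, so an entire 16-image experiment is reproducible from a single
integer. The validation experiments use control/experimental query means
50/140 over background 20, i.e. corrected means 30/120 and a true
fold-change of 4, with pixel noise SD 5.

What the generator does **not** emulate: neuropil texture and structured
autofluorescence, optical blur and the partial-volume dimming of nucleus
edges, Poisson photon statistics, anisotropic nucleus shapes, and z-stacks
with per-slice content (multi-slice handling is exercised with synthetic
stacks, but the disks live in one slice). Passing tests therefore
demonstrate that the *algorithmic* chain is correct and unbiased under its
own assumptions — not that segmentation will be clean on any particular
tissue. On real images the threshold and particle filters still need the
empirical tuning the interactive workflow was designed for.

## Numerical and degenerate-case decisions

* Corrected means may be negative (a dim nucleus on bright background);
  they are flagged with a warning and **never clipped** — clipping would
  bias fold-changes towards controls.
* An empty background mask (ROIs tile the selection) makes background
  undefined: an error, with advice, rather than a silent 0.
* An image with no surviving ROIs yields an empty table whose CSV still
  carries the summary row (ROI count 0), so batch outputs stay rectangular.
* Means are accumulated in double precision; CSV round-trips are exact to
  at least $10^{-6}$.
* Per-image failures in a batch are recorded and skipped; the run
  continues and the exit status distinguishes clean/partial/failed.

## Problem sizes used in validation

The test suite validates oracle equivalence (flood-fill labelling,
exhaustive Otsu search, per-pixel polygon membership) on dozens to
hundreds of randomised 20–64 px cases, and the statistical recovery
properties on 50 replicate experiments of 16 images (128×128 px, 10 nuclei
each) per ratio — sizes chosen so the full suite documents the behaviour
of every stage while remaining quick enough to run on every change.
Recovery accuracy at these sizes is limited by sampling error, which the
3-standard-error acceptance band accounts for; larger images or more
replicates would tighten the band but test the same mathematics.

## Known limitations

* Segmentation is a single global threshold per image: gradients in
  marker staining need the selection to exclude the affected region, or
  manual levels per image.
* Background is global; local background structure (e.g. tracheae) biases
  corrected means and is not modelled.
* The perimeter estimator is an outer-boundary walk; particles with
  internal holes are measured by their filled outline length, and
  circularity for particles under ~10 px² is dominated by discretisation
  (hence the clamp).
* 3-D measurement (voxels across z) is out of scope; stacks are reduced
  to one plane by projection or slice choice.
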