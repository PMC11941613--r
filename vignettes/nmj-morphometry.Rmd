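---
title: "Quantifying diaphragm NMJ morphology from two-channel confocal stacks"
author: "nmjMorph"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying diaphragm NMJ morphology from two-channel confocal stacks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nmjMorph)
```

## The measurement problem

A neuromuscular junction (NMJ) seen en face in whole-mount diaphragm
muscle consists of a post-synaptic motor end-plate — a branched
"pretzel" of acetylcholine-receptor membrane labeled by
alpha-bungarotoxin — and, overlying it, the pre-synaptic nerve terminal
labeled by anti-synaptophysin. Confocal z-stacks of such junctions
(two 12-bit channels, 0.5 x 0.5 um pixels, 1 um steps, 10--18 optical
slices, superficial junctions no deeper than 60 um) support a small set
of morphometric descriptors that track denervation:

* **pre-synaptic terminal volume** and **motor end-plate volume**:
  foreground voxel counts of the binarized channels times the physical
  voxel volume (0.25 um^3 at default geometry);
* **planar area**: the end-plate's area in a maximum-intensity
  projection (MIP);
* **relative planar area**: planar area divided by the area spanned by
  the end-plate's two main orthogonal axes, as a percentage. A
  sprawling, branched end-plate fills little of its axes box, so lower
  values indicate higher complexity;
* **apposition percentage**: the volume of the intersection of the two
  binarized channels as a percentage of the pre-synaptic volume —
  the fraction of the terminal directly opposing the end-plate;
* **denervation category**: innervated / partially denervated / fully
  denervated, from the overlap of the two structures in projection.

The package implements this pipeline end to end and couples it to a
synthetic stack generator with voxel-level ground truth, so that every
stage can be validated by parameter recovery rather than by eye.

## Segmentation

The original analyses of this kind used manual thresholding in
commercial software, which cannot be reproduced exactly. The default
here is automatic Otsu thresholding computed on the full 3D intensity
histogram with 256 bins; fixed thresholds remain available
(`measureConfig(method = "fixed", fixedThreshold = ...)`), and every
threshold applied is logged and stored on the mask.

Two guards make the automatic threshold safe on degenerate inputs. A
constant-intensity channel has no Otsu optimum and returns an empty
mask with a warning. A channel with no labeled structure at all (the
pre-synaptic channel of a fully denervated junction) has an essentially
unimodal histogram, and an unguarded Otsu threshold would land inside
the background noise and segment most of the stack; when the threshold
is indistinguishable from background (within six robust standard
deviations of the median intensity) the structure is declared absent.
The practical consequence is a detection limit: terminal remnants of a
few tens of um^3 measure as zero volume and classify as fully
denervated, which is the intended reading of such junctions.

Mask cleanup removes 26-connected components smaller than
`minObjectVolume` (default 5 um^3, well above single-voxel noise
speckle) and, for the pre-synaptic channel, retains only components
within `linkDistance` (default 2 um) of the end-plate mask. The second
rule exists because synaptophysin labels axons as well as terminals;
axonal segments distant from the end-plate would otherwise inflate the
terminal volume. A connected axonal stub that enters the terminal
remains part of its component and contributes about one percent of the
terminal volume — the same ambiguity a human analyst faces. Apposition
is computed on cleaned masks by default
(`measureConfig(appositionOnCleaned = FALSE)` reverts to raw masks).

## Shape descriptors

The MIP is binarized with the same threshold calibrated on the 3D
histogram of its channel. The "main orthogonal axes" of the end-plate
are taken as the principal axes of the foreground pixel cloud (second
central moments); the axes-box area is the product of the extents along
the two axes, each measured between extreme pixel centers plus one
pixel width, so an axis-aligned filled rectangle scores a relative
planar area of exactly 100 percent. A convex-hull denominator would be
an alternative reading of "the area described by the main orthogonal
axes"; the axes box is the more literal one and is what we implement.
For degenerate (collinear) masks the minor extent falls back to one
pixel width.

The visual denervation call of the original workflow is replaced by a
quantitative rule on the projected overlap fraction
f = |pre MIP ∩ end-plate MIP| / |end-plate MIP|: innervated when
f >= 0.80, partially denervated when 0.10 <= f < 0.80, fully denervated
below 0.10. Boundary values classify into the higher-innervation class.
Both cutoffs are configurable
(`measureConfig(denervationThresholds = c(0.10, 0.80))`).

## The synthetic generator

The generator's purpose is statistical, not photorealistic: it produces
stacks whose measured morphometrics have the population structure of
the replication design, with exact voxel-level truth for validation.

**Geometry.** The end-plate skeleton is a gently curved main path
(~24 um) with 4--6 branches (9--13 um) that alternate sides, laid on a
smoothly undulating surface patch (+/- 0.9 um). The skeleton is grown
into a tube by taking the `k` nearest voxels in an axially stretched
metric, where `k` is the voxel count of the target volume — so the true
end-plate volume matches its target to well under the 5 percent
calibration bound by construction. The axial stretch (default 1.5)
makes branch cross-sections taller than wide, which is what a structure
sampled at 1 um steps with an axially elongated confocal PSF
effectively looks like. Tube defaults were chosen so that measured
relative planar area lands in the low-to-mid 40s percent at branch
count 4--6, the range reported for adult diaphragm end-plates.

The terminal is a flatter tube over the covered fraction of the
skeleton, lifted toward the superficial face of the end-plate; the lift
height is solved by bisection so that the realized fraction of terminal
voxels inside the end-plate mask matches the apposition target, and
true apposition increases strictly with the target. A `coverage`
parameter sets how much of the end-plate footprint the terminal spans,
which is what drives the projected-overlap denervation classes:
innervated junctions draw coverage 0.92--1, partially denervated
0.35--0.65 with apposition 25--50 percent, fully denervated junctions
keep only a 30--120 um^3 remnant at 2--8 percent coverage.

**Rendering.** Fluorophore density is full in the structure core and
tapers linearly over the outermost ~1.4 um of the boundary to half
density, as label density does at real structure margins; a hard
density step would make thresholded volumes systematically larger than
the geometric truth under the PSF. Each channel is blurred with a
separable Gaussian PSF (defaults sigma 0.6 um lateral, 1.2 um axial),
subjected to Poisson photon noise (`noiseLevel` is intensity units per
detected photon; 0 disables noise, the default 10 gives a foreground
signal-to-noise ratio around 14), rounded and clipped to the 12-bit
range. Axonal label is rendered on by default: a thin stub exiting the
terminal plus a stray filament at least 8 um from the end-plate, which
the reference-linked cleanup must remove. Background sits at 100 DN and
foreground at 2000 DN of 4095 — a well-exposed confocal acquisition.

**Populations.** Per-NMJ targets are drawn from truncated normals
(volumes truncated at zero, apposition clamped to [0, 1]). A
between-animal random effect takes a fraction (default 0.4) of each
printed per-NMJ SD, giving an intraclass correlation near 0.16 —
a typical magnitude for nested histological data — and the
within-animal SD is reduced so the marginal SD matches the printed
value. Animals alternate sexes within each group; per-animal NMJ
counts are drawn at 40 +/- 11 with the study's floor of at least 35 en
face NMJs. Body masses use the published sex-specific moments with a
small 7-day change (SD 1.2 g) that keeps the paired pre/post contrast
non-significant at n = 6, as reported.

**What the generator does not emulate.** Antibody penetration gradients
with depth, detector read noise, chromatic misregistration, neighboring
junctions in one field, and end-plate fragmentation. Passing
parameter-recovery tests therefore shows the pipeline is internally
consistent on idealized junction geometry, not that it is robust to
every artifact of real acquisitions.

## Statistics

The statistical battery follows the replication design: one-way ANOVA
with treatment as a fixed effect for per-NMJ morphometrics (individual
NMJs as units, matching the original analysis; a mixed model
acknowledging NMJ-within-animal correlation is a known improvement we
deliberately do not make, so that the replication stays faithful),
two-way ANOVA of per-animal category proportions with treatment,
category and their interaction (Type-II sums of squares, appropriate
for the unbalanced per-animal table; proportions are analyzed
untransformed as in the source design), the Pearson chi-square test on
the category count table, Tukey--Kramer post hoc comparisons, and
matched-pairs t-tests for body mass. All tests are two-sided at
alpha = 0.05. Model fitting is delegated to `stats::lm`/`aov`,
`stats::chisq.test`, `stats::TukeyHSD`, `stats::t.test` and
`car::Anova`; the package owns the contracts and degenerate-case
handling (zero within-group variance reports an infinite F with p = 0,
empty factorial cells drop the interaction with a warning, zero-margin
count tables are an error naming the margin).

Effect sizes are percent changes relative to the vehicle mean,
100 (vehicle - chloroquine) / vehicle, a fold change for the
partial-denervation proportion, and the male/female body-mass percent
difference; `reportedEffects()` rounds to the conventional printed
precision (integer percents, one-decimal fold).

`powerCheck()` gives the Monte-Carlo power of the animal-level
comparison under the nested variance model. At the default profile
(per-NMJ SD 236 um^3 with 0.4 between-animal fraction, 40 NMJs per
animal) four animals per group reach over 80 percent power for a 20
percent treatment effect, consistent with the design rationale of this
kind of study.

## Numerical choices and degenerate inputs

* Volumes and areas are pure voxel/pixel counting; no isosurface
  interpolation. The digital-ball and digital-ellipse closed-form
  checks in the test suite bound the discretization error (3 and 2
  percent at the sizes tested).
* Otsu uses 256 equal bins over the full 12-bit range; the threshold
  reported is the lower edge of the first foreground bin and
  foreground is `intensity >= threshold`.
* Distance computations (tube growth, reference-linked cleanup) are
  exact Euclidean distances on voxel centers, chunked to bound memory.
* Bisection for the terminal lift height runs nine iterations, giving
  sub-0.01 um height resolution; realized (not target) apposition is
  recorded as truth.
* Per-NMJ and per-animal seeds are derived from the master seed with a
  fixed 31-bit linear map, so cohorts are reproducible element-wise and
  fast and image modes draw identical parameters at matched seeds.
* Empty or absent structures: empty pre-synaptic mask forces
  apposition 0 and class fully denervated; a junction with both
  channels empty is flagged invalid and excluded from statistics with
  a log line; animals with no valid junction are dropped from
  aggregation with a warning.

## Problem sizes

Rendered validation runs use one junction per stack at 256 x 192 x 18
voxels (a reduced field that comfortably contains one junction;
full-frame 800 x 600 rendering is available via `dims =`). The test
suite measures a 50-junction batch for parameter recovery and uses
10^4-replicate null simulations for type-I calibration; the fast
(measurement-free) mode is used wherever images are not the point,
including the full-scale 12-animal replication.

## Known limitations

* Measured volumes inherit a residual systematic component from global
  Otsu thresholding on blurred structures; on the default geometry the
  cohort-level bias is within a few percent, but individual thin
  junctions can deviate by 10--15 percent, and occasional threshold
  outliers occur (about one junction in twenty).
* The denervation classifier depends on the projected overlap only; a
  terminal hovering above the end-plate without 3D contact would be
  called innervated, as it would be by eye on a MIP.
* NMJ-level inference ignores within-animal correlation by design
  (fidelity to the replicated analysis), so NMJ-level p-values are
  anti-conservative relative to a mixed model.
* The generator does not model end-plate fragmentation, so the
  complexity index's response to fragmentation is untested here.
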