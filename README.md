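# nmjMorph

3D morphometry of diaphragm neuromuscular junctions (NMJs) from
two-channel confocal z-stacks, plus a synthetic-stack generator with
voxel-level ground truth and the statistical battery of a two-arm
(vehicle vs chloroquine) treatment study.

The package is for researchers quantifying NMJ remodeling — e.g. under
autophagy inhibition or aging — from whole-mount muscle labeled with
alpha-bungarotoxin (motor end-plates) and anti-synaptophysin
(pre-synaptic terminals). From each en face junction it measures:

* pre-synaptic terminal volume and motor end-plate volume, as
  foreground voxels x voxel volume of the binarized channels;
* planar area of the end-plate in a maximum-intensity projection, and
  the **relative planar area** `100 · planar / axes-box` (the axes box
  spans the two principal axes of the end-plate footprint) — an
  inverse index of end-plate complexity;
* the **apposition percentage**
  `100 · |pre ∩ end-plate| / |pre|` of the binarized 3D volumes;
* a denervation category (innervated / partially / fully denervated)
  from the projected overlap fraction f = |pre ∩ end-plate| / |end-plate|
  with configurable cutoffs (0.10, 0.80).

Per-animal aggregation and the study statistics (one-way ANOVA on
per-NMJ morphometrics, two-way treatment x category ANOVA on per-animal
proportions with Type-II sums of squares, Pearson chi-square on
category counts, Tukey–Kramer post hocs, matched-pairs body-mass
t-tests, Monte-Carlo power of the animal-level design) sit on top,
ending in derived effect sizes such as the percent loss of pre-synaptic
volume relative to vehicle, `100 (vehicle − chloroquine) / vehicle`.

## Worked example

Render one synthetic junction, measure it, and compare with the known
truth:

```r
library(nmjMorph)

params <- NMJParams(targetEndplateVolume = 1800, targetPreVolume = 1325,
                    targetApposition = 0.66, branchCount = 5L, seed = 11)
r <- renderNMJStack(params)
r$truth
#> NMJGroundTruth: end-plate 1800.0 um^3, terminal 1325.0 um^3, apposition 66.2%

rec <- measureNMJ(r$stack)
round(rec[, c("pre_volume", "endplate_volume", "relative_planar_area",
              "apposition_pct")], 1)
#>   pre_volume endplate_volume relative_planar_area apposition_pct
#> 1       1385            1727                 39.6           64.9
rec$category
#> [1] "innervated"
```

The measured volumes sit a few percent from the truth (global Otsu
thresholding on PSF-blurred structures), apposition within a few
points, and the junction classifies as innervated.

A full fast-mode replication of the two-arm design (6 animals/group,
~40 NMJs each, calibrated to the published group moments in
`inst/extdata/study_calibration.yaml`):

```r
rep <- runStudy(defaultStudyConfig(seed = 42))
reportedEffects(rep@effects)
#> $pctChangePreVolume    17
#> $pctChangeApposition   15
#> $pctChangeInnervated   13
#> $foldPartialDenervation 2
#> $pctMassSexDifference  48
rep@stats$pre_volume@table$p.value[1] < 0.05
#> [1] TRUE
```

Effect estimates vary a few points across seeds (six animals per arm is
a small sample); the report's `verdicts` table checks each against its
configured bracket. A command-line front end wrapping the same
functions is in `inst/scripts/nmj-pipeline.R`
(`generate`, `measure`, `stats`, `replicate` subcommands).

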