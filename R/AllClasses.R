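#' @import methods
#' @importFrom stats rnorm rpois runif sd var lm anova aov TukeyHSD t.test
#'   chisq.test pt pf setNames complete.cases
#' @importFrom utils read.csv write.csv
NULL

DN_MAX <- 4095L  # 12-bit dynamic range
CATEGORIES <- c("innervated", "partially_denervated", "fully_denervated")

#' ImageStack: a two-channel confocal z-stack
#'
#' Container for a two-channel 3D intensity grid as acquired for en face
#' neuromuscular junction (NMJ) imaging: a synaptophysin-labeled
#' pre-synaptic channel and an alpha-bungarotoxin-labeled motor end-plate
#' channel, 12-bit intensities (0--4095), with physical voxel dimensions.
#'
#' @slot voxels 4D numeric array indexed \code{[y, x, z, channel]}.
#' @slot voxelSize numeric(3), voxel pitch in micrometres along (y, x, z);
#'   default acquisition geometry is 0.5 x 0.5 x 1 um.
#' @slot channelRoles character(2) naming channels 1 and 2; must be
#'   \code{"pre_synaptic"} and \code{"end_plate"} in some order.
#' @aliases ImageStack
#' @exportClass ImageStack
setClass("ImageStack",
  representation(voxels = "array", voxelSize = "numeric",
                 channelRoles = "character"))

setValidity("ImageStack", function(object) {
  v <- object@voxels
  if (length(dim(v)) != 4L)
    return("voxels must be a 4D [y, x, z, channel] array")
  if (dim(v)[4L] != 2L)
    return("exactly 2 channels are required")
  if (anyNA(v) || min(v) < 0 || max(v) > DN_MAX)
    return(sprintf("intensities must lie in [0, %d]", DN_MAX))
  if (length(object@voxelSize) != 3L || any(object@voxelSize <= 0) ||
      any(!is.finite(object@voxelSize)))
    return("voxelSize must be 3 strictly positive values (um)")
  if (length(object@channelRoles) != 2L ||
      !setequal(object@channelRoles, c("pre_synaptic", "end_plate")))
    return("channelRoles must be 'pre_synaptic' and 'end_plate'")
  TRUE
})

#' Construct an ImageStack
#'
#' @param voxels 4D numeric array \code{[y, x, z, channel]} of 12-bit
#'   intensities.
#' @param voxelSize numeric(3) voxel pitch (y, x, z) in micrometres.
#' @param channelRoles character(2), roles of channels 1 and 2.
#' @return An [ImageStack-class] object.
#' @examples
#' v <- array(0, c(8, 8, 4, 2))
#' s <- ImageStack(v)
#' nSlices(s)
#' @export
ImageStack <- function(voxels, voxelSize = c(0.5, 0.5, 1),
                       channelRoles = c("pre_synaptic", "end_plate")) {
  new("ImageStack", voxels = voxels, voxelSize = as.numeric(voxelSize),
      channelRoles = channelRoles)
}

#' BinaryVolume: a segmented 3D mask
#'
#' A binarized single-channel voxel set carrying its physical voxel size,
#' so that voxel counts convert to volumes in cubic micrometres.
#'
#' @slot mask 3D logical array \code{[y, x, z]}.
#' @slot voxelSize numeric(3) voxel pitch (y, x, z) in micrometres.
#' @slot channelRole character(1), which channel the mask came from.
#' @slot threshold numeric(1), the intensity threshold used to produce the
#'   mask (NA when not applicable).
#' @aliases BinaryVolume
#' @exportClass BinaryVolume
setClass("BinaryVolume",
  representation(mask = "array", voxelSize = "numeric",
                 channelRole = "character", threshold = "numeric"))

setValidity("BinaryVolume", function(object) {
  if (length(dim(object@mask)) != 3L || !is.logical(object@mask))
    return("mask must be a 3D logical array")
  if (length(object@voxelSize) != 3L || any(object@voxelSize <= 0))
    return("voxelSize must be 3 strictly positive values (um)")
  TRUE
})

#' @rdname BinaryVolume-class
#' @param mask 3D logical array.
#' @param voxelSize numeric(3) voxel pitch (y, x, z) in micrometres.
#' @param channelRole character(1) channel role label.
#' @param threshold numeric(1) threshold that produced the mask.
#' @export
BinaryVolume <- function(mask, voxelSize = c(0.5, 0.5, 1),
                         channelRole = NA_character_,
                         threshold = NA_real_) {
  new("BinaryVolume", mask = mask, voxelSize = as.numeric(voxelSize),
      channelRole = channelRole, threshold = as.numeric(threshold))
}

#' BinaryMask2D: a segmented projection mask
#'
#' A binarized 2D pixel set (typically from a maximum-intensity
#' projection) carrying its pixel size for area arithmetic.
#'
#' @slot mask 2D logical matrix \code{[y, x]}.
#' @slot pixelSize numeric(2) pixel pitch (y, x) in micrometres.
#' @aliases BinaryMask2D
#' @exportClass BinaryMask2D
setClass("BinaryMask2D",
  representation(mask = "matrix", pixelSize = "numeric"))

setValidity("BinaryMask2D", function(object) {
  if (!is.logical(object@mask)) return("mask must be logical")
  if (length(object@pixelSize) != 2L || any(object@pixelSize <= 0))
    return("pixelSize must be 2 strictly positive values (um)")
  TRUE
})

#' @rdname BinaryMask2D-class
#' @param mask 2D logical matrix.
#' @param pixelSize numeric(2) pixel pitch (y, x) in micrometres.
#' @export
BinaryMask2D <- function(mask, pixelSize = c(0.5, 0.5)) {
  new("BinaryMask2D", mask = mask, pixelSize = as.numeric(pixelSize))
}

#' NMJParams: generative parameters for one synthetic NMJ
#'
#' Target morphology for a single rendered NMJ: end-plate and pre-synaptic
#' terminal volumes, the fraction of the terminal apposing the end-plate,
#' the branching of the "pretzel" end-plate, how much of the end-plate
#' footprint the terminal spans (which drives the projected-overlap
#' denervation class), imaging depth, and photon noise.
#'
#' @slot targetEndplateVolume target motor end-plate volume, um^3.
#' @slot targetPreVolume target pre-synaptic terminal volume, um^3.
#' @slot targetApposition fraction in [0, 1] of the terminal volume that
#'   must intersect the end-plate mask.
#' @slot branchCount positive integer, number of end-plate branches.
#' @slot coverage fraction in (0, 1] of the end-plate skeleton the
#'   terminal overlies; 1 for fully innervated morphology, small values
#'   for (near-)denervated morphology.
#' @slot depthOffset imaging depth of the NMJ below the muscle surface,
#'   um; recorded as metadata, must not exceed 60 um (superficial NMJs).
#' @slot noiseLevel intensity units per detected photon (inverse photon
#'   gain); 0 disables Poisson noise, larger values are noisier.
#' @slot seed integer RNG seed making the rendering deterministic.
#' @slot category intended denervation category (one of
#'   \code{"innervated"}, \code{"partially_denervated"},
#'   \code{"fully_denervated"}); generative intent, not a measurement.
#' @aliases NMJParams
#' @exportClass NMJParams
setClass("NMJParams",
  representation(targetEndplateVolume = "numeric",
                 targetPreVolume = "numeric",
                 targetApposition = "numeric",
                 branchCount = "integer",
                 coverage = "numeric",
                 depthOffset = "numeric",
                 noiseLevel = "numeric",
                 seed = "integer",
                 category = "character"))

setValidity("NMJParams", function(object) {
  n1 <- c(object@targetEndplateVolume, object@targetPreVolume,
          object@targetApposition, object@coverage, object@depthOffset,
          object@noiseLevel)
  if (any(!is.finite(n1))) return("all numeric parameters must be finite")
  if (object@targetEndplateVolume <= 0 || object@targetPreVolume <= 0)
    return("target volumes must be > 0")
  if (object@targetApposition < 0 || object@targetApposition > 1)
    return("targetApposition must lie in [0, 1]")
  if (object@branchCount < 1L) return("branchCount must be >= 1")
  if (object@coverage <= 0 || object@coverage > 1)
    return("coverage must lie in (0, 1]")
  if (object@depthOffset < 0 || object@depthOffset > 60)
    return("depthOffset must lie in [0, 60] um (superficial NMJs only)")
  if (object@noiseLevel < 0) return("noiseLevel must be >= 0")
  if (!object@category %in% CATEGORIES)
    return("category must be one of the denervation categories")
  TRUE
})

#' @rdname NMJParams-class
#' @param targetEndplateVolume,targetPreVolume,targetApposition,branchCount
#'   see slots.
#' @param coverage,depthOffset,noiseLevel,seed,category see slots.
#' @export
NMJParams <- function(targetEndplateVolume = 1800,
                      targetPreVolume = 1325,
                      targetApposition = 0.66,
                      branchCount = 5L,
                      coverage = 1,
                      depthOffset = 20,
                      noiseLevel = 10,
                      seed = 1L,
                      category = "innervated") {
  new("NMJParams",
      targetEndplateVolume = targetEndplateVolume,
      targetPreVolume = targetPreVolume,
      targetApposition = targetApposition,
      branchCount = as.integer(branchCount),
      coverage = coverage,
      depthOffset = depthOffset,
      noiseLevel = noiseLevel,
      seed = as.integer(seed),
      category = category)
}

#' NMJGroundTruth: voxel-level truth for one synthetic NMJ
#'
#' Exact noiseless masks and the realized scalar truths for one rendered
#' NMJ. Realized volumes equal foreground voxel count times voxel volume
#' by construction, which is what parameter-recovery tests compare
#' pipeline measurements against.
#'
#' @slot params the [NMJParams-class] that produced the NMJ.
#' @slot preMask,endplateMask noiseless [BinaryVolume-class] masks
#'   (terminal only; stray/exiting axon label is not part of the truth).
#' @slot preVolume,endplateVolume realized volumes, um^3.
#' @slot appositionPct realized 3D apposition, percent of the pre-synaptic
#'   volume intersecting the end-plate.
#' @aliases NMJGroundTruth
#' @exportClass NMJGroundTruth
setClass("NMJGroundTruth",
  representation(params = "NMJParams",
                 preMask = "BinaryVolume",
                 endplateMask = "BinaryVolume",
                 preVolume = "numeric",
                 endplateVolume = "numeric",
                 appositionPct = "numeric"))

setValidity("NMJGroundTruth", function(object) {
  vv <- prod(object@preMask@voxelSize)
  if (abs(object@preVolume - sum(object@preMask@mask) * vv) > 1e-9)
    return("preVolume must equal voxel count x voxel volume exactly")
  vv <- prod(object@endplateMask@voxelSize)
  if (abs(object@endplateVolume - sum(object@endplateMask@mask) * vv) > 1e-9)
    return("endplateVolume must equal voxel count x voxel volume exactly")
  if (object@appositionPct < 0 || object@appositionPct > 100)
    return("appositionPct must lie in [0, 100]")
  TRUE
})

#' GroupConfig: population parameters for one treatment group
#'
#' Calibration slots for a treatment group's NMJ population: per-NMJ
#' morphometric moments, the per-animal NMJ count distribution, the
#' denervation category mixture, the between-animal variance fraction,
#' and sex-specific body-mass moments.
#'
#' @slot label treatment-group name (e.g. \code{"vehicle"}).
#' @slot nAnimals number of animals in the group.
#' @slot nmjPerAnimalMean,nmjPerAnimalSD per-animal NMJ count moments.
#' @slot nmjMin minimum en face NMJs accepted per animal (study protocol:
#'   at least 35).
#' @slot endplateVolumeMean,endplateVolumeSD end-plate volume moments, um^3.
#' @slot preVolumeMean,preVolumeSD pre-synaptic volume moments, um^3.
#' @slot appositionMean,appositionSD percent-apposition moments.
#' @slot rpaMean,rpaSD relative planar area moments, percent.
#' @slot categoryProbs probability triple (innervated, partially
#'   denervated, fully denervated); must sum to 1.
#' @slot animalEffectFraction fraction of each per-NMJ SD attributed to a
#'   between-animal random effect (nested variance model).
#' @slot bodyMass named numeric: maleMean, maleSD, femaleMean, femaleSD
#'   pre-treatment body masses (g), plus changeMean, changeSD for the
#'   7-day mass change.
#' @aliases GroupConfig
#' @exportClass GroupConfig
setClass("GroupConfig",
  representation(label = "character", nAnimals = "integer",
                 nmjPerAnimalMean = "numeric", nmjPerAnimalSD = "numeric",
                 nmjMin = "integer",
                 endplateVolumeMean = "numeric", endplateVolumeSD = "numeric",
                 preVolumeMean = "numeric", preVolumeSD = "numeric",
                 appositionMean = "numeric", appositionSD = "numeric",
                 rpaMean = "numeric", rpaSD = "numeric",
                 categoryProbs = "numeric",
                 animalEffectFraction = "numeric",
                 bodyMass = "numeric"))

setValidity("GroupConfig", function(object) {
  sds <- c(object@nmjPerAnimalSD, object@endplateVolumeSD,
           object@preVolumeSD, object@appositionSD, object@rpaSD)
  vals <- c(sds, object@nmjPerAnimalMean, object@endplateVolumeMean,
            object@preVolumeMean, object@appositionMean, object@rpaMean,
            object@categoryProbs, object@animalEffectFraction,
            object@bodyMass)
  if (any(!is.finite(vals))) return("configuration values must be finite")
  if (any(sds < 0)) return("all SDs must be >= 0")
  if (object@nAnimals < 1L) return("nAnimals must be > 0")
  if (length(object@categoryProbs) != 3L ||
      abs(sum(object@categoryProbs) - 1) > 1e-9 ||
      any(object@categoryProbs < 0))
    return("categoryProbs must be 3 nonnegative values summing to 1")
  need <- c("maleMean", "maleSD", "femaleMean", "femaleSD",
            "changeMean", "changeSD")
  if (!all(need %in% names(object@bodyMass)))
    return(paste("bodyMass must contain", paste(need, collapse = ", ")))
  if (object@animalEffectFraction < 0 || object@animalEffectFraction >= 1)
    return("animalEffectFraction must lie in [0, 1)")
  TRUE
})

#' @rdname GroupConfig-class
#' @param label,nAnimals,nmjPerAnimalMean,nmjPerAnimalSD,nmjMin see slots.
#' @param endplateVolumeMean,endplateVolumeSD,preVolumeMean,preVolumeSD
#'   see slots.
#' @param appositionMean,appositionSD,rpaMean,rpaSD,categoryProbs see slots.
#' @param animalEffectFraction,bodyMass see slots.
#' @export
GroupConfig <- function(label,
                        nAnimals = 6L,
                        nmjPerAnimalMean = 40, nmjPerAnimalSD = 11,
                        nmjMin = 35L,
                        endplateVolumeMean = 1792, endplateVolumeSD = 259,
                        preVolumeMean = 1411, preVolumeSD = 236,
                        appositionMean = 66, appositionSD = 11,
                        rpaMean = 45, rpaSD = 8,
                        categoryProbs = c(0.93, 0.07, 0),
                        animalEffectFraction = 0.4,
                        bodyMass = c(maleMean = 33.3, maleSD = 2.9,
                                     femaleMean = 22.6, femaleSD = 1.2,
                                     changeMean = 0, changeSD = 1.2)) {
  new("GroupConfig", label = label, nAnimals = as.integer(nAnimals),
      nmjPerAnimalMean = nmjPerAnimalMean, nmjPerAnimalSD = nmjPerAnimalSD,
      nmjMin = as.integer(nmjMin),
      endplateVolumeMean = endplateVolumeMean,
      endplateVolumeSD = endplateVolumeSD,
      preVolumeMean = preVolumeMean, preVolumeSD = preVolumeSD,
      appositionMean = appositionMean, appositionSD = appositionSD,
      rpaMean = rpaMean, rpaSD = rpaSD,
      categoryProbs = unname(categoryProbs),
      animalEffectFraction = animalEffectFraction,
      bodyMass = bodyMass)
}

#' StudyConfig: a full two-arm study definition
#'
#' @slot groups list of two [GroupConfig-class] objects with distinct
#'   labels (conventionally vehicle and chloroquine).
#' @slot seed integer master seed.
#' @slot mode \code{"fast"} (emit measurements from the population model)
#'   or \code{"image"} (render stacks and measure them).
#' @slot measure list of measurement settings (see [measureConfig()]).
#' @slot targets named list of replication target brackets, each a list
#'   with elements \code{expected} and \code{tol}.
#' @aliases StudyConfig
#' @exportClass StudyConfig
setClass("StudyConfig",
  representation(groups = "list", seed = "integer", mode = "character",
                 measure = "list", targets = "list"))

setValidity("StudyConfig", function(object) {
  if (length(object@groups) != 2L ||
      !all(vapply(object@groups, is, logical(1), "GroupConfig")))
    return("groups must be a list of two GroupConfig objects")
  labs <- vapply(object@groups, slot, character(1), "label")
  if (anyDuplicated(labs)) return("group labels must be distinct")
  if (!object@mode %in% c("fast", "image"))
    return("mode must be 'fast' or 'image'")
  if (length(object@seed) != 1L || is.na(object@seed))
    return("seed must be set")
  TRUE
})

#' StatsResult: one statistical test result
#'
#' @slot statisticName e.g. \code{"F"}, \code{"t"}, \code{"X-squared"}.
#' @slot table data.frame with one row per tested term: columns
#'   \code{term}, \code{ss} (sum of squares where applicable),
#'   \code{statistic}, \code{df1}, \code{df2}, \code{p.value}.
#' @slot groupSummaries data.frame of per-group n, mean, sd.
#' @aliases StatsResult
#' @exportClass StatsResult
setClass("StatsResult",
  representation(statisticName = "character", table = "data.frame",
                 groupSummaries = "data.frame"))

setValidity("StatsResult", function(object) {
  tb <- object@table
  if (!all(c("term", "statistic", "df1", "p.value") %in% names(tb)))
    return("table must have term, statistic, df1, p.value columns")
  p <- tb$p.value[!is.na(tb$p.value)]
  if (any(p < 0 | p > 1)) return("p-values must lie in [0, 1]")
  TRUE
})

.statsResult <- function(name, table, groupSummaries = data.frame()) {
  new("StatsResult", statisticName = name, table = table,
      groupSummaries = groupSummaries)
}

#' EffectSizes: derived between-group effect sizes
#'
#' Percent changes are computed relative to the vehicle group,
#' 100 x (vehicle - chloroquine) / vehicle; the partial-denervation effect
#' is the chloroquine / vehicle fold change of the group proportion.
#'
#' @slot raw named numeric of unrounded effect sizes.
#' @slot reported named list rounded to the precision conventionally
#'   printed (integer percent, one-decimal fold).
#' @aliases EffectSizes
#' @exportClass EffectSizes
setClass("EffectSizes",
  representation(raw = "numeric", reported = "list"))

#' ReplicationReport: full study output
#'
#' @slot measurements per-NMJ measurement table.
#' @slot perAnimal per-animal aggregates (means and category proportions).
#' @slot animals animal metadata table.
#' @slot stats named list of [StatsResult-class] objects.
#' @slot effects an [EffectSizes-class] object.
#' @slot verdicts data.frame comparing computed effects against the
#'   configured target brackets.
#' @aliases ReplicationReport
#' @exportClass ReplicationReport
setClass("ReplicationReport",
  representation(measurements = "data.frame", perAnimal = "data.frame",
                 animals = "data.frame", stats = "list",
                 effects = "EffectSizes", verdicts = "data.frame"))

setValidity("ReplicationReport", function(object) {
  if (nrow(object@verdicts) &&
      !all(c("target", "value", "expected", "tol", "pass") %in%
           names(object@verdicts)))
    return("verdicts must have target, value, expected, tol, pass columns")
  TRUE
})

#' NMJCohort: a generated synthetic cohort
#'
#' @slot animals animal metadata (id, sex, treatment, age, body masses).
#' @slot measurements per-NMJ generator-truth table; in fast mode these
#'   are the emitted measurements, in image mode the rendering targets.
#' @slot stacks in image mode, a list (one element per NMJ) of lists with
#'   \code{nmj_id}, \code{animal_id}, \code{stack} ([ImageStack-class])
#'   and \code{truth} ([NMJGroundTruth-class]); empty in fast mode.
#' @slot mode \code{"fast"} or \code{"image"}.
#' @aliases NMJCohort
#' @exportClass NMJCohort
setClass("NMJCohort",
  representation(animals = "data.frame", measurements = "data.frame",
                 stacks = "list", mode = "character"))
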