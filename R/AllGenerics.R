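#' Accessors for image containers
#'
#' \code{voxelSize} returns the physical voxel pitch in micrometres along
#' (y, x, z); \code{channelRoles} the channel role labels;
#' \code{nSlices} the number of optical slices; \code{channelData} one
#' channel's 3D intensity array; \code{maskArray} the logical array of a
#' binary mask; \code{usedThreshold} the intensity threshold that
#' produced a mask.
#'
#' @param object an [ImageStack-class], [BinaryVolume-class] or
#'   [BinaryMask2D-class] object as appropriate.
#' @param channel channel role name (\code{"pre_synaptic"} or
#'   \code{"end_plate"}) or index.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("voxelSize", function(object) standardGeneric("voxelSize"))
#' @rdname accessors
#' @export
setGeneric("channelRoles", function(object) standardGeneric("channelRoles"))
#' @rdname accessors
#' @export
setGeneric("nSlices", function(object) standardGeneric("nSlices"))
#' @rdname accessors
#' @export
setGeneric("channelData",
           function(object, channel) standardGeneric("channelData"))
#' @rdname accessors
#' @export
setGeneric("maskArray", function(object) standardGeneric("maskArray"))
#' @rdname accessors
#' @export
setGeneric("usedThreshold",
           function(object) standardGeneric("usedThreshold"))

#' @rdname accessors
setMethod("voxelSize", "ImageStack", function(object) object@voxelSize)
#' @rdname accessors
setMethod("voxelSize", "BinaryVolume", function(object) object@voxelSize)
#' @rdname accessors
setMethod("channelRoles", "ImageStack", function(object) object@channelRoles)
#' @rdname accessors
setMethod("nSlices", "ImageStack", function(object) dim(object@voxels)[3L])
#' @rdname accessors
setMethod("channelData", "ImageStack", function(object, channel) {
  object@voxels[, , , .channelIndex(object, channel), drop = TRUE]
})
#' @rdname accessors
setMethod("maskArray", "BinaryVolume", function(object) object@mask)
#' @rdname accessors
setMethod("maskArray", "BinaryMask2D", function(object) object@mask)
#' @rdname accessors
setMethod("usedThreshold", "BinaryVolume", function(object) object@threshold)

.channelIndex <- function(stack, channel) {
  if (is.character(channel)) {
    idx <- match(channel, stack@channelRoles)
    if (is.na(idx)) stop("no channel with role '", channel, "'")
    idx
  } else {
    ch <- as.integer(channel)
    if (ch < 1L || ch > 2L) stop("channel index must be 1 or 2")
    ch
  }
}

setMethod("show", "ImageStack", function(object) {
  d <- dim(object@voxels)
  cat(sprintf("ImageStack: %d x %d pixels, %d slices, 2 channels (%s)\n",
              d[2L], d[1L], d[3L],
              paste(object@channelRoles, collapse = ", ")))
  cat(sprintf("  voxel size %.3g x %.3g x %.3g um; intensity range [%d, %d]\n",
              object@voxelSize[2L], object@voxelSize[1L], object@voxelSize[3L],
              as.integer(min(object@voxels)), as.integer(max(object@voxels))))
})

setMethod("show", "BinaryVolume", function(object) {
  d <- dim(object@mask)
  cat(sprintf("BinaryVolume (%s): %d x %d x %d, %d foreground voxels, %.1f um^3\n",
              object@channelRole, d[2L], d[1L], d[3L], sum(object@mask),
              sum(object@mask) * prod(object@voxelSize)))
})

setMethod("show", "BinaryMask2D", function(object) {
  cat(sprintf("BinaryMask2D: %d x %d, %d foreground pixels, %.1f um^2\n",
              ncol(object@mask), nrow(object@mask), sum(object@mask),
              sum(object@mask) * prod(object@pixelSize)))
})

setMethod("show", "NMJParams", function(object) {
  cat(sprintf(paste0("NMJParams: end-plate %.0f um^3, terminal %.0f um^3, ",
                     "apposition %.0f%%, %d branches, coverage %.2f (%s)\n"),
              object@targetEndplateVolume, object@targetPreVolume,
              100 * object@targetApposition, object@branchCount,
              object@coverage, object@category))
})

setMethod("show", "NMJGroundTruth", function(object) {
  cat(sprintf(paste0("NMJGroundTruth: end-plate %.1f um^3, terminal %.1f ",
                     "um^3, apposition %.1f%%\n"),
              object@endplateVolume, object@preVolume, object@appositionPct))
})

setMethod("show", "GroupConfig", function(object) {
  cat(sprintf("GroupConfig '%s': %d animals, ~%.0f NMJs/animal\n",
              object@label, object@nAnimals, object@nmjPerAnimalMean))
  cat(sprintf("  pre %.0f+/-%.0f um^3, end-plate %.0f+/-%.0f um^3, apposition %.0f+/-%.0f%%\n",
              object@preVolumeMean, object@preVolumeSD,
              object@endplateVolumeMean, object@endplateVolumeSD,
              object@appositionMean, object@appositionSD))
  cat(sprintf("  category probs: %s\n",
              paste(sprintf("%s %.2f", CATEGORIES, object@categoryProbs),
                    collapse = ", ")))
})

setMethod("show", "StatsResult", function(object) {
  cat(sprintf("StatsResult (%s):\n", object@statisticName))
  print(object@table, row.names = FALSE, digits = 4)
  if (nrow(object@groupSummaries)) {
    cat("group summaries:\n")
    print(object@groupSummaries, row.names = FALSE, digits = 4)
  }
})

setMethod("show", "EffectSizes", function(object) {
  cat("EffectSizes (reported):\n")
  for (nm in names(object@reported))
    cat(sprintf("  %s: %s\n", nm, format(object@reported[[nm]])))
})

setMethod("show", "NMJCohort", function(object) {
  cat(sprintf("NMJCohort (%s mode): %d animals, %d NMJs%s\n",
              object@mode, nrow(object@animals), nrow(object@measurements),
              if (length(object@stacks))
                sprintf(", %d rendered stacks", length(object@stacks))
              else ""))
})

setMethod("show", "ReplicationReport", function(object) {
  cat(sprintf("ReplicationReport: %d NMJs in %d animals\n",
              nrow(object@measurements), nrow(object@animals)))
  cat("analyses: ", paste(names(object@stats), collapse = ", "), "\n")
  show(object@effects)
  if (nrow(object@verdicts)) {
    cat("replication verdicts:\n")
    print(object@verdicts, row.names = FALSE, digits = 4)
  }
})
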