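# Per-NMJ shape descriptors: MIP planar area, orthogonal-axes area,
# relative planar area, 3D apposition, and denervation classification.

#' Maximum-intensity projection of one channel
#'
#' Per-pixel maximum over the optical slices. The projection is
#' binarized downstream with the same threshold machinery as the 3D
#' volume (see [binarize2D()]).
#'
#' @param stack an [ImageStack-class].
#' @param channel channel role name or index.
#' @return A 2D intensity matrix.
#' @export
maxIntensityProjection <- function(stack, channel) {
  stopifnot(is(stack, "ImageStack"))
  v <- stack@voxels[, , , .channelIndex(stack, channel), drop = TRUE]
  if (length(dim(v)) == 2L) return(v)  # single-slice stack
  apply(v, c(1L, 2L), max)
}

#' Binarize a 2D intensity image at a fixed threshold
#'
#' @param img 2D intensity matrix (e.g. a maximum-intensity projection).
#' @param threshold intensity threshold; pixels >= threshold are
#'   foreground.
#' @param pixelSize numeric(2) pixel pitch (y, x) um.
#' @return A [BinaryMask2D-class].
#' @export
binarize2D <- function(img, threshold, pixelSize = c(0.5, 0.5)) {
  BinaryMask2D(img >= threshold, pixelSize)
}

#' Planar area of a 2D mask
#'
#' Pixel count times pixel area; 0 with a warning for an empty mask.
#'
#' @param mask2d a [BinaryMask2D-class].
#' @return Area in square micrometres.
#' @export
planarArea <- function(mask2d) {
  stopifnot(is(mask2d, "BinaryMask2D"))
  n <- sum(mask2d@mask)
  if (n == 0L) {
    warning("empty 2D mask; planar area is 0")
    return(0)
  }
  n * prod(mask2d@pixelSize)
}

#' Area spanned by the main orthogonal axes of a 2D mask
#'
#' The two principal axes of the foreground pixel-coordinate cloud are
#' taken from the eigenvectors of its second moments; the returned area
#' is the product of the extents along the two axes, each measured
#' between extreme pixel centers plus one pixel width. For a degenerate
#' (collinear) mask the minor extent falls back to one pixel width.
#'
#' @param mask2d a [BinaryMask2D-class] with at least 3 foreground
#'   pixels.
#' @return Area in square micrometres.
#' @export
orthogonalAxesArea <- function(mask2d) {
  stopifnot(is(mask2d, "BinaryMask2D"))
  idx <- which(mask2d@mask, arr.ind = TRUE)
  if (nrow(idx) < 3L)
    stop("orthogonalAxesArea needs at least 3 foreground pixels")
  px <- mean(mask2d@pixelSize)
  pts <- cbind((idx[, 2L] - 1) * mask2d@pixelSize[2L],
               (idx[, 1L] - 1) * mask2d@pixelSize[1L])
  ctr <- colMeans(pts)
  cpts <- sweep(pts, 2L, ctr)
  cv <- crossprod(cpts) / nrow(cpts)
  ev <- eigen(cv, symmetric = TRUE)$vectors
  proj <- cpts %*% ev
  extents <- apply(proj, 2L, function(p) max(p) - min(p)) + px
  if (any(extents <= px + 1e-12))
    message("degenerate (collinear) mask: minor extent set to one pixel width")
  extents <- pmax(extents, px)
  prod(extents)
}

#' Relative planar area
#'
#' 100 x planar area / orthogonal-axes area. The relative planar area
#' indexes end-plate complexity: a lower value reflects greater
#' branching (a sprawling pretzel fills less of its axes box), a higher
#' value lower complexity.
#'
#' @param planar planar area, um^2.
#' @param axes orthogonal-axes area, um^2 (> 0).
#' @return Percentage.
#' @examples
#' relativePlanarArea(75, 150)  # 50
#' @export
relativePlanarArea <- function(planar, axes) {
  if (!is.finite(axes) || axes <= 0) {
    warning("axes area is zero or undefined; relative planar area flagged NA")
    return(NA_real_)
  }
  100 * planar / axes
}

#' 3D apposition percentage
#'
#' Volume of the intersection of the binarized pre- and post-synaptic
#' masks, expressed as the percentage of the pre-synaptic volume
#' opposing the motor end-plate.
#'
#' @param pre,post [BinaryVolume-class] masks on the same grid.
#' @return Percentage in [0, 100]; 0 for an empty pre-synaptic mask
#'   (the record is then classified fully denervated downstream).
#' @export
appositionPercent <- function(pre, post) {
  stopifnot(is(pre, "BinaryVolume"), is(post, "BinaryVolume"))
  if (!identical(dim(pre@mask), dim(post@mask)) ||
      !isTRUE(all.equal(pre@voxelSize, post@voxelSize)))
    stop("pre and post masks must share grid and voxel size")
  nPre <- sum(pre@mask)
  if (nPre == 0L) return(0)
  100 * sum(pre@mask & post@mask) / nPre
}

#' Classify denervation from projected overlap
#'
#' The overlap fraction f = |pre2d intersect post2d| / |post2d| on
#' binarized maximum-intensity projections is thresholded into the three
#' denervation categories. Boundary values classify into the
#' higher-innervation class (f = 0.80 is innervated under the defaults).
#'
#' @param pre2d,post2d [BinaryMask2D-class] projections on the same
#'   grid; \code{post2d} must be nonempty.
#' @param thresholds numeric(2): (full-denervation cutoff, innervation
#'   cutoff) on f; defaults (0.10, 0.80).
#' @return One of \code{"innervated"}, \code{"partially_denervated"},
#'   \code{"fully_denervated"}.
#' @export
classifyDenervation <- function(pre2d, post2d, thresholds = c(0.10, 0.80)) {
  stopifnot(is(pre2d, "BinaryMask2D"), is(post2d, "BinaryMask2D"))
  if (!identical(dim(pre2d@mask), dim(post2d@mask)))
    stop("projection masks must share the grid")
  nPost <- sum(post2d@mask)
  if (nPost == 0L) stop("post-synaptic projection is empty")
  f <- sum(pre2d@mask & post2d@mask) / nPost
  if (f >= thresholds[2L]) "innervated"
  else if (f >= thresholds[1L]) "partially_denervated"
  else "fully_denervated"
}

#' Measurement settings for the NMJ pipeline
#'
#' @param method \code{"otsu"} or \code{"fixed"} binarization.
#' @param fixedThreshold threshold used when \code{method = "fixed"}.
#' @param minObjectVolume,linkDistance mask-cleaning settings, um^3 / um
#'   (see [cleanMask()]).
#' @param cleanPre clean the pre-synaptic mask against the end-plate
#'   reference (excludes distant axonal label).
#' @param appositionOnCleaned compute apposition on the cleaned
#'   pre-synaptic mask (default) or the raw thresholded one.
#' @param denervationThresholds overlap-fraction cutoffs for
#'   [classifyDenervation()].
#' @return A named list of settings.
#' @export
measureConfig <- function(method = "otsu", fixedThreshold = NULL,
                          minObjectVolume = 5, linkDistance = 2,
                          cleanPre = TRUE, appositionOnCleaned = TRUE,
                          denervationThresholds = c(0.10, 0.80)) {
  list(method = method, fixedThreshold = fixedThreshold,
       minObjectVolume = minObjectVolume, linkDistance = linkDistance,
       cleanPre = cleanPre, appositionOnCleaned = appositionOnCleaned,
       denervationThresholds = denervationThresholds)
}

#' Measure one NMJ stack
#'
#' Runs the full per-NMJ pipeline: binarize both channels, clean the
#' masks (the pre-synaptic mask against the end-plate reference), take
#' 3D volumes, compute the MIP descriptors with the 3D-calibrated
#' thresholds, the 3D apposition percentage, and the denervation
#' category.
#'
#' @param stack an [ImageStack-class].
#' @param config settings from [measureConfig()].
#' @param nmj_id identifier stored in the output row.
#' @return A one-row data.frame (an NMJ record): \code{nmj_id},
#'   \code{pre_volume}, \code{endplate_volume}, \code{planar_area},
#'   \code{axes_area}, \code{relative_planar_area},
#'   \code{apposition_pct}, \code{category}, the thresholds used, and a
#'   \code{valid} flag (FALSE when both channels segment empty; such
#'   records are excluded from statistics).
#' @export
measureNMJ <- function(stack, config = measureConfig(), nmj_id = NA) {
  stopifnot(is(stack, "ImageStack"))
  binz <- function(channel) {
    if (config$method == "fixed")
      binarizeChannel(stack, channel, "fixed",
                      threshold = config$fixedThreshold)
    else binarizeChannel(stack, channel, "otsu")
  }
  epRaw <- suppressWarnings(binz("end_plate"))
  ep <- cleanMask(epRaw, config$minObjectVolume, config$linkDistance)
  preRaw <- suppressWarnings(binz("pre_synaptic"))
  pre <- if (config$cleanPre)
    cleanMask(preRaw, config$minObjectVolume, config$linkDistance,
              reference = ep)
  else cleanMask(preRaw, config$minObjectVolume, config$linkDistance)

  epEmpty <- !any(ep@mask)
  preEmpty <- !any(pre@mask)
  if (epEmpty && preEmpty) {
    message("measureNMJ: both channels empty for NMJ ", nmj_id,
            "; record flagged invalid")
    return(data.frame(nmj_id = nmj_id, pre_volume = NA_real_,
                      endplate_volume = NA_real_, planar_area = NA_real_,
                      axes_area = NA_real_, relative_planar_area = NA_real_,
                      apposition_pct = NA_real_, category = NA_character_,
                      pre_threshold = pre@threshold,
                      endplate_threshold = ep@threshold, valid = FALSE,
                      stringsAsFactors = FALSE))
  }

  preVol <- maskVolume(if (config$appositionOnCleaned) pre else preRaw)
  epVol <- maskVolume(ep)
  ps2 <- stack@voxelSize[1:2]

  planar <- axes <- rpa <- NA_real_
  category <- NA_character_
  app <- 0
  if (!epEmpty) {
    epMIP <- binarize2D(maxIntensityProjection(stack, "end_plate"),
                        ep@threshold, ps2)
    planar <- planarArea(epMIP)
    if (sum(epMIP@mask) >= 3L) {
      axes <- orthogonalAxesArea(epMIP)
      rpa <- relativePlanarArea(planar, axes)
    }
    preMIP <- binarize2D(maxIntensityProjection(stack, "pre_synaptic"),
                         if (is.na(pre@threshold)) DN_MAX + 1
                         else pre@threshold, ps2)
    category <- classifyDenervation(preMIP, epMIP,
                                    config$denervationThresholds)
    appMask <- if (config$appositionOnCleaned) pre else preRaw
    if (any(appMask@mask)) {
      app <- appositionPercent(appMask, ep)
    } else {
      app <- 0
      category <- "fully_denervated"
    }
  }
  data.frame(nmj_id = nmj_id,
             pre_volume = preVol, endplate_volume = epVol,
             planar_area = planar, axes_area = axes,
             relative_planar_area = rpa, apposition_pct = app,
             category = category,
             pre_threshold = pre@threshold,
             endplate_threshold = ep@threshold,
             valid = !epEmpty, stringsAsFactors = FALSE)
}
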