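#' Write a two-channel stack as multi-page TIFF with a JSON sidecar
#'
#' Pages are interleaved per optical slice (pre-synaptic page, then
#' end-plate page), 12-bit intensities stored in a 16-bit container. A
#' sidecar \code{<path>.json} records the voxel size, channel roles and,
#' optionally, the generator seed and scalar ground truth.
#'
#' @param stack an [ImageStack-class].
#' @param path output TIFF path.
#' @param truth optional [NMJGroundTruth-class]; its scalar truths are
#'   stored in the sidecar.
#' @param sidecar logical, write the JSON sidecar (default TRUE).
#' @return \code{path}, invisibly.
#' @export
writeStack <- function(stack, path, truth = NULL, sidecar = TRUE) {
  stopifnot(is(stack, "ImageStack"))
  validObject(stack)
  d <- dim(stack@voxels)
  pages <- vector("list", d[3L] * 2L)
  ord <- match(c("pre_synaptic", "end_plate"), stack@channelRoles)
  for (z in seq_len(d[3L])) {
    pages[[2L * z - 1L]] <- stack@voxels[, , z, ord[1L]] / 65535
    pages[[2L * z]] <- stack@voxels[, , z, ord[2L]] / 65535
  }
  tiff::writeTIFF(pages, path, bits.per.sample = 16L)
  if (sidecar) {
    meta <- list(voxel_size_um = stack@voxelSize,
                 channel_order = c("pre_synaptic", "end_plate"),
                 n_slices = d[3L])
    if (!is.null(truth)) {
      meta$seed <- truth@params@seed
      meta$ground_truth <- list(
        pre_volume_um3 = truth@preVolume,
        endplate_volume_um3 = truth@endplateVolume,
        apposition_pct = truth@appositionPct,
        target_endplate_volume_um3 = truth@params@targetEndplateVolume,
        target_pre_volume_um3 = truth@params@targetPreVolume,
        target_apposition = truth@params@targetApposition,
        depth_offset_um = truth@params@depthOffset,
        category = truth@params@category)
    }
    jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                         digits = NA)
  }
  invisible(path)
}

#' Read a two-channel stack from multi-page TIFF
#'
#' Expects the layout written by [writeStack()]: an even number of pages
#' (two channels interleaved per slice) in a 16-bit container holding
#' 12-bit data. Voxel size and channel order are taken from the JSON
#' sidecar when present, otherwise the default acquisition geometry
#' (0.5 x 0.5 x 1 um) is assumed with a warning.
#'
#' @param path TIFF path.
#' @return An [ImageStack-class].
#' @export
readStack <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  pages <- tiff::readTIFF(path, all = TRUE, info = TRUE)
  n <- length(pages)
  if (n %% 2L != 0L)
    stop("format error: odd page count (", n,
         "); expected two channels interleaved per slice")
  bps <- attr(pages[[1L]], "bits.per.sample")
  if (!is.null(bps) && bps != 16L)
    stop("format error: expected a 16-bit container, found ", bps, "-bit")
  vox <- vapply(pages, function(p) round(p * 65535), pages[[1L]] * 0)
  if (max(vox) > DN_MAX)
    stop("format error: intensity ", max(vox), " exceeds the 12-bit ",
         "maximum of ", DN_MAX)
  sidecar <- paste0(path, ".json")
  voxelSize <- c(0.5, 0.5, 1)
  roles <- c("pre_synaptic", "end_plate")
  if (file.exists(sidecar)) {
    meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
    if (!is.null(meta$voxel_size_um)) voxelSize <- meta$voxel_size_um
    if (!is.null(meta$channel_order)) roles <- meta$channel_order
    if (length(roles) != 2L)
      stop("format error: sidecar lists ", length(roles),
           " channels; exactly 2 are required")
  } else {
    warning("no sidecar metadata for ", path,
            "; assuming 0.5 x 0.5 x 1 um voxels")
  }
  nz <- n %/% 2L
  d <- dim(pages[[1L]])
  voxels <- array(0, c(d[1L], d[2L], nz, 2L))
  for (z in seq_len(nz)) {
    voxels[, , z, 1L] <- vox[, , 2L * z - 1L]
    voxels[, , z, 2L] <- vox[, , 2L * z]
  }
  # map pages to canonical channel order
  idx <- match(c("pre_synaptic", "end_plate"), roles)
  if (anyNA(idx))
    stop("format error: sidecar channel_order must name pre_synaptic ",
         "and end_plate")
  ImageStack(voxels[, , , idx, drop = FALSE], voxelSize = voxelSize)
}

#' Write a per-NMJ measurement table to CSV
#'
#' One row per NMJ carrying the animal metadata alongside the NMJ's
#' measurements. The reload via [readMeasurements()] is lossless to
#' double precision.
#'
#' @param measurements data.frame with at least \code{animal_id} and
#'   \code{nmj_id} columns (as produced by [runStudy()] or
#'   [generateCohort()]).
#' @param path output CSV path.
#' @return \code{path}, invisibly.
#' @export
writeMeasurements <- function(measurements, path) {
  stopifnot(is.data.frame(measurements))
  if (nrow(measurements)) {
    need <- c("animal_id", "nmj_id")
    if (!all(need %in% names(measurements)))
      stop("measurements must have animal_id and nmj_id columns")
    dup <- duplicated(measurements[, need])
    if (any(dup))
      stop("integrity error: duplicated nmj_id within animal: ",
           paste(unique(measurements$nmj_id[dup]), collapse = ", "))
  }
  num <- vapply(measurements, is.numeric, logical(1))
  out <- measurements
  out[num] <- lapply(out[num], function(x) format(x, digits = 17,
                                                  trim = TRUE,
                                                  scientific = FALSE))
  write.csv(out, path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' @rdname writeMeasurements
#' @export
readMeasurements <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  read.csv(path, stringsAsFactors = FALSE)
}
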