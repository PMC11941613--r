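# Binarization and mask cleanup: the reproducible stand-in for manual
# thresholding in the original 3D analysis workflow.

# Otsu threshold on a 256-bin histogram of the full 3D intensity volume.
# Returns the lower edge of the first foreground bin; voxels >= threshold
# are foreground.
.otsu3D <- function(v, nbins = 256L, maxval = DN_MAX) {
  breaks <- seq(0, maxval + 1, length.out = nbins + 1L)
  h <- tabulate(findInterval(v, breaks, rightmost.closed = TRUE),
                nbins = nbins)
  w <- h / sum(h)
  mids <- (breaks[-1L] + breaks[-(nbins + 1L)]) / 2
  w0 <- cumsum(w)
  mu <- cumsum(w * mids)
  muT <- mu[nbins]
  sigmaB <- (muT * w0 - mu)^2 / (w0 * (1 - w0))
  sigmaB[!is.finite(sigmaB)] <- -Inf
  if (all(sigmaB == -Inf)) return(NA_real_)  # constant volume
  k <- which.max(sigmaB)  # background = bins 1..k
  breaks[k + 1L]
}

#' Binarize one channel of a stack
#'
#' Voxels at or above the threshold become foreground. With
#' \code{method = "otsu"} the threshold maximizes the between-class
#' variance of the full 3D intensity histogram (256 bins); with
#' \code{method = "fixed"} the supplied threshold is used. The threshold
#' actually applied is logged via \code{message()} and stored on the
#' returned mask.
#'
#' @param stack an [ImageStack-class].
#' @param channel channel role name or index.
#' @param method \code{"otsu"} or \code{"fixed"}.
#' @param threshold fixed threshold in [0, 4095]; required when
#'   \code{method = "fixed"}.
#' @return A [BinaryVolume-class]; empty-foreground results are returned
#'   with a warning, not an error (downstream treats them as absent
#'   structure).
#' @export
binarizeChannel <- function(stack, channel, method = c("otsu", "fixed"),
                            threshold = NULL) {
  stopifnot(is(stack, "ImageStack"))
  method <- match.arg(method)
  ch <- .channelIndex(stack, channel)
  v <- stack@voxels[, , , ch, drop = TRUE]
  if (length(dim(v)) != 3L) v <- array(v, c(dim(v), 1L))
  if (method == "fixed") {
    if (is.null(threshold) || threshold < 0 || threshold > DN_MAX)
      stop("fixed threshold must be supplied within [0, ", DN_MAX, "]")
    t <- threshold
  } else {
    t <- .otsu3D(v)
    if (is.na(t)) {
      warning("constant-intensity channel; Otsu undefined, ",
              "returning an empty mask")
      return(BinaryVolume(array(FALSE, dim(v)), stack@voxelSize,
                          stack@channelRoles[ch], NA_real_))
    }
    # degeneracy guard: with no labeled structure in the channel the
    # histogram is unimodal and Otsu lands inside the background noise;
    # treat the structure as absent rather than segmenting noise
    bgSpread <- stats::mad(v)
    if (t <= stats::median(v) + 6 * bgSpread) {
      warning("Otsu threshold (", round(t), ") is indistinguishable from ",
              "background in channel '", stack@channelRoles[ch],
              "'; treating the structure as absent")
      return(BinaryVolume(array(FALSE, dim(v)), stack@voxelSize,
                          stack@channelRoles[ch], NA_real_))
    }
  }
  mask <- v >= t
  message(sprintf("binarizeChannel: channel '%s', %s threshold = %.1f, %d voxels",
                  stack@channelRoles[ch], method, t, sum(mask)))
  if (!any(mask))
    warning("empty foreground after thresholding channel '",
            stack@channelRoles[ch], "'")
  BinaryVolume(mask, stack@voxelSize, stack@channelRoles[ch], t)
}

# 26-connected component labels of a 3D logical array; 0 = background.
.labelComponents3D <- function(mask) {
  dims <- dim(mask)
  fg <- which(mask)
  lab <- array(0L, dims)
  if (!length(fg)) return(lab)
  a <- arrayInd(fg, dims)
  off <- expand.grid(dy = -1:1, dx = -1:1, dz = -1:1)
  off <- off[off$dz > 0 | (off$dz == 0 & (off$dx > 0 |
               (off$dx == 0 & off$dy > 0))), ]  # half neighbourhood
  from <- integer(0); to <- integer(0)
  for (k in seq_len(nrow(off))) {
    y <- a[, 1L] + off$dy[k]; x <- a[, 2L] + off$dx[k]
    z <- a[, 3L] + off$dz[k]
    ok <- y >= 1L & y <= dims[1L] & x >= 1L & x <= dims[2L] &
      z >= 1L & z <= dims[3L]
    nidx <- y[ok] + (x[ok] - 1L) * dims[1L] + (z[ok] - 1L) * dims[1L] * dims[2L]
    j <- match(nidx, fg)
    hit <- !is.na(j)
    from <- c(from, which(ok)[hit])
    to <- c(to, j[hit])
  }
  g <- igraph::make_graph(edges = rbind(from, to), n = length(fg),
                          directed = FALSE)
  lab[fg] <- as.integer(igraph::components(g)$membership)
  lab
}

#' Remove speckle and non-junctional label from a binary volume
#'
#' Drops 26-connected components smaller than \code{minObjectVolume}.
#' When a \code{reference} mask is supplied (the end-plate mask, used
#' when cleaning the pre-synaptic channel), only components lying within
#' \code{linkDistance} of the reference are retained; this excludes
#' axonal label distant from the end-plate while keeping the terminal.
#' Applying the operation twice equals applying it once.
#'
#' @param vol a [BinaryVolume-class].
#' @param minObjectVolume minimum component volume to keep, um^3.
#' @param linkDistance maximum gap (um) between a retained component and
#'   the reference mask.
#' @param reference optional [BinaryVolume-class] on the same grid.
#' @return A cleaned [BinaryVolume-class].
#' @export
cleanMask <- function(vol, minObjectVolume = 5, linkDistance = 2,
                      reference = NULL) {
  stopifnot(is(vol, "BinaryVolume"))
  voxVol <- prod(vol@voxelSize)
  lab <- .labelComponents3D(vol@mask)
  if (!any(lab > 0L)) return(vol)
  sizes <- tabulate(lab[lab > 0L])
  keep <- which(sizes * voxVol >= minObjectVolume)
  if (!is.null(reference)) {
    stopifnot(is(reference, "BinaryVolume"))
    if (!identical(dim(reference@mask), dim(vol@mask)))
      stop("reference mask must share the volume's grid")
    refIdx <- which(reference@mask)
    refC <- arrayInd(refIdx, dim(vol@mask))
    refP <- sweep(refC - 1, 2L, vol@voxelSize, "*")
    keep <- keep[vapply(keep, function(k) {
      cIdx <- which(lab == k)
      if (any(reference@mask[cIdx])) return(TRUE)  # direct intersection
      cC <- arrayInd(cIdx, dim(vol@mask))
      cP <- sweep(cC - 1, 2L, vol@voxelSize, "*")
      d2min <- Inf
      step <- 2000L
      for (s in seq(1L, nrow(cP), by = step)) {
        rows <- s:min(s + step - 1L, nrow(cP))
        d2 <- outer(rowSums(cP[rows, , drop = FALSE]^2), rowSums(refP^2),
                    "+") - 2 * cP[rows, , drop = FALSE] %*% t(refP)
        d2min <- min(d2min, min(d2))
        if (d2min <= linkDistance^2) break
      }
      d2min <= linkDistance^2 + 1e-9
    }, logical(1))]
  }
  mask <- array(lab %in% keep & lab > 0L, dim(vol@mask))
  BinaryVolume(mask, vol@voxelSize, vol@channelRole, vol@threshold)
}

#' Volume of a binary mask
#'
#' Foreground voxel count times the physical voxel volume (0.25 um^3 at
#' the default 0.5 x 0.5 x 1 um voxel size). Additive over disjoint
#' masks and monotone under mask inclusion.
#'
#' @param vol a [BinaryVolume-class].
#' @return Volume in cubic micrometres.
#' @examples
#' m <- array(FALSE, c(10, 10, 10)); m[1:10, 1:10, 1:10] <- TRUE
#' maskVolume(BinaryVolume(m))  # 1000 voxels x 0.25 um^3
#' @export
maskVolume <- function(vol) {
  stopifnot(is(vol, "BinaryVolume"))
  sum(vol@mask) * prod(vol@voxelSize)
}
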