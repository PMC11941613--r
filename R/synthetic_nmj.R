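#' Draw generative parameters for one NMJ from a group's population model
#'
#' Morphometric targets are drawn from truncated normal distributions
#' (volumes truncated at zero; apposition clamped to [0, 1]), the
#' denervation category from the group's category mixture, and the
#' footprint coverage from a category-specific range so that rendered
#' stacks reproduce the projected-overlap appearance of each class.
#'
#' @param group a [GroupConfig-class].
#' @param seed integer seed; draws are deterministic given the seed.
#' @param animalShift optional named numeric of additive animal-level
#'   effects for \code{pre}, \code{endplate} (um^3) and \code{apposition}
#'   (percent), used by [generateCohort()]'s nested variance model.
#' @return An [NMJParams-class] object.
#' @examples
#' p <- sampleNMJParams(GroupConfig("vehicle"), seed = 7)
#' p
#' @export
sampleNMJParams <- function(group, seed,
                            animalShift = c(pre = 0, endplate = 0,
                                            apposition = 0)) {
  stopifnot(is(group, "GroupConfig"))
  validObject(group)
  withSeed(seed, {
    f <- group@animalEffectFraction
    wsd <- function(s) s * sqrt(1 - f^2)  # within-animal SD
    ep <- rtruncnorm(1, group@endplateVolumeMean + animalShift[["endplate"]],
                     wsd(group@endplateVolumeSD))
    pre <- rtruncnorm(1, group@preVolumeMean + animalShift[["pre"]],
                      wsd(group@preVolumeSD))
    category <- sample(CATEGORIES, 1L, prob = group@categoryProbs)
    app <- switch(category,
      innervated = (rnorm(1, group@appositionMean +
                            animalShift[["apposition"]],
                          wsd(group@appositionSD))) / 100,
      partially_denervated = runif(1, 0.25, 0.50),
      fully_denervated = runif(1, 0.005, 0.05))
    app <- min(1, max(0, app))
    coverage <- switch(category,
      innervated = runif(1, 0.92, 1),
      partially_denervated = runif(1, 0.35, 0.65),
      fully_denervated = runif(1, 0.02, 0.08))
    if (category == "fully_denervated")  # terminal remnant only
      pre <- runif(1, 30, 120)
    NMJParams(targetEndplateVolume = ep,
              targetPreVolume = pre,
              targetApposition = app,
              branchCount = sample(4:6, 1L),
              coverage = coverage,
              depthOffset = runif(1, 5, 55),
              noiseLevel = 10,
              seed = deriveSeed(seed, 1L),
              category = category)
  })
}

# ---- geometry internals ----------------------------------------------------

# Branched "pretzel" skeleton: a curved main path plus branchCount side
# branches, sampled every `step` um. Returns xy coordinates, per-point
# arc fraction (main path first, then branches), and headings.
.skeletonXY <- function(branchCount, mainLength = 24,
                        branchLengthRange = c(9, 13),
                        step = 0.5, headingSD = 0.07, curvature = 0.05) {
  walk <- function(start, heading, len, kappa) {
    n <- max(2L, round(len / step))
    th <- heading + cumsum(rnorm(n, mean = kappa * step, sd = headingSD))
    cbind(x = start[1L] + cumsum(step * cos(th)),
          y = start[2L] + cumsum(step * sin(th)),
          th = th)
  }
  kap <- sample(c(-1, 1), 1L) * rnorm(1, curvature, 0.02)
  main <- walk(c(0, 0), runif(1, 0, 2 * pi), mainLength, kap)
  pts <- main
  side <- sample(c(-1, 1), 1L)
  origins <- round(seq(0.15, 0.9, length.out = branchCount) * nrow(main))
  for (b in seq_len(branchCount)) {
    origin <- min(nrow(main), max(1L, origins[b] +
                                    sample(-4:4, 1L)))
    side <- -side  # alternate sides so the footprint spreads
    bh <- main[origin, "th"] + side * runif(1, pi / 3.6, pi / 1.8)
    bl <- runif(1, branchLengthRange[1L], branchLengthRange[2L])
    bk <- sample(c(-1, 1), 1L) * rnorm(1, curvature, 0.02)
    pts <- rbind(pts, walk(main[origin, c("x", "y")], bh, bl, bk))
  }
  list(xy = pts[, c("x", "y"), drop = FALSE],
       frac = seq_len(nrow(pts)) / nrow(pts))
}

# Gently curved surface patch the end-plate lies on, z in um.
.surfaceFun <- function(center, zc, amplitude = 0.9, period = 45) {
  phi <- runif(2, 0, 2 * pi)
  function(x, y) {
    zc + amplitude * sin(2 * pi * (x - center[1L]) / period + phi[1L]) *
      sin(2 * pi * (y - center[2L]) / period + phi[2L])
  }
}

# Min (possibly axially rescaled) distance and nearest-point index from
# every voxel center in a padded bounding box around `pts` (n x 3, um)
# to the point set. zscale > 1 shrinks axial distances, so "balls" of
# the metric are axially elongated ellipsoids: tubes grown in this
# metric are taller than wide, matching the axially elongated confocal
# point-spread function.
.distanceField <- function(pts, dims, voxelSize, pad, zscale = 1) {
  vs <- voxelSize
  padv <- c(pad, pad, pad * zscale)
  lo <- pmax(c(1L, 1L, 1L),
             as.integer(floor((apply(pts, 2L, min)[c(2L, 1L, 3L)] - padv) /
                                vs)) + 1L)
  hi <- pmin(dims, as.integer(ceiling((apply(pts, 2L, max)[c(2L, 1L, 3L)] +
                                         padv) / vs)) + 1L)
  ys <- lo[1L]:hi[1L]; xs <- lo[2L]:hi[2L]; zs <- lo[3L]:hi[3L]
  spts <- pts
  spts[, 3L] <- spts[, 3L] / zscale
  p2 <- rowSums(spts^2)
  idx <- integer(0); dmin <- numeric(0); nearest <- integer(0)
  for (z in zs) {
    g <- expand.grid(y = ys, x = xs)
    vox <- cbind((g$x - 1) * vs[2L], (g$y - 1) * vs[1L],
                 (z - 1) * vs[3L] / zscale)
    d2 <- outer(rowSums(vox^2), p2, "+") - 2 * vox %*% t(spts)
    j <- max.col(-d2, ties.method = "first")
    dz <- sqrt(pmax(0, d2[cbind(seq_len(nrow(d2)), j)]))
    idx <- c(idx, g$y + (g$x - 1L) * dims[1L] +
               (z - 1L) * dims[1L] * dims[2L])
    dmin <- c(dmin, dz)
    nearest <- c(nearest, j)
  }
  list(idx = idx, dist = dmin, nearest = nearest,
       box = list(lo = lo, hi = hi))
}

# Linear voxel indices of a tube of radius r (um) around polyline points.
.tubeVoxels <- function(pts, r, dims, voxelSize) {
  vs <- voxelSize
  ry <- floor(r / vs[1L]); rx <- floor(r / vs[2L]); rz <- floor(r / vs[3L])
  off <- expand.grid(dy = -ry:ry, dx = -rx:rx, dz = -rz:rz)
  off <- off[(off$dy * vs[1L])^2 + (off$dx * vs[2L])^2 +
               (off$dz * vs[3L])^2 <= r^2, , drop = FALSE]
  cy <- round(pts[, 2L] / vs[1L]) + 1L
  cx <- round(pts[, 1L] / vs[2L]) + 1L
  cz <- round(pts[, 3L] / vs[3L]) + 1L
  out <- integer(0)
  for (k in seq_len(nrow(off))) {
    y <- cy + off$dy[k]; x <- cx + off$dx[k]; z <- cz + off$dz[k]
    ok <- y >= 1L & y <= dims[1L] & x >= 1L & x <= dims[2L] &
      z >= 1L & z <= dims[3L]
    out <- c(out, y[ok] + (x[ok] - 1L) * dims[1L] +
               (z[ok] - 1L) * dims[1L] * dims[2L])
  }
  unique(out)
}

.touchesBorder <- function(idx, dims) {
  a <- arrayInd(idx, dims)
  any(a[, 1L] <= 1L | a[, 1L] >= dims[1L] |
      a[, 2L] <= 1L | a[, 2L] >= dims[2L] |
      a[, 3L] <= 1L | a[, 3L] >= dims[3L])
}

# Separable Gaussian blur: lateral blur per slice (EBImage) plus a 1D
# axial pass with edge renormalization.
.blurStack <- function(img, sigmaLateral, sigmaAxial, voxelSize) {
  if (sigmaLateral > 0) {
    if (abs(voxelSize[1L] - voxelSize[2L]) > 1e-9)
      stop("lateral PSF blur assumes square pixels")
    img <- EBImage::gblur(img, sigma = sigmaLateral / voxelSize[1L])
  }
  if (sigmaAxial > 0) {
    s <- sigmaAxial / voxelSize[3L]
    K <- ceiling(3 * s)
    w <- exp(-((-K:K)^2) / (2 * s^2))
    nz <- dim(img)[3L]
    out <- array(0, dim(img))
    norm <- numeric(nz)
    for (k in -K:K) {
      src <- pmin(pmax(seq_len(nz) + k, 1L), nz)  # handled via validity below
      valid <- (seq_len(nz) + k) >= 1L & (seq_len(nz) + k) <= nz
      wi <- w[k + K + 1L]
      for (z in which(valid)) {
        out[, , z] <- out[, , z] + wi * img[, , z + k]
      }
      norm[valid] <- norm[valid] + wi
    }
    for (z in seq_len(nz)) out[, , z] <- out[, , z] / norm[z]
    img <- out
  }
  img
}

# ---- renderer --------------------------------------------------------------

#' Render a synthetic two-channel NMJ stack with exact ground truth
#'
#' Builds a branched tubular ("pretzel") motor end-plate on a gently
#' curved surface patch, dilates its skeleton until the noiseless binary
#' volume matches the target end-plate volume, constructs the
#' pre-synaptic terminal as a cap hugging the superficial face of the
#' end-plate with an exact voxel budget realizing the target volume and
#' apposition fraction, optionally adds thin axonal label (a connected
#' exit stub plus a stray filament from a neighbouring axon), and renders
#' both channels with Gaussian PSF blur, Poisson photon noise, and 12-bit
#' quantization. The noiseless masks and realized scalars are returned as
#' ground truth. Deterministic given \code{params@@seed}.
#'
#' @param params an [NMJParams-class] object.
#' @param dims integer(3) stack dimensions (ny, nx, nz) in voxels. The
#'   default renders each NMJ in its own reduced field of view; use
#'   \code{c(600L, 800L, 14L)} for full acquisition-sized frames.
#' @param voxelSize numeric(3) voxel pitch (y, x, z) um.
#' @param psfSigma numeric(2): lateral and axial Gaussian PSF sigma, um.
#'   \code{c(0, 0)} disables blur.
#' @param bgLevel,fgLevel background and foreground intensities (12-bit
#'   DN) before blur and noise.
#' @param axon logical; render axonal synaptophysin label (on by
#'   default so segmentation must cope with non-terminal label).
#' @return A list with elements \code{stack} ([ImageStack-class]) and
#'   \code{truth} ([NMJGroundTruth-class]).
#' @examples
#' r <- renderNMJStack(NMJParams(seed = 11, noiseLevel = 0), axon = FALSE)
#' r$truth
#' @export
renderNMJStack <- function(params,
                           dims = c(192L, 256L, 18L),
                           voxelSize = c(0.5, 0.5, 1),
                           psfSigma = c(0.6, 1.2),
                           bgLevel = 100, fgLevel = 2000,
                           axon = TRUE, axialStretch = 1.5,
                           edgeTaper = 0.5, edgeTaperWidth = 1.4) {
  stopifnot(is(params, "NMJParams"))
  validObject(params)
  dims <- as.integer(dims)
  vs <- as.numeric(voxelSize)
  voxVol <- prod(vs)
  withSeed(params@seed, {
    center <- c((dims[2L] - 1L) * vs[2L] / 2, (dims[1L] - 1L) * vs[1L] / 2)
    # the end-plate sits below the mid-plane so the lifted terminal and
    # its blur skirt stay clear of the shallow stack face
    zc <- 0.62 * (dims[3L] - 1L) * vs[3L]
    sk <- .skeletonXY(params@branchCount)
    # centre the skeleton footprint in the field of view
    mid <- (apply(sk$xy, 2L, max) + apply(sk$xy, 2L, min)) / 2
    xy <- sweep(sk$xy, 2L, mid) + rep(center, each = nrow(sk$xy))
    surf <- .surfaceFun(center, zc)
    pts <- cbind(xy, z = surf(xy[, 1L], xy[, 2L]))

    fld <- .distanceField(pts, dims, vs, pad = 6, zscale = axialStretch)

    # end-plate: k-th nearest-distance dilation hits the target volume
    kEP <- round(params@targetEndplateVolume / voxVol)
    if (kEP > length(fld$dist))
      stop("generation error: target end-plate volume not realizable ",
           "inside the stack bounds")
    rEP <- sort(fld$dist, partial = kEP)[kEP]
    epSel <- which(fld$dist <= rEP)
    epIdx <- fld$idx[epSel]
    epVol <- length(epIdx) * voxVol
    if (abs(epVol - params@targetEndplateVolume) /
        params@targetEndplateVolume > 0.05)
      stop("generation error: end-plate dilation missed the target volume")
    if (.touchesBorder(epIdx, dims))
      stop("generation error: end-plate touches the stack boundary; ",
           "increase dims or reduce the target volume")

    epArr <- array(FALSE, dims); epArr[epIdx] <- TRUE

    # pre-synaptic terminal: a tube around the covered part of the
    # skeleton, lifted toward the superficial face of the end-plate; the
    # lift height is solved so that the target fraction of the terminal
    # volume lies inside the end-plate mask
    nPre <- round(params@targetPreVolume / voxVol)
    covPts <- pts[sk$frac <= params@coverage, , drop = FALSE]
    if (nrow(covPts) < 2L) covPts <- pts[1:2, , drop = FALSE]
    preAt <- function(h) {
      shifted <- covPts
      shifted[, 3L] <- shifted[, 3L] - h
      fld2 <- .distanceField(shifted, dims, vs, pad = 5,
                             zscale = 0.75 * axialStretch)
      if (nPre > length(fld2$dist))
        stop("generation error: target pre-synaptic volume not ",
             "realizable inside the stack bounds")
      r2 <- sort(fld2$dist, partial = nPre)[nPre]
      sel <- fld2$dist <= r2
      list(idx = fld2$idx[sel], dist = fld2$dist[sel], r = r2)
    }
    appFrac <- function(p) sum(epArr[p$idx]) / length(p$idx)
    lo <- 0; hi <- rEP + 2 * sqrt(nPre * voxVol / (pi * 20)) + 2
    pre <- preAt(lo)
    if (appFrac(pre) < params@targetApposition - 0.005) {
      # even fully embedded the tube cannot reach the target (coverage
      # or volume bound); realize the maximum and record it
      message("apposition target clipped by coverage; realized ",
              sprintf("%.1f%%", 100 * appFrac(pre)))
    } else {
      for (it in 1:9) {
        mid <- (lo + hi) / 2
        cand <- preAt(mid)
        if (appFrac(cand) >= params@targetApposition) lo <- mid else hi <- mid
      }
      pre <- preAt(lo)
    }
    preIdx <- pre$idx
    if (.touchesBorder(preIdx, dims))
      stop("generation error: pre-synaptic terminal touches the stack ",
           "boundary")
    preVol <- length(preIdx) * voxVol
    appPct <- 100 * appFrac(pre)

    epMaskArr <- epArr
    preMaskArr <- array(FALSE, dims); preMaskArr[preIdx] <- TRUE

    # axonal label (pre channel only; not part of the truth masks)
    axonIdx <- integer(0)
    if (axon) {
      nMain <- max(2L, round(32 / 0.5))
      endPt <- pts[min(nMain, nrow(pts)), ]
      prevPt <- pts[min(nMain, nrow(pts)) - 1L, ]
      th <- atan2(endPt[2L] - prevPt[2L], endPt[1L] - prevPt[1L])
      nseg <- 24L
      thw <- th + cumsum(rnorm(nseg, 0, 0.05))
      sx <- endPt[1L] + cumsum(0.5 * cos(thw))
      sy <- endPt[2L] + cumsum(0.5 * sin(thw))
      stub <- cbind(sx, sy, z = surf(sx, sy))
      # stray filament from a neighbouring axon, well clear of the end-plate
      epY <- (arrayInd(epIdx, dims)[, 1L] - 1) * vs[1L]
      yStray <- max(epY) + 8
      if (yStray > (dims[1L] - 2L) * vs[1L]) yStray <- min(epY) - 8
      xs <- seq(center[1L] - 22, center[1L] + 22, by = 0.5)
      stray <- cbind(xs, yStray + 1.5 * sin(xs / 7), z = zc)
      keep <- function(p) {
        p[p[, 1L] > 0 & p[, 1L] < (dims[2L] - 1L) * vs[2L] &
          p[, 2L] > 0 & p[, 2L] < (dims[1L] - 1L) * vs[1L] &
          p[, 3L] > 0 & p[, 3L] < (dims[3L] - 1L) * vs[3L], , drop = FALSE]
      }
      stub <- keep(stub); stray <- keep(stray)
      for (p in list(stub, stray))
        if (nrow(p))
          axonIdx <- c(axonIdx, .tubeVoxels(p, 0.35, dims, vs))
      axonIdx <- unique(axonIdx)
    }

    # intensity rendering: fluorophore density is full in the structure
    # core and tapers linearly over the outermost edgeTaperWidth (metric
    # units) to edgeTaper at the surface, as label density does at real
    # structure margins
    amp <- fgLevel - bgLevel
    taper <- function(d, r) {
      ifelse(d <= r - edgeTaperWidth, 1,
             edgeTaper + (1 - edgeTaper) * pmax(0, r - d) / edgeTaperWidth)
    }
    epImg <- array(bgLevel, dims)
    epImg[epIdx] <- bgLevel + amp * taper(fld$dist[epSel], rEP)
    preImg <- array(bgLevel, dims)
    if (length(axonIdx)) preImg[axonIdx] <- bgLevel + 0.8 * amp
    preImg[preIdx] <- bgLevel + amp * taper(pre$dist, pre$r)
    # FFT-based blur can undershoot slightly; Poisson rates must be >= 0
    epImg <- pmax(.blurStack(epImg, psfSigma[1L], psfSigma[2L], vs), 0)
    preImg <- pmax(.blurStack(preImg, psfSigma[1L], psfSigma[2L], vs), 0)
    if (params@noiseLevel > 0) {
      g <- params@noiseLevel
      epImg <- array(rpois(length(epImg), epImg / g) * g, dims)
      preImg <- array(rpois(length(preImg), preImg / g) * g, dims)
    }
    quant <- function(x) {
      x <- round(x)
      x[x < 0] <- 0; x[x > DN_MAX] <- DN_MAX
      x
    }
    voxels <- array(0, c(dims, 2L))
    voxels[, , , 1L] <- quant(preImg)
    voxels[, , , 2L] <- quant(epImg)
    stack <- ImageStack(voxels, voxelSize = vs,
                        channelRoles = c("pre_synaptic", "end_plate"))
    truth <- new("NMJGroundTruth",
                 params = params,
                 preMask = BinaryVolume(preMaskArr, vs, "pre_synaptic"),
                 endplateMask = BinaryVolume(epMaskArr, vs, "end_plate"),
                 preVolume = preVol,
                 endplateVolume = epVol,
                 appositionPct = appPct)
    list(stack = stack, truth = truth)
  })
}
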