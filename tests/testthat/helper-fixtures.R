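# Shared fixture builders; everything is generated in code at test time.

# Two-level stack: background voxels at bg, a cuboid object at fg, in
# both channels unless a channel-specific object is given.
twoLevelStack <- function(dims = c(24L, 24L, 6L), bg = 100, fg = 4000,
                          obj = NULL) {
  if (is.null(obj)) {
    obj <- array(FALSE, dims)
    obj[8:16, 8:16, 2:5] <- TRUE
  }
  v <- array(bg, c(dims, 2L))
  v[, , , 1L][obj] <- fg
  v[, , , 2L][obj] <- fg
  list(stack = ImageStack(v), object = obj)
}

# Digital ball mask: voxel centers within radius r (voxels) of the center.
digitalBall <- function(r, voxelSize = c(0.5, 0.5, 0.5)) {
  n <- 2L * ceiling(r) + 5L
  cx <- (n + 1) / 2
  g <- expand.grid(y = 1:n, x = 1:n, z = 1:n)
  inside <- (g$y - cx)^2 + (g$x - cx)^2 + (g$z - cx)^2 <= r^2
  BinaryVolume(array(inside, c(n, n, n)), voxelSize)
}

# Filled-ellipse 2D mask with the ellipse center on a pixel corner, so
# the extreme pixel centers straddle the true axes symmetrically.
ellipseMask <- function(a, b, pixelSize = c(0.5, 0.5)) {
  ny <- 2L * ceiling(b) + 6L; nx <- 2L * ceiling(a) + 6L
  cx <- (nx + 1) / 2; cy <- (ny + 1) / 2  # half-integer center
  g <- expand.grid(y = 1:ny, x = 1:nx)
  inside <- ((g$x - cx) / a)^2 + ((g$y - cy) / b)^2 <= 1
  BinaryMask2D(matrix(inside, ny, nx), pixelSize)
}

# Axis-aligned filled rectangle mask (ny x nx pixels of foreground).
rectMask <- function(nyFg, nxFg, pad = 4L, pixelSize = c(0.5, 0.5)) {
  m <- matrix(FALSE, nyFg + 2L * pad, nxFg + 2L * pad)
  m[pad + seq_len(nyFg), pad + seq_len(nxFg)] <- TRUE
  BinaryMask2D(m, pixelSize)
}

# Brute-force Otsu oracle: minimize the weighted within-class variance
# over every 256-bin split by direct enumeration.
otsuOracle <- function(v, nbins = 256L, maxval = 4095) {
  breaks <- seq(0, maxval + 1, length.out = nbins + 1L)
  best <- NULL; bestW <- Inf
  for (k in seq_len(nbins - 1L)) {
    t <- breaks[k + 1L]
    lo <- v[v < t]; hi <- v[v >= t]
    if (!length(lo) || !length(hi)) next
    w <- length(lo) * mean((lo - mean(lo))^2) +
      length(hi) * mean((hi - mean(hi))^2)
    if (w < bestW - 1e-9) { bestW <- w; best <- t }
  }
  best
}

quietMeasure <- function(stack, ...) {
  suppressWarnings(suppressMessages(measureNMJ(stack, ...)))
}

quietBinarize <- function(...) {
  suppressWarnings(suppressMessages(binarizeChannel(...)))
}
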