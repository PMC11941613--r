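# Shape descriptors: projections, areas, apposition, classification.

test_that("a single-slice stack projects to itself and projections dominate slices", {
  v <- array(sample(0:4095, 16 * 16 * 2, replace = TRUE), c(16, 16, 1, 2))
  s <- ImageStack(v)
  expect_identical(maxIntensityProjection(s, 1), v[, , 1, 1])
  fx <- twoLevelStack()
  mip <- maxIntensityProjection(fx$stack, "end_plate")
  for (z in seq_len(dim(fx$stack@voxels)[3]))
    expect_true(all(mip >= fx$stack@voxels[, , z, 2]))
})

test_that("the projected binary area equals the true mask's 2D shadow", {
  p <- NMJParams(noiseLevel = 0, seed = 91)
  r <- renderNMJStack(p, psfSigma = c(0, 0), axon = FALSE)
  mip <- maxIntensityProjection(r$stack, "end_plate")
  m2 <- binarize2D(mip, 600, c(0.5, 0.5))
  shadow <- apply(maskArray(r$truth@endplateMask), c(1, 2), any)
  expect_identical(maskArray(m2), shadow)
  expect_equal(planarArea(m2), sum(shadow) * 0.25)
})

test_that("planar area follows pixel counting", {
  expect_equal(planarArea(rectMask(20, 30)), 150)
  expect_warning(a0 <- planarArea(BinaryMask2D(matrix(FALSE, 5, 5))),
                 "empty")
  expect_equal(a0, 0)
  disk <- ellipseMask(40, 40)
  expect_lt(abs(planarArea(disk) - pi * 20^2) / (pi * 20^2), 0.02)
})

test_that("an axis-aligned rectangle fills its orthogonal-axes box exactly", {
  m <- rectMask(20, 30)
  expect_equal(orthogonalAxesArea(m), 150)
  expect_equal(relativePlanarArea(planarArea(m), orthogonalAxesArea(m)),
               100)
})

test_that("the axes box is rotation invariant up to discretization", {
  rot45 <- function(halfU, halfV, n) {
    ctr <- (n + 1) / 2
    g <- expand.grid(y = 1:n, x = 1:n)
    u <- ((g$x - ctr) + (g$y - ctr)) / sqrt(2)
    v <- ((g$x - ctr) - (g$y - ctr)) / sqrt(2)
    BinaryMask2D(matrix(abs(u) <= halfU & abs(v) <= halfV, n, n),
                 c(0.5, 0.5))
  }
  # at the acquisition pixel size the one-pixel-width margin overcounts
  # rotated corners by ~3 percent per axis
  m <- rot45(15, 10, 60L)
  expect_lt(abs(orthogonalAxesArea(m) - 150) / 150, 0.075)
  # the discretization error shrinks with scale: same shape, doubled
  m2 <- rot45(30, 20, 110L)
  expect_lt(abs(orthogonalAxesArea(m2) - 600) / 600, 0.05)
})

test_that("a filled ellipse's relative planar area approaches pi/4", {
  m <- ellipseMask(40, 20)
  rpa <- relativePlanarArea(planarArea(m), orthogonalAxesArea(m))
  expect_lt(abs(rpa - 100 * pi / 4), 2)
})

test_that("degenerate and tiny masks are handled explicitly", {
  row <- matrix(FALSE, 9, 9); row[5, 3:7] <- TRUE
  m <- BinaryMask2D(row, c(0.5, 0.5))
  expect_message(a <- orthogonalAxesArea(m), "collinear")
  expect_equal(a, 2.5 * 0.5)  # major extent x one pixel width
  two <- matrix(FALSE, 4, 4); two[1, 1:2] <- TRUE
  expect_error(orthogonalAxesArea(BinaryMask2D(two)), "at least 3")
  expect_warning(rpaNA <- relativePlanarArea(10, 0), "axes")
  expect_true(is.na(rpaNA))
  expect_equal(relativePlanarArea(75, 150), 50)
})

test_that("apposition percentage identities hold", {
  base <- array(FALSE, c(12, 12, 6))
  a <- base; a[2:7, 2:7, 2:4] <- TRUE
  expect_equal(appositionPercent(BinaryVolume(a), BinaryVolume(a)), 100)
  b <- base; b[9:11, 9:11, 5] <- TRUE
  expect_equal(appositionPercent(BinaryVolume(a), BinaryVolume(b)), 0)
  # 200-voxel mask with 120 voxels inside the reference
  pre <- base; pre[1:8, 1:5, 1:5] <- TRUE          # 200 voxels
  post <- base; post[1:8, 1:3, 1:5] <- TRUE        # covers 120 of them
  expect_equal(appositionPercent(BinaryVolume(pre), BinaryVolume(post)), 60)
  expect_equal(appositionPercent(BinaryVolume(base), BinaryVolume(a)), 0)
  expect_error(appositionPercent(BinaryVolume(a),
                                 BinaryVolume(array(FALSE, c(4, 4, 2)))),
               "grid")
})

test_that("denervation classification follows the overlap-fraction contract", {
  post <- matrix(FALSE, 10, 10); post[3:7, 3:6] <- TRUE  # 20 px
  sup <- matrix(FALSE, 10, 10); sup[2:8, 2:7] <- TRUE
  expect_identical(classifyDenervation(BinaryMask2D(sup),
                                       BinaryMask2D(post)), "innervated")
  expect_identical(classifyDenervation(BinaryMask2D(matrix(FALSE, 10, 10)),
                                       BinaryMask2D(post)),
                   "fully_denervated")
  half <- matrix(FALSE, 10, 10); half[3:7, 3:4] <- TRUE  # f = 0.5
  expect_identical(classifyDenervation(BinaryMask2D(half),
                                       BinaryMask2D(post)),
                   "partially_denervated")
  # boundary values go to the higher-innervation class
  b80 <- matrix(FALSE, 10, 10); b80[3:6, 3:6] <- TRUE  # 16/20 = 0.8
  expect_identical(classifyDenervation(BinaryMask2D(b80),
                                       BinaryMask2D(post)), "innervated")
  b10 <- matrix(FALSE, 10, 10); b10[3, 3:4] <- TRUE  # 2/20 = 0.1
  expect_identical(classifyDenervation(BinaryMask2D(b10),
                                       BinaryMask2D(post)),
                   "partially_denervated")
  expect_error(classifyDenervation(BinaryMask2D(half),
                                   BinaryMask2D(matrix(FALSE, 10, 10))),
               "empty")
})

test_that("measureNMJ recovers a noiseless NMJ exactly", {
  p <- NMJParams(noiseLevel = 0, seed = 101)
  r <- renderNMJStack(p, psfSigma = c(0, 0), axon = FALSE)
  rec <- quietMeasure(r$stack, measureConfig(method = "fixed",
                                             fixedThreshold = 600))
  expect_equal(rec$pre_volume, r$truth@preVolume)
  expect_equal(rec$endplate_volume, r$truth@endplateVolume)
  expect_equal(rec$apposition_pct, r$truth@appositionPct)
  expect_identical(rec$category, "innervated")
  expect_true(rec$valid)
})

test_that("measureNMJ recovers noisy NMJs within the pipeline tolerances", {
  for (s in c(111, 112, 113)) {
    r <- renderNMJStack(NMJParams(seed = s))
    rec <- quietMeasure(r$stack)
    expect_lt(abs(rec$pre_volume / r$truth@preVolume - 1), 0.15)
    expect_lt(abs(rec$endplate_volume / r$truth@endplateVolume - 1), 0.10)
    expect_lt(abs(rec$apposition_pct - r$truth@appositionPct), 5)
    expect_true(is.finite(rec$relative_planar_area))
  }
})

test_that("an empty stack yields an invalid record, excluded downstream", {
  v <- array(100, c(32, 32, 6, 2))
  set.seed(2)
  v[] <- rpois(length(v), 100)
  rec <- quietMeasure(ImageStack(v), nmj_id = "blank")
  expect_false(rec$valid)
  agg <- data.frame(animal_id = c("a", "a"), treatment = "g",
                    pre_volume = c(1000, NA), endplate_volume = c(1800, NA),
                    relative_planar_area = c(45, NA),
                    apposition_pct = c(66, NA),
                    category = c("innervated", NA),
                    valid = c(TRUE, FALSE))
  out <- aggregateByAnimal(agg)
  expect_identical(out$n_nmj, 1L)
})

test_that("branched end-plates land near the expected complexity range", {
  rpas <- vapply(121:126, function(s) {
    r <- renderNMJStack(NMJParams(branchCount = 5L, seed = s))
    quietMeasure(r$stack)$relative_planar_area
  }, numeric(1))
  expect_gt(mean(rpas), 35)
  expect_lt(mean(rpas), 50)
})
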