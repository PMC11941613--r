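# The statistical battery: frozen hand-computed oracles, degenerate
# cases, and distributional properties at small simulation sizes.

test_that("one-way ANOVA matches the hand decomposition", {
  # groups {1,2,3} vs {4,5,6}: SSB = 13.5, SSW = 4, F = 13.5 on (1, 4)
  res <- oneWayAnova(c(1, 2, 3, 4, 5, 6), rep(c("a", "b"), each = 3))
  tab <- res@table
  expect_equal(tab$statistic[1], 13.5)
  expect_equal(tab$df1[1], 1)
  expect_equal(tab$df2[1], 4)
  expect_equal(tab$ss, c(13.5, 4))
  expect_equal(tab$p.value[1], pf(13.5, 1, 4, lower.tail = FALSE))
  expect_equal(res@groupSummaries$mean, c(2, 5))
})

test_that("one-way ANOVA degenerate cases", {
  res0 <- oneWayAnova(c(1, 2, 3, 1, 2, 3), rep(c("a", "b"), each = 3))
  expect_equal(res0@table$statistic[1], 0)
  resInf <- oneWayAnova(c(1, 1, 2, 2), c("a", "a", "b", "b"))
  expect_identical(resInf@table$statistic[1], Inf)
  expect_identical(resInf@table$p.value[1], 0)
  expect_error(oneWayAnova(1:4, rep("a", 4)), ">= 2 groups")
  expect_error(oneWayAnova(1:3, c("a", "a", "b")), ">= 2 values")
})

test_that("ANOVA sums of squares decompose exactly", {
  set.seed(11)
  y <- rnorm(60, rep(c(10, 12, 9), each = 20), 2)
  g <- rep(c("a", "b", "c"), each = 20)
  res <- oneWayAnova(y, g)
  total <- sum((y - mean(y))^2)
  expect_lt(abs(sum(res@table$ss) - total) / total, 1e-9)
})

test_that("two-way ANOVA matches a brute-force Type-II oracle", {
  set.seed(21)
  A <- rep(c("t1", "t2"), times = 15)
  B <- rep(c("x", "y", "z"), each = 10)
  y <- 5 + (A == "t2") * 2 + (B == "y") * 1.5 - (B == "z") * 1 +
    (A == "t2" & B == "z") * 0.8 + rnorm(30, 0, 0.7)
  res <- twoWayAnova(y, A, B)
  # oracle: Type-II SS from residual sums of nested OLS fits, solved
  # directly through model matrices
  rss <- function(form) {
    X <- model.matrix(form, data.frame(A = A, B = B))
    sum(qr.resid(qr(X), y)^2)
  }
  ssA <- rss(~B) - rss(~A + B)
  ssB <- rss(~A) - rss(~A + B)
  ssAB <- rss(~A + B) - rss(~A * B)
  dfRes <- 30 - 6
  msRes <- rss(~A * B) / dfRes
  expect_equal(res@table$ss, c(ssA, ssB, ssAB))
  expect_equal(res@table$statistic,
               c(ssA / 1, ssB / 2, ssAB / 2) / msRes)
  expect_equal(res@table$df2, rep(dfRes, 3))
})

test_that("two-way ANOVA degenerate layouts", {
  A <- rep(c("a", "b"), each = 6)
  B <- rep(c("x", "y", "z"), times = 4)
  resConst <- twoWayAnova(rep(3, 12), A, B)
  expect_true(all(resConst@table$statistic == 0))
  expect_true(all(resConst@table$p.value == 1))
  # empty cell: interaction omitted with a warning
  A2 <- c("a", "a", "a", "a", "b", "b", "b", "b")
  B2 <- c("x", "x", "y", "y", "x", "x", "x", "x")
  expect_warning(res2 <- twoWayAnova(rnorm(8), A2, B2), "empty cells")
  expect_false("A:B" %in% res2@table$term)
})

test_that("chi-square independence matches hand computation", {
  res <- chiSquareIndependence(rbind(c(50, 50), c(25, 75)))
  expect_equal(res@table$statistic, 40 / 3)
  expect_equal(res@table$df1, 1)
  resEq <- chiSquareIndependence(rbind(c(30, 20, 10), c(30, 20, 10)))
  expect_equal(resEq@table$statistic, 0)
  expect_equal(resEq@table$p.value, 1)
  expect_error(chiSquareIndependence(rbind(c(5, 0), c(7, 0))),
               "degenerate margin")
  expect_error(chiSquareIndependence(rbind(c(1.5, 2), c(1, 2))),
               "nonnegative integers")
})

test_that("category counts at the study's scale separate the groups", {
  # mixtures and group sizes of the replication design
  veh <- round(270 * c(0.93, 0.07, 0.00))
  chl <- round(221 * c(0.78, 0.19, 0.03))
  res <- chiSquareIndependence(rbind(veh, chl))
  expect_lt(res@table$p.value, 0.05)
})

test_that("Tukey-Kramer behaves on null, shifted, and unbalanced groups", {
  set.seed(31)
  y0 <- rnorm(20, 10, 1)
  g0 <- rep(c("a", "b"), each = 10)
  tk0 <- tukeyKramer(c(y0, y0), rep(c("a", "b"), each = 20))
  expect_gt(tk0$p.adj[1], 0.5)
  # three groups, one far away: only its two pairs significant
  y <- c(rnorm(8, 0, 1), rnorm(8, 0.3, 1), rnorm(6, 8, 1))
  g <- c(rep("a", 8), rep("b", 8), rep("c", 6))
  tk <- tukeyKramer(y, g)
  hit <- tk$p.adj < 0.05
  names(hit) <- tk$pair
  expect_true(hit[["c-a"]] && hit[["c-b"]])
  expect_false(hit[["b-a"]])
  # adjusted p is conservative relative to the unadjusted pairwise test
  tt <- t.test(y[g == "b"], y[g == "a"], var.equal = TRUE)$p.value
  expect_gte(tk$p.adj[tk$pair == "b-a"], tt)
  expect_identical(nrow(tukeyKramer(y0, rep("a", 20))), 0L)
})

test_that("matched-pairs t-test identities", {
  x <- c(30.1, 33.2, 28.9, 31.5, 29.7)
  res0 <- pairedTTest(x, x)
  expect_equal(res0@table$statistic, 0)
  expect_equal(res0@table$p.value, 1)
  resC <- pairedTTest(c(2, 3, 4, 5), c(1, 2, 3, 4))
  expect_identical(resC@table$statistic, Inf)
  res <- pairedTTest(c(1, 2, 3), c(2, 2, 2))
  tt <- t.test(c(1, 2, 3), c(2, 2, 2), paired = TRUE)
  expect_equal(res@table$statistic, unname(tt$statistic))
  expect_equal(res@table$p.value, tt$p.value)
  expect_equal(res@table$df1, 2)
  expect_error(pairedTTest(1:3, 1:2), "pair up")
})

test_that("body-mass contrasts at the published group moments behave as reported", {
  # paired group means from the study table, n = 6: no significant
  # 7-day change in either arm (direction check only)
  cfg <- defaultStudyConfig(seed = 19L)
  cohort <- generateCohort(cfg)
  for (lab in c("vehicle", "chloroquine")) {
    d <- cohort@animals[cohort@animals$treatment == lab, ]
    res <- pairedTTest(d$body_mass_pre, d$body_mass_post)
    expect_gt(res@table$p.value, 0.05)
    expect_equal(res@table$df1, 5)
  }
  sexRes <- oneWayAnova(cohort@animals$body_mass_pre, cohort@animals$sex)
  expect_lt(sexRes@table$p.value[1], 0.001)
})

test_that("effect sizes reproduce the published derived values exactly", {
  es <- effectSizes(
    vehicle = list(preVolume = 1411, apposition = 66,
                   innervatedPct = 93, partialPct = 7),
    chloroquine = list(preVolume = 1248, apposition = 56,
                       innervatedPct = 78, partialPct = 19),
    maleMass = (33.3 + 30.8) / 2, femaleMass = (22.6 + 22.8) / 2)
  rep <- reportedEffects(es)
  expect_equal(rep$pctChangePreVolume, 12)
  expect_equal(rep$pctChangeApposition, 15)
  expect_equal(rep$pctChangeInnervated, 16)
  expect_equal(rep$foldPartialDenervation, 2.7)
  expect_equal(rep$pctMassSexDifference, 41)
  raw <- rawEffects(es)
  expect_equal(unname(raw["pctChangePreVolume"]), 100 * 163 / 1411)
  expect_warning(effectSizes(list(preVolume = 0, apposition = 1,
                                  innervatedPct = 1, partialPct = 1),
                             list(preVolume = 1, apposition = 1,
                                  innervatedPct = 1, partialPct = 1)),
                 "vehicle mean")
})

test_that("power analysis is calibrated at the null and monotone in effect and n", {
  p0 <- powerCheck(0, nPerGroup = 4, reps = 400, seed = 5)
  expect_lt(abs(p0 - 0.05), 0.035)
  pSmall <- powerCheck(6, nPerGroup = 4, reps = 300, seed = 6)
  pBig <- powerCheck(25, nPerGroup = 4, reps = 300, seed = 6)
  expect_gt(pBig, pSmall)
  pN2 <- powerCheck(15, nPerGroup = 2, reps = 300, seed = 7)
  pN8 <- powerCheck(15, nPerGroup = 8, reps = 300, seed = 7)
  expect_gt(pN8, pN2)
})

test_that("four animals per group suffice for a 20 percent effect", {
  pw <- powerCheck(20, nPerGroup = 4, reps = 500, seed = 8)
  expect_gte(pw, 0.8)
})
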