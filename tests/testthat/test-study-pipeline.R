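# Orchestration: aggregation, fast-mode replication, null behavior,
# and a reduced-scale image-mode run against ground truth.

test_that("per-animal aggregation computes proportions and means", {
  one <- data.frame(animal_id = "a1", treatment = "vehicle",
                    pre_volume = rnorm(40, 1400, 10),
                    endplate_volume = 1800, relative_planar_area = 45,
                    apposition_pct = 66, category = "innervated")
  agg <- aggregateByAnimal(one)
  expect_equal(agg$prop_innervated, 1)
  expect_equal(agg$prop_partially_denervated, 0)
  expect_equal(agg$prop_fully_denervated, 0)
  split <- data.frame(animal_id = "a2", treatment = "chloroquine",
                      pre_volume = 1200, endplate_volume = 1800,
                      relative_planar_area = 43, apposition_pct = 56,
                      category = rep(c("innervated",
                                       "partially_denervated",
                                       "fully_denervated"),
                                     times = c(30, 8, 2)))
  agg2 <- aggregateByAnimal(split)
  expect_equal(agg2$prop_innervated, 0.75)
  expect_equal(agg2$prop_partially_denervated, 0.20)
  expect_equal(agg2$prop_fully_denervated, 0.05)
})

test_that("category proportions always sum to one", {
  cfg <- defaultStudyConfig(seed = 23L)
  agg <- aggregateByAnimal(generateCohort(cfg)@measurements)
  sums <- agg$prop_innervated + agg$prop_partially_denervated +
    agg$prop_fully_denervated
  expect_true(all(abs(sums - 1) < 1e-12))
})

test_that("the fast-mode replication reproduces the study's pattern of effects", {
  rep <- runStudy(defaultStudyConfig(seed = 101L))
  expect_identical(nrow(rep@animals), 12L)
  expect_gte(nrow(rep@measurements), 12 * 35)
  # treatment effects present where the study found them
  expect_lt(rep@stats$pre_volume@table$p.value[1], 0.05)
  expect_lt(rep@stats$apposition@table$p.value[1], 0.05)
  expect_gt(rep@stats$endplate_volume@table$p.value[1], 0.05)
  expect_lt(rep@stats$category_counts@table$p.value, 0.05)
  tw <- rep@stats$category_proportions@table
  expect_lt(tw$p.value[tw$term == "B"], 0.05)        # category effect
  expect_lt(tw$p.value[tw$term == "A:B"], 0.05)      # interaction
  # conventional NMJ-level degrees of freedom
  expect_equal(rep@stats$pre_volume@table$df1[1], 1)
  expect_equal(rep@stats$pre_volume@table$df2[1],
               nrow(rep@measurements) - 2)
  # effect sizes in the study's direction, within stochastic brackets
  raw <- rawEffects(rep@effects)
  expect_gt(raw[["pctChangePreVolume"]], 4)
  expect_lt(abs(raw[["pctChangeApposition"]] - 15), 6)
  expect_gt(raw[["foldPartialDenervation"]], 1.3)
  expect_true(all(c("pctChangePreVolume", "foldPartialDenervation") %in%
                    rep@verdicts$target))
})

test_that("a null study shows no systematic effects", {
  veh <- defaultStudyConfig(seed = 1L)@groups[[1]]
  sham <- veh; slot(sham, "label") <- "sham"
  cfg <- new("StudyConfig", groups = list(veh, sham), seed = 311L,
             mode = "fast", measure = measureConfig(),
             targets = list())
  rep <- runStudy(cfg)
  raw <- rawEffects(rep@effects)
  expect_lt(abs(raw[["pctChangePreVolume"]]), 8)
  expect_lt(abs(raw[["pctChangeApposition"]]), 8)
  # NMJ-level p-values are anti-conservative under the nested variance
  # model (pseudo-replication, a documented fidelity choice), so only
  # the animal-level effect magnitudes are bounded here
  expect_gt(rep@stats$endplate_volume@table$p.value[1], 0.01)
})

test_that("replication runs are deterministic given the seed", {
  r1 <- runStudy(defaultStudyConfig(seed = 55L))
  r2 <- runStudy(defaultStudyConfig(seed = 55L))
  expect_identical(rawEffects(r1@effects), rawEffects(r2@effects))
  expect_identical(r1@measurements, r2@measurements)
})

test_that("a reduced-scale image-mode study completes and agrees with fast mode", {
  grp <- function(base) {
    g <- base
    slot(g, "nAnimals") <- 2L
    slot(g, "nmjPerAnimalMean") <- 6
    slot(g, "nmjPerAnimalSD") <- 0
    slot(g, "nmjMin") <- 6L
    g
  }
  base <- defaultStudyConfig(seed = 77L)
  cfg <- new("StudyConfig",
             groups = lapply(base@groups, grp),
             seed = 77L, mode = "image", measure = measureConfig(),
             targets = base@targets)
  rep <- suppressWarnings(runStudy(cfg,
                                   renderArgs = list(dims = c(160L, 192L,
                                                              18L))))
  expect_identical(nrow(rep@measurements), 24L)
  expect_true(all(c("pre_volume", "apposition") %in% names(rep@stats)))
  expect_identical(nrow(rep@verdicts), length(base@targets))
  # image-mode group means agree with the fast-mode generator table
  fastM <- generateCohort(cfg, mode = "fast")@measurements
  for (lab in c("vehicle", "chloroquine")) {
    img <- rep@measurements[rep@measurements$treatment == lab &
                              rep@measurements$valid, ]
    fst <- fastM[fastM$treatment == lab, ]
    expect_lt(abs(mean(img$pre_volume) / mean(fst$pre_volume) - 1), 0.10)
    expect_lt(abs(mean(img$endplate_volume) /
                    mean(fst$endplate_volume) - 1), 0.10)
    expect_lt(abs(mean(img$apposition_pct) - mean(fst$apposition_pct)), 6)
  }
})

test_that("study configurations load from YAML", {
  path <- tempfile(fileext = ".yaml")
  writeLines(c(
    "seed: 9",
    "mode: fast",
    "groups:",
    "  vehicle:",
    "    preVolumeMean: 1500",
    "    nAnimals: 4",
    "  chloroquine:",
    "    preVolumeMean: 1300"), path)
  cfg <- readStudyConfig(path)
  expect_identical(cfg@seed, 9L)
  expect_equal(cfg@groups[[1]]@preVolumeMean, 1500)
  expect_identical(cfg@groups[[1]]@nAnimals, 4L)
  expect_equal(cfg@groups[[2]]@preVolumeMean, 1300)
  # untouched fields keep the shipped calibration
  expect_equal(cfg@groups[[2]]@appositionMean, 56)
})

test_that("the shipped calibration file matches the built-in defaults", {
  path <- system.file("extdata", "study_calibration.yaml",
                      package = "nmjMorph")
  expect_true(nzchar(path))
  cfg <- readStudyConfig(path)
  ref <- defaultStudyConfig()
  for (i in 1:2)
    for (sl in c("preVolumeMean", "preVolumeSD", "endplateVolumeMean",
                 "appositionMean", "rpaMean", "categoryProbs"))
      expect_equal(slot(cfg@groups[[i]], sl), slot(ref@groups[[i]], sl))
})

test_that("reports serialize to JSON", {
  rep <- runStudy(defaultStudyConfig(seed = 13L))
  path <- tempfile(fileext = ".json")
  writeReport(rep, path)
  back <- jsonlite::read_json(path, simplifyVector = TRUE)
  expect_true(all(c("analyses", "effect_sizes", "verdicts") %in%
                    names(back)))
  expect_equal(back$effect_sizes$raw$pctChangePreVolume,
               unname(rawEffects(rep@effects)["pctChangePreVolume"]))
})
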