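# End-to-end orchestration: cohort generation, per-animal aggregation,
# the statistical battery, effect sizes, and replication verdicts.

#' Default two-arm study configuration
#'
#' The shipped calibration reproduces the published study conditions:
#' 6 animals per arm (equal males and females), about 40 +/- 11 en face
#' NMJs per animal with a floor of 35, vehicle NMJ moments of
#' 1411 +/- 236 um^3 pre-synaptic and 1792 +/- 259 um^3 end-plate volume,
#' 66 +/- 11 percent apposition and 45 +/- 8 percent relative planar
#' area with a (0.93, 0.07, 0) denervation mixture, and chloroquine
#' moments of 1248 +/- 274 and 1804 +/- 269 um^3, 56 +/- 10 percent,
#' 43 +/- 7 percent with a (0.78, 0.19, 0.03) mixture. Target brackets
#' for the replication verdicts cover the derived effect sizes.
#'
#' @param seed master seed.
#' @param mode \code{"fast"} or \code{"image"}.
#' @param nAnimals animals per group; the image mode is typically run at
#'   reduced scale (see \code{nmjPerAnimalMean}).
#' @param nmjPerAnimalMean,nmjPerAnimalSD,nmjMin per-animal NMJ count
#'   distribution.
#' @return A [StudyConfig-class].
#' @export
defaultStudyConfig <- function(seed = 1L, mode = c("fast", "image"),
                               nAnimals = 6L,
                               nmjPerAnimalMean = 40,
                               nmjPerAnimalSD = 11, nmjMin = 35L) {
  mode <- match.arg(mode)
  vehicle <- GroupConfig("vehicle", nAnimals = nAnimals,
    nmjPerAnimalMean = nmjPerAnimalMean, nmjPerAnimalSD = nmjPerAnimalSD,
    nmjMin = nmjMin,
    endplateVolumeMean = 1792, endplateVolumeSD = 259,
    preVolumeMean = 1411, preVolumeSD = 236,
    appositionMean = 66, appositionSD = 11,
    rpaMean = 45, rpaSD = 8,
    categoryProbs = c(0.93, 0.07, 0),
    bodyMass = c(maleMean = 33.3, maleSD = 2.9,
                 femaleMean = 22.6, femaleSD = 1.2,
                 changeMean = 0.5, changeSD = 1.2))
  chloroquine <- GroupConfig("chloroquine", nAnimals = nAnimals,
    nmjPerAnimalMean = nmjPerAnimalMean, nmjPerAnimalSD = nmjPerAnimalSD,
    nmjMin = nmjMin,
    endplateVolumeMean = 1804, endplateVolumeSD = 269,
    preVolumeMean = 1248, preVolumeSD = 274,
    appositionMean = 56, appositionSD = 10,
    rpaMean = 43, rpaSD = 7,
    categoryProbs = c(0.78, 0.19, 0.03),
    bodyMass = c(maleMean = 30.8, maleSD = 3.4,
                 femaleMean = 22.8, femaleSD = 2.1,
                 changeMean = -0.2, changeSD = 1.2))
  targets <- list(
    pctChangePreVolume = list(expected = 12, tol = 5),
    pctChangeApposition = list(expected = 15, tol = 5),
    pctChangeInnervated = list(expected = 16, tol = 8),
    foldPartialDenervation = list(expected = 2.7, tol = 1.2),
    pctMassSexDifference = list(expected = 41, tol = 10))
  new("StudyConfig", groups = list(vehicle, chloroquine),
      seed = as.integer(seed), mode = mode, measure = measureConfig(),
      targets = targets)
}

#' Read a study configuration from YAML
#'
#' The YAML mirrors the [GroupConfig-class] fields per group plus
#' top-level \code{seed}, \code{mode} and optional \code{targets}; any
#' field left out keeps its default. See
#' \code{system.file("extdata", "study_calibration.yaml",
#' package = "nmjMorph")} for the shipped calibration.
#'
#' @param path YAML file path.
#' @return A [StudyConfig-class].
#' @export
readStudyConfig <- function(path) {
  y <- yaml::read_yaml(path)
  base <- defaultStudyConfig(seed = if (!is.null(y$seed)) y$seed else 1L,
                             mode = if (!is.null(y$mode)) y$mode else "fast")
  groups <- base@groups
  for (i in 1:2) {
    lab <- groups[[i]]@label
    g <- y$groups[[lab]]
    if (is.null(g)) next
    for (fld in names(g)) {
      if (!fld %in% slotNames("GroupConfig")) next
      val <- g[[fld]]
      if (fld %in% c("categoryProbs", "bodyMass")) val <- unlist(val)
      if (fld == "bodyMass" && !is.null(names(val)))
        val <- val[c("maleMean", "maleSD", "femaleMean", "femaleSD",
                     "changeMean", "changeSD")]
      slot(groups[[i]], fld) <-
        if (is(slot(groups[[i]], fld), "integer")) as.integer(val)
        else if (fld == "label") as.character(val)
        else if (fld == "bodyMass") vapply(val, as.numeric, numeric(1))
        else as.numeric(unname(val))
    }
    validObject(groups[[i]])
  }
  tg <- base@targets
  if (!is.null(y$targets)) tg <- y$targets
  new("StudyConfig", groups = groups, seed = base@seed, mode = base@mode,
      measure = base@measure, targets = tg)
}

#' Generate a synthetic cohort
#'
#' Animals are assigned sexes alternately within each group; each
#' animal's NMJ count is drawn from the configured count distribution
#' with the study's floor of 35 en face NMJs; per-NMJ parameters come
#' from [sampleNMJParams()] under the nested variance model (a
#' between-animal random effect plus within-animal noise). In fast mode
#' the drawn parameters are emitted directly as measurements; in image
#' mode each NMJ is additionally rendered via [renderNMJStack()] with
#' the drawn parameters as targets. The parameter draws are identical
#' across modes at matched seeds.
#'
#' @param study a [StudyConfig-class].
#' @param seed master seed (defaults to the config's).
#' @param mode \code{"fast"} or \code{"image"} (defaults to the
#'   config's).
#' @param renderArgs list of extra arguments for [renderNMJStack()] in
#'   image mode (e.g. reduced \code{dims}).
#' @return An [NMJCohort-class].
#' @export
generateCohort <- function(study, seed = study@seed, mode = study@mode,
                           renderArgs = list()) {
  stopifnot(is(study, "StudyConfig"))
  validObject(study)
  animals <- list(); rows <- list(); stacks <- list()
  nmjCounter <- 0L
  for (gi in seq_along(study@groups)) {
    grp <- study@groups[[gi]]
    for (ai in seq_len(grp@nAnimals)) {
      aSeed <- deriveSeed(seed, gi * 1000L + ai)
      sex <- if (ai %% 2L == 1L) "M" else "F"
      ainfo <- withSeed(aSeed, {
        massPre <- if (sex == "M")
          rtruncnorm(1, grp@bodyMass[["maleMean"]], grp@bodyMass[["maleSD"]])
        else rtruncnorm(1, grp@bodyMass[["femaleMean"]],
                        grp@bodyMass[["femaleSD"]])
        massPost <- massPre + rnorm(1, grp@bodyMass[["changeMean"]],
                                    grp@bodyMass[["changeSD"]])
        nNMJ <- max(grp@nmjMin,
                    as.integer(round(rnorm(1, grp@nmjPerAnimalMean,
                                           grp@nmjPerAnimalSD))))
        f <- grp@animalEffectFraction
        shift <- c(pre = rnorm(1, 0, f * grp@preVolumeSD),
                   endplate = rnorm(1, 0, f * grp@endplateVolumeSD),
                   apposition = rnorm(1, 0, f * grp@appositionSD))
        rpaShift <- rnorm(1, 0, f * grp@rpaSD)
        age <- round(runif(1, 5, 8), 1)
        list(massPre = massPre, massPost = massPost, nNMJ = nNMJ,
             shift = shift, rpaShift = rpaShift, age = age)
      })
      animalId <- sprintf("%s_%02d", grp@label, ai)
      animals[[animalId]] <- data.frame(
        animal_id = animalId, sex = sex, treatment = grp@label,
        age_months = ainfo$age,
        body_mass_pre = ainfo$massPre, body_mass_post = ainfo$massPost,
        n_nmj = ainfo$nNMJ, stringsAsFactors = FALSE)
      for (ni in seq_len(ainfo$nNMJ)) {
        nmjCounter <- nmjCounter + 1L
        nSeed <- deriveSeed(aSeed, ni)
        params <- sampleNMJParams(grp, nSeed, animalShift = ainfo$shift)
        rpa <- withSeed(deriveSeed(nSeed, 7L), {
          f <- grp@animalEffectFraction
          min(100, max(5, rnorm(1, grp@rpaMean + ainfo$rpaShift,
                                grp@rpaSD * sqrt(1 - f^2))))
        })
        axes <- withSeed(deriveSeed(nSeed, 8L), rtruncnorm(1, 950, 180))
        nmjId <- sprintf("%s_nmj%03d", animalId, ni)
        rows[[nmjCounter]] <- data.frame(
          animal_id = animalId, sex = sex, treatment = grp@label,
          nmj_id = nmjId,
          pre_volume = params@targetPreVolume,
          endplate_volume = params@targetEndplateVolume,
          planar_area = rpa / 100 * axes, axes_area = axes,
          relative_planar_area = rpa,
          apposition_pct = 100 * params@targetApposition,
          category = params@category, valid = TRUE,
          stringsAsFactors = FALSE)
        if (mode == "image") {
          rend <- do.call(renderNMJStack, c(list(params = params),
                                            renderArgs))
          stacks[[nmjId]] <- list(nmj_id = nmjId, animal_id = animalId,
                                  stack = rend$stack, truth = rend$truth)
        }
      }
    }
  }
  new("NMJCohort", animals = do.call(rbind, c(animals,
                                              make.row.names = FALSE)),
      measurements = do.call(rbind, c(rows, make.row.names = FALSE)),
      stacks = stacks, mode = mode)
}

#' Aggregate per-NMJ measurements per animal
#'
#' Per-animal means of each morphometric and the per-animal proportions
#' of the three denervation categories (always summing to 1). Animals
#' with no valid NMJ are excluded with a warning.
#'
#' @param measurements per-NMJ table with \code{animal_id},
#'   \code{treatment}, the morphometrics, \code{category}, and a
#'   \code{valid} flag (absent means all valid).
#' @return data.frame with one row per animal.
#' @export
aggregateByAnimal <- function(measurements) {
  stopifnot(is.data.frame(measurements))
  m <- measurements
  if (!is.null(m$valid)) m <- m[m$valid %in% TRUE, , drop = FALSE]
  dropped <- setdiff(unique(measurements$animal_id), unique(m$animal_id))
  if (length(dropped))
    warning("excluding animals with no valid NMJ: ",
            paste(dropped, collapse = ", "))
  if (!nrow(m)) stop("no valid NMJ records to aggregate")
  sp <- split(m, m$animal_id)
  out <- lapply(sp, function(d) {
    props <- vapply(CATEGORIES,
                    function(cc) mean(d$category == cc), numeric(1))
    data.frame(animal_id = d$animal_id[1L],
               treatment = d$treatment[1L],
               sex = if (!is.null(d$sex)) d$sex[1L] else NA_character_,
               n_nmj = nrow(d),
               pre_volume = mean(d$pre_volume),
               endplate_volume = mean(d$endplate_volume),
               relative_planar_area = mean(d$relative_planar_area,
                                           na.rm = TRUE),
               apposition_pct = mean(d$apposition_pct),
               prop_innervated = props[[1L]],
               prop_partially_denervated = props[[2L]],
               prop_fully_denervated = props[[3L]],
               stringsAsFactors = FALSE)
  })
  do.call(rbind, c(out, make.row.names = FALSE))
}

#' Run the full study and build a replication report
#'
#' Generates (fast mode) or renders and measures (image mode) a
#' two-arm cohort, aggregates per animal, runs the statistical battery
#' (one-way treatment ANOVAs on the per-NMJ morphometrics, the two-way
#' treatment x category ANOVA on per-animal proportions, the chi-square
#' test on category counts, matched-pairs body-mass t-tests per group,
#' the sex effect on body mass, and category ANOVAs of end-plate volume
#' and relative planar area within each treatment), derives the effect
#' sizes, and checks them against the configured target brackets.
#'
#' @param config a [StudyConfig-class].
#' @param seed master seed (defaults to the config's).
#' @param renderArgs image-mode rendering arguments (see
#'   [generateCohort()]).
#' @return A [ReplicationReport-class].
#' @export
runStudy <- function(config = defaultStudyConfig(), seed = config@seed,
                     renderArgs = list()) {
  cohort <- generateCohort(config, seed = seed, renderArgs = renderArgs)
  labs <- vapply(config@groups, slot, character(1), "label")
  if (cohort@mode == "image") {
    meas <- lapply(cohort@stacks, function(s) {
      rec <- suppressMessages(measureNMJ(s$stack, config@measure,
                                         nmj_id = s$nmj_id))
      rec$animal_id <- s$animal_id
      rec
    })
    meas <- do.call(rbind, c(meas, make.row.names = FALSE))
    meta <- cohort@animals[, c("animal_id", "sex", "treatment")]
    measurements <- merge(meas, meta, by = "animal_id", sort = FALSE)
  } else {
    measurements <- cohort@measurements
  }
  measurements$treatment <- factor(measurements$treatment, levels = labs)
  valid <- if (!is.null(measurements$valid))
    measurements[measurements$valid %in% TRUE, , drop = FALSE]
  else measurements

  stats <- list()
  stats$pre_volume <- oneWayAnova(valid$pre_volume, valid$treatment)
  stats$endplate_volume <- oneWayAnova(valid$endplate_volume,
                                       valid$treatment)
  ok <- is.finite(valid$relative_planar_area)
  stats$relative_planar_area <- oneWayAnova(valid$relative_planar_area[ok],
                                            valid$treatment[ok])
  stats$apposition <- oneWayAnova(valid$apposition_pct, valid$treatment)

  perAnimal <- aggregateByAnimal(measurements)
  propLong <- do.call(rbind, lapply(CATEGORIES, function(cc) {
    data.frame(animal_id = perAnimal$animal_id,
               treatment = perAnimal$treatment,
               category = cc,
               prop = perAnimal[[paste0("prop_", cc)]],
               stringsAsFactors = FALSE)
  }))
  stats$category_proportions <- twoWayAnova(propLong$prop,
                                            propLong$treatment,
                                            propLong$category)
  counts <- table(valid$treatment, factor(valid$category,
                                          levels = CATEGORIES))
  counts <- counts[, colSums(counts) > 0, drop = FALSE]
  stats$category_counts <- chiSquareIndependence(unclass(counts))

  # within-treatment category effects on end-plate size and complexity
  for (lab in labs) {
    d <- valid[valid$treatment == lab, , drop = FALSE]
    tb <- table(d$category)
    cats <- names(tb)[tb >= 2L]
    if (length(cats) >= 2L) {
      dd <- d[d$category %in% cats, , drop = FALSE]
      stats[[paste0("endplate_by_category_", lab)]] <-
        oneWayAnova(dd$endplate_volume, dd$category)
      ok2 <- is.finite(dd$relative_planar_area)
      stats[[paste0("rpa_by_category_", lab)]] <-
        oneWayAnova(dd$relative_planar_area[ok2], dd$category[ok2])
    }
  }

  an <- cohort@animals
  for (lab in labs) {
    d <- an[an$treatment == lab, , drop = FALSE]
    stats[[paste0("body_mass_", lab)]] <-
      pairedTTest(d$body_mass_pre, d$body_mass_post)
  }
  stats$body_mass_sex <- oneWayAnova(an$body_mass_pre, an$sex)

  smry <- function(lab) {
    d <- valid[valid$treatment == lab, , drop = FALSE]
    pa <- perAnimal[perAnimal$treatment == lab, , drop = FALSE]
    list(preVolume = mean(d$pre_volume),
         apposition = mean(d$apposition_pct),
         innervatedPct = 100 * mean(pa$prop_innervated),
         partialPct = 100 * mean(pa$prop_partially_denervated))
  }
  effects <- effectSizes(smry(labs[1L]), smry(labs[2L]),
                         maleMass = mean(an$body_mass_pre[an$sex == "M"]),
                         femaleMass = mean(an$body_mass_pre[an$sex == "F"]))

  verdicts <- data.frame(target = character(0), value = numeric(0),
                         expected = numeric(0), tol = numeric(0),
                         pass = logical(0), stringsAsFactors = FALSE)
  for (nm in names(config@targets)) {
    tgt <- config@targets[[nm]]
    val <- if (nm %in% names(effects@raw)) unname(effects@raw[[nm]])
    else NA_real_
    verdicts <- rbind(verdicts, data.frame(
      target = nm, value = val, expected = tgt$expected, tol = tgt$tol,
      pass = is.finite(val) && abs(val - tgt$expected) <= tgt$tol,
      stringsAsFactors = FALSE))
  }

  new("ReplicationReport",
      measurements = measurements, perAnimal = perAnimal,
      animals = cohort@animals, stats = stats, effects = effects,
      verdicts = verdicts)
}

#' Write a replication report to JSON
#'
#' @param report a [ReplicationReport-class].
#' @param path output JSON path.
#' @return \code{path}, invisibly.
#' @export
writeReport <- function(report, path) {
  stopifnot(is(report, "ReplicationReport"))
  out <- list(
    analyses = lapply(report@stats, function(s)
      list(statistic = s@statisticName, table = s@table,
           group_summaries = s@groupSummaries)),
    effect_sizes = list(raw = as.list(report@effects@raw),
                        reported = report@effects@reported),
    per_animal = report@perAnimal,
    verdicts = report@verdicts)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows")
  invisible(path)
}
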