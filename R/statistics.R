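# The study's statistical battery over NMJ- and animal-level tables.
# Model fitting is delegated to stats::lm/aov/t.test/chisq.test/TukeyHSD
# and car::Anova; this module owns the contracts, degenerate-case
# handling, and the derived effect sizes.

#' One-way ANOVA with a single fixed effect
#'
#' Standard between/within sum-of-squares decomposition: F with
#' (k - 1, N - k) degrees of freedom. When every group has zero
#' within-group variance but means differ, F is infinite and p = 0.
#'
#' @param values numeric response (e.g. per-NMJ pre-synaptic volumes).
#' @param groups group labels (e.g. treatment), >= 2 groups with >= 2
#'   values each.
#' @return A [StatsResult-class] with terms \code{groups} and
#'   \code{Residuals} (the \code{ss} column carries the decomposition)
#'   and per-group summaries.
#' @examples
#' oneWayAnova(c(1, 2, 3, 4, 5, 6), rep(c("a", "b"), each = 3))
#' @export
oneWayAnova <- function(values, groups) {
  groups <- as.factor(groups)
  if (nlevels(groups) < 2L) stop("need >= 2 groups")
  if (any(table(groups) < 2L)) stop("each group needs >= 2 values")
  if (any(!is.finite(values))) stop("values must be finite")
  fit <- lm(values ~ groups)
  # anova() warns on an essentially perfect fit; that degenerate case is
  # handled explicitly below
  an <- suppressWarnings(anova(fit))
  ssb <- an$`Sum Sq`[1L]; ssw <- an$`Sum Sq`[2L]
  df1 <- an$Df[1L]; df2 <- an$Df[2L]
  if (ssw <= 1e-12 * max(ssb, 1)) {
    fstat <- if (ssb > 0) Inf else 0
    p <- if (ssb > 0) 0 else 1
  } else {
    fstat <- an$`F value`[1L]
    p <- an$`Pr(>F)`[1L]
  }
  tab <- data.frame(term = c("groups", "Residuals"),
                    ss = c(ssb, ssw),
                    statistic = c(fstat, NA_real_),
                    df1 = c(df1, df2), df2 = c(df2, NA_real_),
                    p.value = c(p, NA_real_), stringsAsFactors = FALSE)
  .statsResult("F", tab, groupSummaryTable(values, groups))
}

#' Two-way ANOVA with interaction (Type-II sums of squares)
#'
#' Fixed-effects two-factor ANOVA used for the per-animal denervation
#' category proportions (treatment x category). Type-II sums of squares
#' accommodate the unbalanced per-animal table. If any cell of the
#' layout is empty, the interaction is omitted with a warning.
#'
#' @param response numeric response.
#' @param factorA,factorB factor labels.
#' @return A [StatsResult-class] with one row per term (A, B, and A:B
#'   when estimable).
#' @export
twoWayAnova <- function(response, factorA, factorB) {
  A <- as.factor(factorA); B <- as.factor(factorB)
  if (nlevels(A) < 2L || nlevels(B) < 2L)
    stop("both factors need >= 2 levels")
  cells <- table(A, B)
  withInteraction <- all(cells > 0L)
  if (!withInteraction)
    warning("empty cells in the two-factor layout; interaction omitted")
  dat <- data.frame(y = response, A = A, B = B)
  form <- if (withInteraction) y ~ A * B else y ~ A + B
  fit <- lm(form, data = dat)
  resVar <- sum(fit$residuals^2)
  if (resVar <= 1e-12 * max(sum((response - mean(response))^2), 1)) {
    # constant response (or exact fit): no variance to test
    terms <- c("A", "B", if (withInteraction) "A:B")
    tab <- data.frame(term = terms, ss = 0,
                      statistic = 0, df1 = NA_real_, df2 = NA_real_,
                      p.value = 1, stringsAsFactors = FALSE)
    if (sum((response - mean(response))^2) > 1e-12) {
      an <- suppressWarnings(car::Anova(fit, type = 2))
      ss <- an$`Sum Sq`
      tab$ss <- ss[seq_along(terms)]
      tab$statistic <- ifelse(tab$ss > 1e-12, Inf, 0)
      tab$p.value <- ifelse(tab$ss > 1e-12, 0, 1)
    }
    return(.statsResult("F", tab))
  }
  an <- car::Anova(fit, type = 2)
  rn <- rownames(an)
  keep <- rn != "Residuals"
  dfRes <- an$Df[rn == "Residuals"]
  tab <- data.frame(term = rn[keep], ss = an$`Sum Sq`[keep],
                    statistic = an$`F value`[keep],
                    df1 = an$Df[keep], df2 = dfRes,
                    p.value = an$`Pr(>F)`[keep], stringsAsFactors = FALSE)
  .statsResult("F", tab)
}

#' Pearson chi-square test of independence
#'
#' Pearson statistic sum (O - E)^2 / E over a treatment x category count
#' table, df = (r - 1)(c - 1), without continuity correction.
#'
#' @param counts matrix of nonnegative integer counts with positive row
#'   and column sums.
#' @return A [StatsResult-class].
#' @examples
#' chiSquareIndependence(rbind(c(50, 50), c(25, 75)))
#' @export
chiSquareIndependence <- function(counts) {
  counts <- as.matrix(counts)
  if (any(counts < 0) || any(counts != round(counts)))
    stop("counts must be nonnegative integers")
  rs <- rowSums(counts); cs <- colSums(counts)
  if (any(rs == 0))
    stop("degenerate margin: row ", which(rs == 0)[1L], " has zero total")
  if (any(cs == 0))
    stop("degenerate margin: column ", which(cs == 0)[1L],
         " has zero total (expected count 0)")
  ct <- suppressWarnings(chisq.test(counts, correct = FALSE))
  tab <- data.frame(term = "independence",
                    ss = NA_real_,
                    statistic = unname(ct$statistic),
                    df1 = unname(ct$parameter), df2 = NA_real_,
                    p.value = ct$p.value, stringsAsFactors = FALSE)
  .statsResult("X-squared", tab)
}

#' Tukey--Kramer honestly significant difference test
#'
#' Studentized-range-based pairwise comparisons after a one-way ANOVA,
#' with the Kramer correction for unequal group sizes.
#'
#' @param values,groups as in [oneWayAnova()].
#' @return data.frame with one row per pair: \code{pair}, \code{diff},
#'   \code{lwr}, \code{upr}, \code{p.adj}; empty for a single group.
#' @export
tukeyKramer <- function(values, groups) {
  groups <- as.factor(groups)
  if (nlevels(groups) < 2L)
    return(data.frame(pair = character(0), diff = numeric(0),
                      lwr = numeric(0), upr = numeric(0),
                      p.adj = numeric(0)))
  fit <- aov(values ~ groups)
  tk <- TukeyHSD(fit)$groups
  data.frame(pair = rownames(tk), diff = tk[, "diff"],
             lwr = tk[, "lwr"], upr = tk[, "upr"],
             p.adj = tk[, "p adj"], row.names = NULL,
             stringsAsFactors = FALSE)
}

#' Matched-pairs t-test
#'
#' t statistic on the paired differences (pre - post), df = n - 1,
#' two-sided p. Zero-variance differences give t = 0 (all-zero
#' differences) or an infinite-t flag.
#'
#' @param pre,post paired numeric vectors of equal length >= 2 (e.g.
#'   pre- and post-treatment body masses).
#' @return A [StatsResult-class].
#' @export
pairedTTest <- function(pre, post) {
  if (length(pre) != length(post)) stop("pre and post must pair up")
  if (length(pre) < 2L) stop("need >= 2 pairs")
  d <- pre - post
  n <- length(d)
  if (sd(d) == 0) {
    tstat <- if (mean(d) == 0) 0 else Inf * sign(mean(d))
    p <- if (mean(d) == 0) 1 else 0
  } else {
    tt <- t.test(pre, post, paired = TRUE)
    tstat <- unname(tt$statistic)
    p <- tt$p.value
  }
  tab <- data.frame(term = "pre - post", ss = NA_real_, statistic = tstat,
                    df1 = n - 1, df2 = NA_real_, p.value = p,
                    stringsAsFactors = FALSE)
  .statsResult("t", tab,
               data.frame(group = c("pre", "post"), n = n,
                          mean = c(mean(pre), mean(post)),
                          sd = c(sd(pre), sd(post))))
}

#' Derived between-group effect sizes
#'
#' Percent changes are computed relative to the vehicle group,
#' 100 x (vehicle - chloroquine) / vehicle, the partial-denervation
#' effect as the chloroquine / vehicle fold change of the group
#' proportion, and (when masses are supplied) the male/female body-mass
#' difference as 100 x (male - female) / female. Reported values are
#' rounded to the conventional printed precision (integer percentages,
#' one-decimal fold change).
#'
#' @param vehicle,chloroquine named lists (or vectors) of group
#'   summaries with elements \code{preVolume} (um^3), \code{apposition}
#'   (percent), \code{innervatedPct} and \code{partialPct} (percent of
#'   NMJs per category).
#' @param maleMass,femaleMass optional mean body masses (g) across
#'   treatment groups.
#' @return An [EffectSizes-class] object.
#' @examples
#' es <- effectSizes(
#'   vehicle = list(preVolume = 1411, apposition = 66,
#'                  innervatedPct = 93, partialPct = 7),
#'   chloroquine = list(preVolume = 1248, apposition = 56,
#'                      innervatedPct = 78, partialPct = 19))
#' reportedEffects(es)
#' @export
effectSizes <- function(vehicle, chloroquine,
                        maleMass = NULL, femaleMass = NULL) {
  v <- as.list(vehicle); c2 <- as.list(chloroquine)
  need <- c("preVolume", "apposition", "innervatedPct", "partialPct")
  if (!all(need %in% names(v)) || !all(need %in% names(c2)))
    stop("group summaries need ", paste(need, collapse = ", "))
  pct <- function(a, b) {
    if (!is.finite(a) || a == 0) {
      warning("vehicle mean is zero; percent change undefined")
      return(NA_real_)
    }
    100 * (a - b) / a
  }
  raw <- c(pctChangePreVolume = pct(v$preVolume, c2$preVolume),
           pctChangeApposition = pct(v$apposition, c2$apposition),
           pctChangeInnervated = pct(v$innervatedPct, c2$innervatedPct),
           foldPartialDenervation =
             if (v$partialPct > 0) c2$partialPct / v$partialPct
             else NA_real_)
  if (!is.null(maleMass) && !is.null(femaleMass))
    raw["pctMassSexDifference"] <- 100 * (maleMass - femaleMass) / femaleMass
  reported <- lapply(seq_along(raw), function(i) {
    if (names(raw)[i] == "foldPartialDenervation") round(raw[[i]], 1)
    else round(raw[[i]])
  })
  names(reported) <- names(raw)
  new("EffectSizes", raw = raw, reported = reported)
}

#' @rdname effectSizes
#' @param object an [EffectSizes-class] object.
#' @return \code{reportedEffects}: named list of rounded effect sizes.
#' @export
reportedEffects <- function(object) {
  stopifnot(is(object, "EffectSizes"))
  object@reported
}

#' @rdname effectSizes
#' @export
rawEffects <- function(object) {
  stopifnot(is(object, "EffectSizes"))
  object@raw
}

#' Monte-Carlo power of the animal-level treatment comparison
#'
#' Simulates the nested variance model (between-animal random effect
#' plus within-animal NMJ noise averaged over the per-animal sample),
#' applies [oneWayAnova()] to per-animal means, and reports the fraction
#' of replicates with p below \code{alpha}. Used to check that the
#' design's animals-per-group suffices for a 15--20 percent treatment
#' effect.
#'
#' @param effectPct percent reduction of the treated group mean.
#' @param nPerGroup animals per group.
#' @param profile named numeric: \code{mean} (control group mean),
#'   \code{sd} (total per-NMJ SD), \code{animalFraction} (fraction of
#'   \code{sd} that is between-animal), \code{nmjPerAnimal}.
#' @param alpha significance level.
#' @param reps Monte-Carlo replicates (>= 200 for a stable estimate).
#' @param seed RNG seed.
#' @return Achieved power (proportion in [0, 1]).
#' @export
powerCheck <- function(effectPct, nPerGroup = 4L,
                       profile = c(mean = 1411, sd = 236,
                                   animalFraction = 0.4,
                                   nmjPerAnimal = 40),
                       alpha = 0.05, reps = 500L, seed = 1L) {
  if (effectPct < 0) stop("effectPct must be >= 0")
  sdA <- profile[["sd"]] * profile[["animalFraction"]]
  sdW <- sqrt(profile[["sd"]]^2 - sdA^2)
  sdAnimalMean <- sqrt(sdA^2 + sdW^2 / profile[["nmjPerAnimal"]])
  mu <- c(profile[["mean"]], profile[["mean"]] * (1 - effectPct / 100))
  g <- rep(c("g1", "g2"), each = nPerGroup)
  withSeed(seed, {
    hits <- vapply(seq_len(reps), function(i) {
      y <- rnorm(2L * nPerGroup, mean = rep(mu, each = nPerGroup),
                 sd = sdAnimalMean)
      res <- oneWayAnova(y, g)
      res@table$p.value[1L] < alpha
    }, logical(1))
    mean(hits)
  })
}
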