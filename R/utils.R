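# Internal helpers shared across modules.

# Evaluate expr under a fixed RNG seed, restoring the caller's RNG state.
withSeed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(if (exists(".Random.seed", envir = globalenv(),
                       inherits = FALSE))
      rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(as.integer(seed))
  expr
}

# Truncated-normal draws by rejection; lower bound only. sd = 0 collapses
# to the mean (which must satisfy the bound).
rtruncnorm <- function(n, mean, sd, lower = 0) {
  if (sd == 0) {
    if (any(mean <= lower)) stop("degenerate draw below truncation bound")
    return(rep(mean, length.out = n))
  }
  out <- rnorm(n, mean, sd)
  bad <- which(out <= lower)
  guard <- 0L
  while (length(bad)) {
    out[bad] <- rnorm(length(bad), mean, sd)
    bad <- bad[out[bad] <= lower]
    guard <- guard + 1L
    if (guard > 1000L) stop("truncated-normal rejection failed; ",
                            "check that mean lies well above the bound")
  }
  out
}

# Derive a per-unit 31-bit seed from a master seed and an index.
deriveSeed <- function(seed, index) {
  as.integer((as.numeric(seed) * 48271 + as.numeric(index) * 16807) %%
             2147483647)
}

# Group summaries used in StatsResult objects.
groupSummaryTable <- function(values, groups) {
  groups <- as.factor(groups)
  data.frame(
    group = levels(groups),
    n = as.integer(tapply(values, groups, length)),
    mean = as.numeric(tapply(values, groups, mean)),
    sd = as.numeric(tapply(values, groups, sd)),
    row.names = NULL)
}
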