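## Independent brute-force oracles used across the suite. These deliberately
## avoid the package's own code paths (plain O(n^2) loops, exhaustive
## searches) so that oracle-equality tests mean something.

## O(n^2) pair counting on full distance matrices (boundary inclusive)
bruteCountCross <- function(ref, tgt, r) {
  if (nrow(ref) == 0 || nrow(tgt) == 0) return(0)
  d <- sqrt(outer(ref[, 1], tgt[, 1], "-")^2 + outer(ref[, 2], tgt[, 2], "-")^2)
  as.numeric(sum(d <= r))
}

bruteCountSelf <- function(pts, r) {
  if (nrow(pts) < 2) return(0)
  d <- as.matrix(stats::dist(pts))
  as.numeric(sum(d[upper.tri(d)] <= r))
}

## Exhaustive Otsu: every histogram split point, weighted intra-class
## variance computed directly on the binned values
bruteOtsu <- function(x, nBins = 256) {
  rng <- range(x)
  breaks <- seq(rng[1], rng[2], length.out = nBins + 1)
  bin <- findInterval(x, breaks, rightmost.closed = TRUE)
  mid <- (breaks[-1] + breaks[-(nBins + 1)]) / 2
  v <- mid[bin]  # values collapsed to their bin midpoint
  ssd <- function(w) sum((w - mean(w))^2)
  best <- Inf; bestT <- NA
  for (t in seq_len(nBins - 1)) {
    lo <- v[bin <= t]; hi <- v[bin > t]
    if (!length(lo) || !length(hi)) next
    wv <- (ssd(lo) + ssd(hi)) / length(x)
    if (wv < best - 1e-12) { best <- wv; bestT <- t }
  }
  breaks[bestT + 1]
}

## Brute-force kneedle search over every eligible ECDF point (the lower
## region, where a knee separating few low outliers from the mass must sit)
bruteKnee <- function(x, maxHeight = 0.3) {
  x <- sort(x)
  n <- length(x)
  F <- seq_len(n) / n
  u <- (x - x[1]) / (x[n] - x[1])
  d <- vapply(seq_len(n), function(i) {
    abs(F[i] - F[1] - (1 - F[1]) * u[i]) / sqrt(1 + (1 - F[1])^2)
  }, 0)
  elig <- which(F <= maxHeight)
  best <- elig[which.max(d[elig])]
  list(index = best, score = d[best], x = x)
}

## Nested-if reference implementation of the default phenotyping rules
ruleOracle <- function(ck, cd68, foxp3, cd8, cd4) {
  if (ck) "tumor"
  else if (cd68) "macrophage"
  else if (foxp3) "t_regulatory"
  else if (cd8) "cytotoxic_t"
  else if (cd4) "t_helper"
  else "other"
}

## Small, fast simulation config for generator-heavy tests
quickConfig <- function(..., seed = 1L) {
  simConfig(nPatients = 1, coresPerPatient = 1,
            coreShape = coreShapeRect(0.3, 0.3),
            cellDensity = c(tumor = 500, cytotoxic_t = 500),
            ...,
            seed = seed)
}

## Marker-call matrix helper
callMatrix <- function(df) {
  m <- as.matrix(df)
  storage.mode(m) <- "logical"
  if (is.null(rownames(m))) rownames(m) <- sprintf("c%03d", seq_len(nrow(m)))
  m
}
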