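## Cohort-level comparison layer: rank tests of metrics by group, pattern
## contingency tests, Spearman correlation matrices, per-radius group medians.
## Two-sided tests throughout; no multiplicity adjustment is applied.

#' Compare a metric between outcome groups
#'
#' Wilcoxon rank-sum test for two groups, Kruskal-Wallis for more. For two
#' groups the exact rank-sum distribution is used when both groups have at
#' most `exactMax` observations and the values are tie-free; otherwise the
#' tie-corrected normal approximation is used (continuity-corrected).
#'
#' @param values Numeric metric values; `NA`s are dropped with their group.
#' @param groups Grouping vector of the same length, at least 2 non-empty
#'   groups.
#' @param exactMax Largest per-group size for the exact two-sample test.
#' @return List with `test`, `statistic`, `p_value` and a per-group `groups`
#'   data frame (n, median, IQR).
#' @export
compareMetricByGroup <- function(values, groups, exactMax = 25) {
  keep <- !is.na(values) & !is.na(groups)
  values <- values[keep]
  groups <- factor(groups[keep])
  groups <- droplevels(groups)
  if (nlevels(groups) < 2) stop("need at least 2 non-empty groups")
  tab <- table(groups)
  if (any(tab == 0)) stop("every group needs at least one observation")
  desc <- do.call(rbind, lapply(levels(groups), function(g) {
    v <- values[groups == g]
    data.frame(group = g, n = length(v), median = stats::median(v),
               iqr = stats::IQR(v), stringsAsFactors = FALSE)
  }))
  if (nlevels(groups) == 2) {
    useExact <- all(tab <= exactMax) && !anyDuplicated(values)
    ht <- stats::wilcox.test(values ~ groups, exact = useExact, correct = TRUE)
  } else {
    ht <- stats::kruskal.test(values, groups)
  }
  list(test = ht$method, statistic = unname(ht$statistic),
       p_value = ht$p.value, groups = desc)
}

#' Test a pattern-by-outcome contingency table
#'
#' Pearson's chi-squared test when all expected counts are at least 5,
#' otherwise Fisher's exact test; the path taken is reported in `method`.
#'
#' @param table Contingency matrix/table of non-negative counts.
#' @return List `method` (`"chisq"`/`"fisher"`), `statistic` (NA for the exact
#'   test), `p_value`, `expected`.
#' @export
patternTest <- function(table) {
  table <- as.matrix(table)
  if (sum(table) == 0) stop("empty contingency table")
  expected <- outer(rowSums(table), colSums(table)) / sum(table)
  if (all(expected >= 5)) {
    ht <- stats::chisq.test(table, correct = FALSE)
    list(method = "chisq", statistic = unname(ht$statistic),
         p_value = ht$p.value, expected = expected)
  } else {
    ht <- stats::fisher.test(table)
    list(method = "fisher", statistic = NA_real_,
         p_value = ht$p.value, expected = expected)
  }
}

#' Pairwise Spearman correlation matrix
#'
#' Pairwise-complete Spearman rank correlations with two-sided p-values
#' (normal approximation). Constant columns yield `NA` for their pairs.
#'
#' @param metrics Data frame or matrix of metric columns.
#' @param minPairs Minimum number of complete pairs for a coefficient.
#' @return List with matrices `rho`, `p_value` and `n` (complete pairs).
#' @export
correlationMatrix <- function(metrics, minPairs = 3) {
  m <- as.matrix(metrics)
  k <- ncol(m)
  rho <- p <- n <- matrix(NA_real_, k, k, dimnames = list(colnames(m), colnames(m)))
  diag(rho) <- 1
  diag(p) <- 0
  diag(n) <- colSums(!is.na(m))
  for (i in seq_len(k - 1)) for (j in (i + 1):k) {
    ok <- stats::complete.cases(m[, c(i, j)])
    n[i, j] <- n[j, i] <- sum(ok)
    if (sum(ok) < minPairs) next
    x <- m[ok, i]; y <- m[ok, j]
    if (stats::sd(x) == 0 || stats::sd(y) == 0) next
    ct <- suppressWarnings(stats::cor.test(x, y, method = "spearman", exact = FALSE))
    rho[i, j] <- rho[j, i] <- unname(ct$estimate)
    p[i, j] <- p[j, i] <- ct$p.value
  }
  list(rho = rho, p_value = p, n = n)
}

#' Per-radius group medians of NMS curves
#'
#' The tabular form behind radar plots of the mixing score: the median NMS at
#' each ladder radius within each outcome group, with the number of
#' contributing patients (missing NMS values excluded per cell).
#'
#' @param curves Long curve table from [spatialCurves()] (`metric == "nms"`
#'   rows are used).
#' @param outcome Named group labels: a data frame with `patient_id` and a
#'   group column, or a named vector keyed by patient id.
#' @param groupCol Group column name when `outcome` is a data frame.
#' @return Data frame `group`, `reference`, `radius`, `n`, `median_nms`.
#' @export
summarizeNmsByGroup <- function(curves, outcome, groupCol = "pcr") {
  nmsRows <- curves[curves$metric == "nms", ]
  if (is.data.frame(outcome)) {
    grp <- outcome[[groupCol]][match(nmsRows$patient_id, outcome$patient_id)]
  } else {
    grp <- outcome[nmsRows$patient_id]
  }
  nmsRows$group <- grp
  nmsRows <- nmsRows[!is.na(nmsRows$group), ]
  if (!nrow(nmsRows)) stop("no patients with group labels")
  agg <- list()
  for (g in unique(nmsRows$group)) for (ref in unique(nmsRows$reference)) {
    sub <- nmsRows[nmsRows$group == g & nmsRows$reference == ref, ]
    for (r in sort(unique(sub$radius))) {
      v <- sub$value[sub$radius == r]
      v <- v[!is.na(v)]
      agg[[length(agg) + 1L]] <- data.frame(
        group = g, reference = ref, radius = r, n = length(v),
        median_nms = if (length(v)) stats::median(v) else NA_real_,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, agg)
}
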