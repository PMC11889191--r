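## Digital-TIL scores from H&E classifier cell annotations.

#' Compute the five digital-TIL metrics
#'
#' Given per-sample counts of lymphocytes (TILs), tumor cells, fibroblasts and
#' "other" cells, plus the summed TIL area, stroma area and analyzed tumor
#' region area, computes:
#' \itemize{
#'   \item eTILs (\%)  = 100 * TILs / (tumor cells + TILs)
#'   \item etTILs (\%) = 100 * TILs / all detected cells
#'   \item esTILs (\%) = 100 * TILs / stromal cells (TILs + fibroblasts + other)
#'   \item eaTILs (cells/mm^2) = TILs / tumor region area
#'   \item easTILs (\%) = 100 * TIL area / stroma area, capped at 100
#' }
#' A zero denominator yields `NA` for that metric (the caller decides
#' exclusion); it is never silently reported as 0.
#'
#' @param inputs Data frame with columns `n_tils`, `n_tumor`, `n_fibro`,
#'   `n_other`, `tils_area_mm2`, `stroma_area_mm2`, `tumor_region_area_mm2`
#'   (one row per sample; id columns are carried through).
#' @param etTilsIncludesTils Whether the etTILs denominator ("all detected
#'   cells") includes the TILs themselves (default TRUE, the literal reading);
#'   FALSE reproduces the parenthetical tumor+fibroblast+other reading.
#' @param capEastils Cap easTILs at 100\% (the uncapped value is always
#'   reported in `eastils_uncapped_pct`).
#' @return `inputs` with columns `etils_pct`, `ettils_pct`, `estils_pct`,
#'   `eatils_per_mm2`, `eastils_pct`, `eastils_uncapped_pct` appended.
#' @export
computeDTILs <- function(inputs, etTilsIncludesTils = TRUE, capEastils = TRUE) {
  req <- c("n_tils", "n_tumor", "n_fibro", "n_other",
           "tils_area_mm2", "stroma_area_mm2", "tumor_region_area_mm2")
  missingCols <- setdiff(req, names(inputs))
  if (length(missingCols)) stop("missing columns: ", paste(missingCols, collapse = ", "))
  if (any(inputs[req] < 0, na.rm = TRUE)) stop("counts and areas must be non-negative")
  ratio <- function(num, den) ifelse(den > 0, num / den, NA_real_)
  tils <- inputs$n_tils
  allCells <- tils + inputs$n_tumor + inputs$n_fibro + inputs$n_other
  if (!etTilsIncludesTils) allCells <- allCells - tils
  inputs$etils_pct <- 100 * ratio(tils, tils + inputs$n_tumor)
  inputs$ettils_pct <- 100 * ratio(tils, allCells)
  inputs$estils_pct <- 100 * ratio(tils, tils + inputs$n_fibro + inputs$n_other)
  inputs$eatils_per_mm2 <- ratio(tils, inputs$tumor_region_area_mm2)
  eas <- 100 * ratio(inputs$tils_area_mm2, inputs$stroma_area_mm2)
  inputs$eastils_uncapped_pct <- eas
  inputs$eastils_pct <- if (capEastils) pmin(eas, 100) else eas
  inputs
}

#' Derive dTILs inputs from a classified multiplex cell table
#'
#' Maps phenotyped classes onto the H&E classifier categories: the T-cell
#' classes are lymphocytes, `other` plays the fibroblast/stromal-cell role and
#' macrophages the "other" role. The TIL area is approximated as the TIL count
#' times a nominal lymphocyte footprint.
#'
#' @param cells Classified cell table.
#' @param areas Area table.
#' @param tilClasses Classes counted as lymphocytes.
#' @param tumorClasses,fibroClasses Class mapping for the remaining categories.
#' @param tilCellAreaUm2 Nominal per-lymphocyte area (um^2) used for the TIL
#'   area term.
#' @return One row per patient of dTILs inputs (see [computeDTILs()]).
#' @export
dtilsInputsFromCells <- function(cells, areas,
                                 tilClasses = c("t_helper", "cytotoxic_t", "t_regulatory"),
                                 tumorClasses = "tumor",
                                 fibroClasses = "other",
                                 tilCellAreaUm2 = 50) {
  stopifnot("cell_class" %in% names(cells))
  patients <- sort(unique(cells$patient_id))
  rows <- lapply(patients, function(p) {
    cc <- cells[cells$patient_id == p, ]
    aa <- areas[areas$core_id %in% unique(cc$core_id), ]
    nT <- sum(cc$cell_class %in% tilClasses)
    data.frame(
      patient_id = p,
      n_tils = nT,
      n_tumor = sum(cc$cell_class %in% tumorClasses),
      n_fibro = sum(cc$cell_class %in% fibroClasses),
      n_other = sum(!cc$cell_class %in% c(tilClasses, tumorClasses, fibroClasses)),
      tils_area_mm2 = nT * tilCellAreaUm2 / 1e6,
      stroma_area_mm2 = sum(aa$stroma_area_mm2),
      tumor_region_area_mm2 = sum(aa$tumor_area_mm2),
      stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Cohort summary of dTILs metrics
#'
#' Medians and ranges per metric (overall and per subtype when provided) and
#' the pairwise Spearman correlation matrix among the five metrics.
#'
#' @param metrics Output of [computeDTILs()], one row per sample.
#' @param subtype Optional per-sample subtype factor for stratified summaries.
#' @return List with `summary` (long data frame) and `spearman`
#'   (see [correlationMatrix()]).
#' @export
summarizeDTILs <- function(metrics, subtype = NULL) {
  cols <- c("etils_pct", "ettils_pct", "estils_pct", "eatils_per_mm2", "eastils_pct")
  missingCols <- setdiff(cols, names(metrics))
  if (length(missingCols)) stop("missing metric columns: ", paste(missingCols, collapse = ", "))
  if (nrow(metrics) < 1) stop("need at least one sample")
  summarize <- function(df, group) {
    do.call(rbind, lapply(cols, function(m) {
      v <- df[[m]][!is.na(df[[m]])]
      data.frame(metric = m, group = group, n = length(v),
                 median = if (length(v)) stats::median(v) else NA_real_,
                 min = if (length(v)) min(v) else NA_real_,
                 max = if (length(v)) max(v) else NA_real_,
                 stringsAsFactors = FALSE)
    }))
  }
  out <- summarize(metrics, "all")
  if (!is.null(subtype)) {
    for (s in unique(subtype)) {
      out <- rbind(out, summarize(metrics[subtype == s, , drop = FALSE], s))
    }
  }
  list(summary = out, spearman = correlationMatrix(metrics[cols]))
}
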