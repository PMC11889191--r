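#' @import methods
#' @importFrom Rcpp evalCpp
#' @importClassesFrom SingleCellExperiment SingleCellExperiment
#' @useDynLib tmespat, .registration = TRUE
NULL

#' CellExperiment: per-cell multiplex intensities with spatial metadata
#'
#' The central container of the package: a
#' \linkS4class{SingleCellExperiment} with one marker-by-cell intensity assay
#' per cellular region (`nucleus`, `cytoplasm`, `whole`) and per-cell spatial
#' metadata (core coordinates in um, tissue compartment, patient/core ids,
#' and -- after phenotyping -- the cell class and checkpoint flags) in
#' `colData`.
#'
#' @slot ... Inherits all slots from `SingleCellExperiment`.
#' @name CellExperiment-class
#' @aliases CellExperiment-class
#' @exportClass CellExperiment
setClass("CellExperiment", contains = "SingleCellExperiment")

.REGIONS <- c("nucleus", "cytoplasm", "whole")

setValidity("CellExperiment", function(object) {
  cd <- SummarizedExperiment::colData(object)
  req <- c("patient_id", "core_id", "x_um", "y_um", "compartment")
  miss <- setdiff(req, colnames(cd))
  if (length(miss)) return(paste("missing colData column(s):", paste(miss, collapse = ", ")))
  if (any(!is.finite(cd$x_um)) || any(!is.finite(cd$y_um))) {
    return("coordinates must be finite")
  }
  if (!all(cd$compartment %in% c("tumor", "stroma"))) {
    return("compartment must be 'tumor' or 'stroma'")
  }
  for (a in SummarizedExperiment::assayNames(object)) {
    if (any(SummarizedExperiment::assay(object, a) < 0, na.rm = TRUE)) {
      return(paste("negative intensities in assay", a))
    }
  }
  TRUE
})

#' Construct a CellExperiment from a flat cell table
#'
#' Parses `<marker>_<region>` intensity columns into region-wise assays; all
#' remaining columns become cell metadata.
#'
#' @param cells Cell table data frame (e.g. from [simulateCohort()] or
#'   `cells.csv`), with `cell_id`, `patient_id`, `core_id`, `x_um`, `y_um`,
#'   `compartment` and `<marker>_<region>` columns.
#' @return A `CellExperiment`.
#' @export
CellExperiment <- function(cells) {
  stopifnot(is.data.frame(cells), "cell_id" %in% names(cells))
  pat <- paste0("_(", paste(.REGIONS, collapse = "|"), ")$")
  intCols <- grep(pat, names(cells), value = TRUE)
  markers <- unique(sub(pat, "", intCols))
  assays <- list()
  for (reg in .REGIONS) {
    cols <- paste0(markers, "_", reg)
    if (!all(cols %in% names(cells))) next
    m <- t(as.matrix(cells[cols]))
    dimnames(m) <- list(markers, cells$cell_id)
    assays[[reg]] <- m
  }
  meta <- cells[setdiff(names(cells), intCols)]
  if (!length(assays)) {
    assays <- list(counts = matrix(numeric(0), 0, nrow(cells),
                                   dimnames = list(NULL, cells$cell_id)))
  }
  sce <- SingleCellExperiment::SingleCellExperiment(
    assays = assays,
    colData = S4Vectors::DataFrame(meta, row.names = cells$cell_id))
  methods::new("CellExperiment", sce)
}

#' @describeIn CellExperiment-class Flatten back to the cell-table data frame.
#' @param x A `CellExperiment`.
#' @export
cellTable <- function(x) {
  stopifnot(methods::is(x, "CellExperiment"))
  df <- as.data.frame(SummarizedExperiment::colData(x))
  rownames(df) <- NULL
  for (reg in SummarizedExperiment::assayNames(x)) {
    m <- SummarizedExperiment::assay(x, reg)
    for (mk in rownames(m)) df[[paste0(mk, "_", reg)]] <- unname(m[mk, ])
  }
  df
}

#' @describeIn CellExperiment-class Cell coordinates (um) as a two-column matrix.
#' @export
cellCoords <- function(x) {
  cd <- SummarizedExperiment::colData(x)
  cbind(x_um = cd$x_um, y_um = cd$y_um)
}

#' @describeIn CellExperiment-class Tissue compartment per cell.
#' @export
cellCompartment <- function(x) SummarizedExperiment::colData(x)$compartment

#' @describeIn CellExperiment-class Phenotyped class per cell (NA before phenotyping).
#' @export
cellClass <- function(x) {
  cd <- SummarizedExperiment::colData(x)
  if ("cell_class" %in% colnames(cd)) cd$cell_class else rep(NA_character_, ncol(x))
}

#' @describeIn CellExperiment-class Patient id per cell.
#' @export
patientIds <- function(x) SummarizedExperiment::colData(x)$patient_id

#' @describeIn CellExperiment-class Core id per cell.
#' @export
coreIds <- function(x) SummarizedExperiment::colData(x)$core_id

#' @describeIn CellExperiment-class Marker names.
#' @export
markerNames <- function(x) rownames(x)

#' @describeIn CellExperiment-class Marker-by-cell intensity matrix for one region.
#' @param region One of `"nucleus"`, `"cytoplasm"`, `"whole"`.
#' @export
intensityMatrix <- function(x, region = "cytoplasm") {
  region <- match.arg(region, .REGIONS)
  SummarizedExperiment::assay(x, region)
}

setMethod("show", "CellExperiment", function(object) {
  cd <- SummarizedExperiment::colData(object)
  cat("CellExperiment:", ncol(object), "cells,",
      nrow(object), "markers,",
      length(unique(cd$core_id)), "cores,",
      length(unique(cd$patient_id)), "patients\n")
  cat("  regions:", paste(SummarizedExperiment::assayNames(object), collapse = ", "), "\n")
  cat("  compartments:",
      paste(sprintf("%s=%d", names(table(cd$compartment)), table(cd$compartment)),
            collapse = ", "), "\n")
  if ("cell_class" %in% colnames(cd)) {
    cat("  classes:",
        paste(sprintf("%s=%d", names(table(cd$cell_class)), table(cd$cell_class)),
              collapse = ", "), "\n")
  } else cat("  classes: <not phenotyped>\n")
})
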