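## Generics dispatched on the central container as well as flat tables.

#' @include CellExperiment-class.R
NULL

#' Apply marker cutoffs to cells
#'
#' Calls each cell positive or negative per marker: positive when the
#' intensity in the marker's designated region is at or above the cutoff
#' (inclusive boundary). Annotation-flagged low-level outliers can be forced
#' negative via `negativeOverrides`.
#'
#' @param cells A cell table data frame or a [CellExperiment()].
#' @param cutoffs CutoffSet data frame (`marker`, `region`, `cutoff`, ...),
#'   e.g. from [markerCutoffs()].
#' @param negativeOverrides Optional data frame `cell_id`, `marker` of calls
#'   forced negative.
#' @return Logical cell-by-marker call matrix.
#' @export
setGeneric("applyCutoffs", function(cells, cutoffs, negativeOverrides = NULL)
  standardGeneric("applyCutoffs"))

#' @rdname applyCutoffs
setMethod("applyCutoffs", "data.frame", function(cells, cutoffs, negativeOverrides = NULL) {
  .applyCutoffsDF(cells, cutoffs, negativeOverrides)
})

#' @rdname applyCutoffs
setMethod("applyCutoffs", "CellExperiment", function(cells, cutoffs, negativeOverrides = NULL) {
  .applyCutoffsDF(cellTable(cells), cutoffs, negativeOverrides)
})

#' Phenotype cells: cutoffs, marker calls and class assignment
#'
#' Runs the full phenotyping stage: determine cutoffs (Otsu for CK, the
#' annotation-guided ECDF rule elsewhere) unless supplied, threshold every
#' marker in its designated region, and classify each cell by the rule table.
#'
#' @param cells Cell table data frame or [CellExperiment()].
#' @param annotations Optional annotation table (see [sampleAnnotations()]).
#' @param cutoffs Optional precomputed CutoffSet.
#' @param rules Rule table, see [classificationRules()].
#' @param regions Marker-region map.
#' @param otsuMarkers Markers thresholded by Otsu on all cells.
#' @param negativeOverrides See [applyCutoffs()].
#' @return For a data frame input: list with `cells` (classified table),
#'   `cutoffs` and `calls`. For a `CellExperiment`: the object with
#'   `cell_class`, `pd1_pos`, `pdl1_pos` added to its colData and the cutoff
#'   table in `metadata(x)$cutoffs`.
#' @export
setGeneric("phenotypeCells", function(cells, annotations = NULL, cutoffs = NULL,
                                      rules = classificationRules(),
                                      regions = defaultMarkerRegions(),
                                      otsuMarkers = "CK",
                                      negativeOverrides = NULL)
  standardGeneric("phenotypeCells"))

#' @rdname phenotypeCells
setMethod("phenotypeCells", "data.frame", function(cells, annotations, cutoffs, rules,
                                                   regions, otsuMarkers, negativeOverrides) {
  .phenotypeCellsDF(cells, annotations, cutoffs, rules, regions, otsuMarkers,
                    negativeOverrides)
})

#' @rdname phenotypeCells
setMethod("phenotypeCells", "CellExperiment", function(cells, annotations, cutoffs, rules,
                                                       regions, otsuMarkers, negativeOverrides) {
  res <- .phenotypeCellsDF(cellTable(cells), annotations, cutoffs, rules, regions,
                           otsuMarkers, negativeOverrides)
  cd <- SummarizedExperiment::colData(cells)
  i <- match(rownames(cd), res$cells$cell_id)
  cd$cell_class <- res$cells$cell_class[i]
  cd$pd1_pos <- res$cells$pd1_pos[i]
  cd$pdl1_pos <- res$cells$pdl1_pos[i]
  SummarizedExperiment::colData(cells) <- cd
  S4Vectors::metadata(cells)$cutoffs <- res$cutoffs
  cells
})

#' Per-patient, per-class, per-compartment cell densities
#'
#' Pools counts and areas across each patient's cores (pooled counts divided
#' by pooled compartment area, not a mean of per-core densities) and reports
#' densities in cells/mm^2 together with their log2 display transform.
#' Patients whose cores have zero area in a compartment get `NA` there.
#' Checkpoint-flagged subclasses (`pd1_pos`, `pdl1_pos`) are reported
#' alongside each parent class and overlap with it.
#'
#' @param cells Classified cell table or phenotyped [CellExperiment()].
#' @param areas Area table (`core_id`, `tumor_area_mm2`, `stroma_area_mm2`,
#'   `total_area_mm2`, optionally `patient_id`).
#' @param compartments Subset of `total`, `tumor`, `stroma`.
#' @param classes Classes to report (default: all observed).
#' @param pseudocount For the log2 transform.
#' @return Long data frame `patient_id`, `cell_class`, `checkpoint`,
#'   `compartment`, `n_cells`, `area_mm2`, `density`, `log2_density`.
#' @export
setGeneric("computeDensities", function(cells, areas,
                                        compartments = c("total", "tumor", "stroma"),
                                        classes = NULL, pseudocount = 1)
  standardGeneric("computeDensities"))

#' @rdname computeDensities
setMethod("computeDensities", "data.frame", function(cells, areas, compartments,
                                                     classes, pseudocount) {
  .computeDensitiesDF(cells, areas, compartments, classes, pseudocount)
})

#' @rdname computeDensities
setMethod("computeDensities", "CellExperiment", function(cells, areas, compartments,
                                                         classes, pseudocount) {
  .computeDensitiesDF(cellTable(cells), areas, compartments, classes, pseudocount)
})

#' Patient-level spatial colocalization curves and patterns
#'
#' For each patient, stitches that patient's cores with boundary gaps larger
#' than the largest ladder radius, then computes the NMS and aggregated
#' entropy curves and the entropy-gradient pattern for each reference cell
#' group against the target class.
#'
#' @param cells Classified cell table or phenotyped [CellExperiment()].
#' @param references Named list of reference class groups (each a character
#'   vector of classes pooled as reference cells), or a single character
#'   vector.
#' @param target Target class(es), default `"tumor"`.
#' @param radii Radius ladder (um).
#' @param eps Flat-slope tolerance, see [entropyGradient()].
#' @return List with `curves` (`patient_id`, `reference`, `metric`, `radius`,
#'   `value`) and `patterns` (`patient_id`, `reference`, `slope`, `pattern`).
#' @export
setGeneric("spatialCurves", function(cells,
                                     references = list(immune = c("t_helper", "cytotoxic_t", "t_regulatory", "macrophage")),
                                     target = "tumor", radii = radiusLadder(),
                                     eps = 1e-4)
  standardGeneric("spatialCurves"))

#' @rdname spatialCurves
setMethod("spatialCurves", "data.frame", function(cells, references, target, radii, eps) {
  .spatialCurvesDF(cells, references, target, radii, eps)
})

#' @rdname spatialCurves
setMethod("spatialCurves", "CellExperiment", function(cells, references, target, radii, eps) {
  .spatialCurvesDF(cellTable(cells), references, target, radii, eps)
})
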