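## Synthetic tissue-microarray generator: core geometry, cell placement under
## controllable immune-tumor mixing regimes, two-component marker intensities,
## and outcome labels. All randomness is driven by the seed in the SimConfig.

#' Disc core geometry
#'
#' A circular TMA core, by default 0.6 mm in diameter (the punch size of the
#' arrays the pipeline is designed around).
#'
#' @param diameter_mm Core diameter in millimetres.
#' @return A core-shape specification list.
#' @export
coreShapeDisc <- function(diameter_mm = 0.6) {
  stopifnot(is.numeric(diameter_mm), length(diameter_mm) == 1, diameter_mm > 0)
  list(type = "disc", diameter_mm = diameter_mm)
}

#' Rectangular core geometry
#'
#' A rectangular imaging field, by default 0.93 mm x 0.7 mm (the size of one
#' multispectral image).
#'
#' @param width_mm,height_mm Field dimensions in millimetres.
#' @return A core-shape specification list.
#' @export
coreShapeRect <- function(width_mm = 0.93, height_mm = 0.7) {
  stopifnot(width_mm > 0, height_mm > 0)
  list(type = "rect", width_mm = width_mm, height_mm = height_mm)
}

#' Default two-component marker intensity models
#'
#' Each marker gets a log-normal negative and positive component (meanlog/sdlog
#' on the log scale). Components are deliberately well separated so that
#' threshold-recovery properties of the phenotyping stage can be tested.
#'
#' @param markers Marker names.
#' @param negMeanLog,negSdLog,posMeanLog,posSdLog Component parameters shared
#'   across markers.
#' @return Named list of per-marker component models.
#' @export
defaultMarkerModels <- function(markers = c("CK", "CD4", "CD8", "FoxP3", "CD68", "PD1", "PDL1"),
                                negMeanLog = log(2), negSdLog = 0.3,
                                posMeanLog = log(30), posSdLog = 0.3) {
  mod <- list(negMeanLog = negMeanLog, negSdLog = negSdLog,
              posMeanLog = posMeanLog, posSdLog = posSdLog)
  stats::setNames(rep(list(mod), length(markers)), markers)
}

#' Default class-to-marker truth map
#'
#' Which lineage markers each generated cell class truly expresses. Regulatory
#' T-cells co-express CD4, which exercises the FoxP3-over-CD4 rule priority of
#' the classifier.
#'
#' @return Named list: class -> character vector of expressed markers.
#' @export
defaultClassMarkers <- function() {
  list(
    tumor        = "CK",
    t_helper     = "CD4",
    cytotoxic_t  = "CD8",
    t_regulatory = c("FoxP3", "CD4"),
    macrophage   = "CD68",
    other        = character(0)
  )
}

#' Marker cellular-region assignment
#'
#' FoxP3 is a nuclear transcription factor and is read in the nucleus; CD4
#' stains diffusely and is read in the whole cell; all other markers are read
#' in the cytoplasm.
#'
#' @param markers Marker names.
#' @return Named character vector marker -> region.
#' @export
defaultMarkerRegions <- function(markers = c("CK", "CD4", "CD8", "FoxP3", "CD68", "PD1", "PDL1")) {
  region <- rep("cytoplasm", length(markers))
  names(region) <- markers
  region[names(region) == "FoxP3"] <- "nucleus"
  region[names(region) == "CD4"] <- "whole"
  region
}

.defaultCheckpointProbs <- function() {
  list(
    pd1  = c(tumor = 0.01, t_helper = 0.30, cytotoxic_t = 0.20,
             t_regulatory = 0.10, macrophage = 0.05, other = 0.01),
    pdl1 = c(tumor = 0.10, t_helper = 0.25, cytotoxic_t = 0.15,
             t_regulatory = 0.08, macrophage = 0.20, other = 0.01)
  )
}

#' Simulation configuration
#'
#' Defines one synthetic cohort: core geometry, tumor-blob fraction, per-class
#' point-process intensities, the immune-tumor mixing regime, marker intensity
#' models, and the outcome model. `cellDensity` is the intensity (cells/mm^2 of
#' core area) of each class's generating point process; under the `csr` regime
#' the realized density matches it in expectation, while the attraction and
#' repulsion regimes thin the candidate immune process by their acceptance
#' kernels and therefore modulate realized abundance as well as placement.
#'
#' @param nPatients Number of patients.
#' @param coresPerPatient Cores per patient (1 to 3).
#' @param coreShape See [coreShapeDisc()] / [coreShapeRect()].
#' @param tumorFraction Fraction of core area occupied by tumor blobs, in (0,1).
#' @param cellDensity Named vector of generating intensities (cells/mm^2) per
#'   class; must contain `tumor`.
#' @param mixingRegime One of `"attraction"`, `"csr"`, `"repulsion"` applied to
#'   every non-tumor class.
#' @param mixingStrength Length scale tau (um) of the acceptance kernel:
#'   attraction accepts an immune candidate at distance d from the nearest
#'   tumor cell with probability exp(-d/tau), repulsion with 1 - exp(-d/tau).
#' @param blobRadiusRange Tumor blob radius range (um).
#' @param markerModels Per-marker two-component models, see [defaultMarkerModels()].
#' @param classMarkers Truth map class -> expressed markers.
#' @param markerRegions Marker -> designated cellular region.
#' @param checkpointProbs List with `pd1` and `pdl1` named per-class positivity
#'   probabilities.
#' @param subtypeProbs,tp53Probs Named sampling probabilities for the clinical
#'   labels.
#' @param outcomeModel List with `intercept` and named `coefficients` on the
#'   logit scale for the pCR outcome.
#' @param seed Integer seed; all generator stages derive their streams from it.
#' @return A validated `SimConfig` list.
#' @export
simConfig <- function(nPatients = 20,
                      coresPerPatient = 2,
                      coreShape = coreShapeDisc(),
                      tumorFraction = 0.25,
                      cellDensity = c(tumor = 500, cytotoxic_t = 150, t_helper = 100,
                                      t_regulatory = 60, macrophage = 80, other = 120),
                      mixingRegime = c("csr", "attraction", "repulsion"),
                      mixingStrength = 30,
                      blobRadiusRange = c(80, 160),
                      markerModels = defaultMarkerModels(),
                      classMarkers = defaultClassMarkers(),
                      markerRegions = defaultMarkerRegions(names(markerModels)),
                      checkpointProbs = .defaultCheckpointProbs(),
                      subtypeProbs = c("TN" = 0.35, "HER2+" = 0.20, "HR+/HER2-" = 0.45),
                      tp53Probs = c(mutated = 0.40, wildtype = 0.40, unknown = 0.20),
                      outcomeModel = list(intercept = 0, coefficients = numeric(0)),
                      seed = 1L) {
  mixingRegime <- match.arg(mixingRegime)
  if (!is.numeric(tumorFraction) || length(tumorFraction) != 1 ||
      tumorFraction <= 0 || tumorFraction >= 1) {
    stop("tumorFraction must lie strictly inside (0, 1)")
  }
  if (any(cellDensity < 0)) stop("cell densities must be non-negative")
  if (is.null(names(cellDensity)) || !"tumor" %in% names(cellDensity)) {
    stop("cellDensity must be a named vector containing a 'tumor' entry")
  }
  if (!coresPerPatient %in% 1:3) stop("coresPerPatient must be 1, 2 or 3")
  if (mixingStrength < 0) stop("mixingStrength must be non-negative")
  if (nPatients < 1) stop("nPatients must be at least 1")
  stopifnot(coreShape$type %in% c("disc", "rect"))
  cfg <- list(nPatients = as.integer(nPatients),
              coresPerPatient = as.integer(coresPerPatient),
              coreShape = coreShape, tumorFraction = tumorFraction,
              cellDensity = cellDensity, mixingRegime = mixingRegime,
              mixingStrength = mixingStrength, blobRadiusRange = blobRadiusRange,
              markerModels = markerModels, classMarkers = classMarkers,
              markerRegions = markerRegions, checkpointProbs = checkpointProbs,
              subtypeProbs = subtypeProbs, tp53Probs = tp53Probs,
              outcomeModel = outcomeModel, seed = as.integer(seed))
  class(cfg) <- "SimConfig"
  cfg
}

## ---- core geometry ---------------------------------------------------------

## Rasterize the core outline on a 1 um grid; pixel centers at (i - 0.5).
.coreMask <- function(shape) {
  if (shape$type == "disc") {
    d <- shape$diameter_mm * 1000
    nx <- ny <- as.integer(round(d))
    cx <- d / 2
    xs <- seq_len(nx) - 0.5
    mask <- outer((xs - cx)^2, (xs - cx)^2, "+") <= (d / 2)^2
  } else {
    nx <- as.integer(round(shape$width_mm * 1000))
    ny <- as.integer(round(shape$height_mm * 1000))
    mask <- matrix(TRUE, nx, ny)
  }
  list(mask = mask, nx = nx, ny = ny)
}

## Grow a union of random discs inside the core until the tumor fraction is
## reached; the final disc radius is bisected so the realized fraction lands
## within half a percent of the target.
.tumorMask <- function(core, fraction, radiusRange) {
  nx <- core$nx; ny <- core$ny
  xs <- seq_len(nx) - 0.5
  ys <- seq_len(ny) - 0.5
  target <- fraction * sum(core$mask)
  tum <- matrix(FALSE, nx, ny)
  inside <- which(core$mask)
  addDisc <- function(m, ctr, r) {
    ix <- which(abs(xs - ctr[1]) <= r)
    iy <- which(abs(ys - ctr[2]) <= r)
    if (!length(ix) || !length(iy)) return(m)
    sub <- outer((xs[ix] - ctr[1])^2, (ys[iy] - ctr[2])^2, "+") <= r^2
    m[ix, iy] <- m[ix, iy] | sub
    m
  }
  repeat {
    r <- stats::runif(1, radiusRange[1], radiusRange[2])
    pix <- inside[sample.int(length(inside), 1)]
    ctr <- c(xs[(pix - 1) %% nx + 1], ys[(pix - 1) %/% nx + 1])
    cand <- addDisc(tum, ctr, r) & core$mask
    if (sum(cand) >= target) {
      ## bisect this blob's radius to land close to the target fraction
      lo <- 0; hi <- r
      for (i in 1:14) {
        mid <- (lo + hi) / 2
        m <- addDisc(tum, ctr, mid) & core$mask
        if (sum(m) >= target) hi <- mid else lo <- mid
      }
      tum <- addDisc(tum, ctr, hi) & core$mask
      break
    }
    tum <- cand
  }
  tum
}

## Uniform positions over TRUE pixels of a mask, jittered inside the pixel.
.samplePositions <- function(mask, nx, n) {
  idx <- which(mask)
  if (!length(idx) || n == 0) {
    return(matrix(numeric(0), ncol = 2, dimnames = list(NULL, c("x", "y"))))
  }
  pick <- idx[sample.int(length(idx), n, replace = TRUE)]
  i <- (pick - 1) %% nx + 1
  j <- (pick - 1) %/% nx + 1
  cbind(x = i - 0.5 + stats::runif(n, -0.5, 0.5),
        y = j - 0.5 + stats::runif(n, -0.5, 0.5))
}

.lookupCompartment <- function(tumorMask, nx, ny, xy) {
  i <- pmin(pmax(ceiling(xy[, 1]), 1L), nx)
  j <- pmin(pmax(ceiling(xy[, 2]), 1L), ny)
  ifelse(tumorMask[cbind(i, j)], "tumor", "stroma")
}

## ---- cells, areas, clinical ------------------------------------------------

#' Generate synthetic cores, cells and clinical labels
#'
#' Places tumor cells uniformly inside tumor blobs and each non-tumor class
#' according to the configured mixing regime (candidate homogeneous Poisson
#' process thinned by the distance-to-nearest-tumor-cell acceptance kernel).
#' Areas are computed from the generating masks, so
#' `total = tumor + stroma` holds exactly.
#'
#' @param config A [simConfig()].
#' @return List with `cells` (cell table, without intensities), `areas`,
#'   `clinical` and `truth` (cell-level ground-truth class and checkpoint
#'   flags; written to a separate file, never part of the analysis input).
#' @export
generateCores <- function(config) {
  stopifnot(inherits(config, "SimConfig"))
  set.seed(config$seed)
  cellsL <- list(); areasL <- list(); truthL <- list()
  classes <- names(config$cellDensity)
  immuneClasses <- setdiff(classes, "tumor")
  core <- .coreMask(config$coreShape)
  coreArea <- sum(core$mask) / 1e6
  pd1p <- config$checkpointProbs$pd1
  pdl1p <- config$checkpointProbs$pdl1
  for (p in seq_len(config$nPatients)) {
    pid <- sprintf("P%03d", p)
    for (k in seq_len(config$coresPerPatient)) {
      cid <- sprintf("%s_core%d", pid, k)
      tum <- .tumorMask(core, config$tumorFraction, config$blobRadiusRange)
      tumorArea <- sum(tum) / 1e6
      stromaMaskArea <- coreArea - tumorArea
      nT <- stats::rpois(1, config$cellDensity[["tumor"]] * coreArea)
      posT <- .samplePositions(tum, core$nx, nT)
      xyL <- list(tumor = posT)
      for (cl in immuneClasses) {
        m <- stats::rpois(1, config$cellDensity[[cl]] * coreArea)
        cand <- .samplePositions(core$mask, core$nx, m)
        if (config$mixingRegime != "csr" && nrow(posT) > 0 && nrow(cand) > 0) {
          d <- .nearestDist(cand[, 1], cand[, 2], posT[, 1], posT[, 2])
          acc <- if (config$mixingRegime == "attraction") {
            exp(-d / config$mixingStrength)
          } else {
            1 - exp(-d / config$mixingStrength)
          }
          cand <- cand[stats::runif(nrow(cand)) < acc, , drop = FALSE]
        }
        xyL[[cl]] <- cand
      }
      n <- sum(vapply(xyL, nrow, 0L))
      if (n > 0) {
        xy <- do.call(rbind, xyL)
        cls <- rep(names(xyL), vapply(xyL, nrow, 0L))
        ids <- sprintf("%s_c%05d", cid, seq_len(n))
        cellsL[[cid]] <- data.frame(
          cell_id = ids, patient_id = pid, core_id = cid,
          x_um = xy[, 1], y_um = xy[, 2],
          compartment = .lookupCompartment(tum, core$nx, core$ny, xy),
          stringsAsFactors = FALSE)
        p1 <- unname(pd1p[cls]); p1[is.na(p1)] <- 0
        p2 <- unname(pdl1p[cls]); p2[is.na(p2)] <- 0
        truthL[[cid]] <- data.frame(
          cell_id = ids, true_class = cls,
          pd1_pos = stats::runif(n) < p1,
          pdl1_pos = stats::runif(n) < p2,
          stringsAsFactors = FALSE)
      }
      areasL[[cid]] <- data.frame(
        core_id = cid, patient_id = pid,
        tumor_area_mm2 = tumorArea, stroma_area_mm2 = stromaMaskArea,
        total_area_mm2 = tumorArea + stromaMaskArea, stringsAsFactors = FALSE)
    }
  }
  cells <- do.call(rbind, c(cellsL, list(make.row.names = FALSE)))
  clinical <- generateOutcomes(
    matrix(numeric(0), nrow = config$nPatients, ncol = 0,
           dimnames = list(sprintf("P%03d", seq_len(config$nPatients)), NULL)),
    config)
  list(cells = cells,
       areas = do.call(rbind, c(areasL, list(make.row.names = FALSE))),
       clinical = clinical,
       truth = do.call(rbind, c(truthL, list(make.row.names = FALSE))))
}

#' Fill marker intensities into a cell table
#'
#' Every cell draws every marker in every region from the marker's negative
#' log-normal component, except that cells truly expressing a marker (per the
#' truth table and class-marker map, plus the PD-1/PD-L1 flags) draw from the
#' positive component in the marker's designated region only.
#'
#' @param cells Cell table from [generateCores()].
#' @param truth Matching truth table.
#' @param config A [simConfig()].
#' @param markers Markers to generate; all must have a model in the config.
#' @return The cell table with `<marker>_<region>` intensity columns appended.
#' @export
generateIntensities <- function(cells, truth, config,
                                markers = names(config$markerModels)) {
  stopifnot(inherits(config, "SimConfig"))
  missingModel <- setdiff(markers, names(config$markerModels))
  if (length(missingModel)) {
    stop("no intensity model for marker(s): ", paste(missingModel, collapse = ", "))
  }
  set.seed(config$seed + 1L)
  truth <- truth[match(cells$cell_id, truth$cell_id), ]
  n <- nrow(cells)
  for (m in markers) {
    mod <- config$markerModels[[m]]
    designated <- config$markerRegions[[m]]
    pos <- switch(m,
      PD1 = truth$pd1_pos,
      PDL1 = truth$pdl1_pos,
      vapply(truth$true_class, function(cl) m %in% config$classMarkers[[cl]], TRUE))
    pos[is.na(pos)] <- FALSE
    for (region in c("nucleus", "cytoplasm", "whole")) {
      v <- stats::rlnorm(n, mod$negMeanLog, mod$negSdLog)
      if (region == designated && any(pos)) {
        v[pos] <- stats::rlnorm(sum(pos), mod$posMeanLog, mod$posSdLog)
      }
      cells[[paste0(m, "_", region)]] <- v
    }
  }
  cells
}

#' Generate binary pCR outcomes from patient-level features
#'
#' `pcr ~ Bernoulli(plogis(intercept + coefficients . features))`. Subtype and
#' TP53 status are sampled from the configured probabilities.
#'
#' @param features Numeric matrix or data.frame, one row per patient (rownames
#'   are patient ids), columns named as the model coefficients; assumed
#'   standardized by the caller.
#' @param config A [simConfig()].
#' @return Clinical table: `patient_id`, `pcr`, `subtype`, `tp53`.
#' @export
generateOutcomes <- function(features, config) {
  stopifnot(inherits(config, "SimConfig"))
  features <- as.matrix(features)
  coefs <- config$outcomeModel$coefficients
  if (length(coefs)) {
    if (is.null(names(coefs)) || !all(names(coefs) %in% colnames(features))) {
      stop("outcome-model coefficients do not match the feature columns")
    }
    eta <- config$outcomeModel$intercept +
      drop(features[, names(coefs), drop = FALSE] %*% coefs)
  } else {
    eta <- rep(config$outcomeModel$intercept, nrow(features))
  }
  set.seed(config$seed + 2L)
  nP <- nrow(features)
  ids <- rownames(features)
  if (is.null(ids)) ids <- sprintf("P%03d", seq_len(nP))
  data.frame(
    patient_id = ids,
    pcr = as.integer(stats::runif(nP) < stats::plogis(eta)),
    subtype = sample(names(config$subtypeProbs), nP, TRUE, config$subtypeProbs),
    tp53 = sample(names(config$tp53Probs), nP, TRUE, config$tp53Probs),
    stringsAsFactors = FALSE)
}

#' Sample a synthetic annotation set
#'
#' Emulates the manual annotation step of the phenotyping workflow: for each
#' marker, a subset of truly positive cells plus a subset of cells negative to
#' all markers, with the intensity read in the marker's designated region.
#'
#' @param cells Cell table with intensities.
#' @param truth Matching truth table.
#' @param config A [simConfig()].
#' @param nPos,nNeg Cells sampled per marker.
#' @return Data frame: `marker`, `cell_id`, `intensity`, `label`
#'   (`positive` / `negative_all`).
#' @export
sampleAnnotations <- function(cells, truth, config, nPos = 30, nNeg = 50) {
  set.seed(config$seed + 3L)
  truth <- truth[match(cells$cell_id, truth$cell_id), ]
  out <- list()
  allNeg <- truth$true_class == "other" & !truth$pd1_pos & !truth$pdl1_pos
  for (m in names(config$markerModels)) {
    region <- config$markerRegions[[m]]
    col <- paste0(m, "_", region)
    pos <- switch(m,
      PD1 = truth$pd1_pos,
      PDL1 = truth$pdl1_pos,
      vapply(truth$true_class, function(cl) m %in% config$classMarkers[[cl]], TRUE))
    posIdx <- which(pos)
    if (length(posIdx)) {
      posIdx <- if (length(posIdx) > nPos) sample(posIdx, nPos) else posIdx
      out[[paste0(m, "_pos")]] <- data.frame(
        marker = m, cell_id = cells$cell_id[posIdx],
        intensity = cells[[col]][posIdx], label = "positive",
        stringsAsFactors = FALSE)
    }
    negIdx <- which(allNeg)
    if (length(negIdx)) {
      negIdx <- if (length(negIdx) > nNeg) sample(negIdx, nNeg) else negIdx
      out[[paste0(m, "_neg")]] <- data.frame(
        marker = m, cell_id = cells$cell_id[negIdx],
        intensity = cells[[col]][negIdx], label = "negative_all",
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}

#' Simulate a full synthetic cohort
#'
#' @param config A [simConfig()].
#' @return List with `cells` (with intensities), `areas`, `clinical`, `truth`,
#'   `annotations` and the `config`.
#' @export
simulateCohort <- function(config = simConfig()) {
  sim <- generateCores(config)
  sim$cells <- generateIntensities(sim$cells, sim$truth, config)
  sim$annotations <- sampleAnnotations(sim$cells, sim$truth, config)
  sim$config <- config
  sim
}

#' Write a simulated cohort to CSV files
#'
#' Writes `cells.csv`, `areas.csv`, `clinical.csv`, `annotations.csv` and the
#' ground-truth `truth.csv` (the latter is study metadata, not analysis input).
#'
#' @param sim Result of [simulateCohort()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
writeCohort <- function(sim, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- c(cells = file.path(dir, "cells.csv"),
             areas = file.path(dir, "areas.csv"),
             clinical = file.path(dir, "clinical.csv"),
             annotations = file.path(dir, "annotations.csv"),
             truth = file.path(dir, "truth.csv"))
  utils::write.csv(sim$cells, paths["cells"], row.names = FALSE)
  utils::write.csv(sim$areas, paths["areas"], row.names = FALSE)
  utils::write.csv(sim$clinical, paths["clinical"], row.names = FALSE)
  utils::write.csv(sim$annotations, paths["annotations"], row.names = FALSE)
  utils::write.csv(sim$truth, paths["truth"], row.names = FALSE)
  invisible(paths)
}
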