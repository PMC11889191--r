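## Pipeline orchestration: simulate -> phenotype -> dtils/densities ->
## spatial -> report, with flat-CSV inter-stage exchange, a manifest, and
## per-stage timing logged to stderr. Re-running with the same config and
## seed reproduces byte-identical outputs.

#' Default pipeline run configuration
#'
#' @param seed Integer seed recorded in the manifest and driving every stage.
#' @return A nested list consumable by [runPipeline()].
#' @export
defaultRunConfig <- function(seed = 1L) {
  list(
    seed = as.integer(seed),
    stages = c("simulate", "phenotype", "dtils", "densities", "spatial", "report"),
    simulate = list(nPatients = 24, coresPerPatient = 2, mixingRegime = "csr"),
    radii = list(from = 50, to = 600, by = 50),
    eps = 1e-4,
    pseudocount = 1,
    etTilsIncludesTils = TRUE,
    tilCellAreaUm2 = 50,
    references = list(immune = c("t_helper", "cytotoxic_t", "t_regulatory", "macrophage"),
                      cytotoxic_t = "cytotoxic_t",
                      t_helper = "t_helper",
                      t_regulatory = "t_regulatory",
                      macrophage = "macrophage"),
    target = "tumor")
}

#' Read a pipeline run configuration from a YAML file
#'
#' Values present in the file override the defaults of [defaultRunConfig()];
#' the `simulate` block is passed to [simConfig()].
#'
#' @param path YAML file.
#' @param seed Optional seed overriding both the file and the default.
#' @return Run-configuration list.
#' @export
readRunConfig <- function(path, seed = NULL) {
  if (!file.exists(path)) stop("config file not found: ", path)
  user <- yaml::read_yaml(path)
  cfg <- utils::modifyList(defaultRunConfig(), user)
  if (!is.null(seed)) cfg$seed <- as.integer(seed)
  if (is.list(cfg$simulate$cellDensity)) {
    cfg$simulate$cellDensity <- unlist(cfg$simulate$cellDensity)
  }
  cfg
}

.readStageCsv <- function(outDir, file, stage) {
  path <- file.path(outDir, file)
  if (!file.exists(path)) {
    stop("stage '", stage, "' needs ", path,
         " ; run the producing stage first", call. = FALSE)
  }
  utils::read.csv(path, stringsAsFactors = FALSE)
}

.writeStageCsv <- function(x, outDir, file) {
  utils::write.csv(x, file.path(outDir, file), row.names = FALSE, na = "")
}

#' Run the analysis pipeline
#'
#' Executes the configured stages into `outDir`; each stage reads its inputs
#' from and writes its outputs to that directory as flat CSV files, so stages
#' can also be re-run individually. A `manifest.json` records the package
#' version, seed, configuration hash and emitted files.
#'
#' @param config Run configuration, see [defaultRunConfig()] /
#'   [readRunConfig()].
#' @param outDir Output directory (created if needed).
#' @param seed Optional override of `config$seed`.
#' @param stages Optional override of `config$stages`.
#' @return Invisibly, the manifest list.
#' @export
runPipeline <- function(config = defaultRunConfig(), outDir, seed = NULL,
                        stages = NULL) {
  if (!is.null(seed)) config$seed <- as.integer(seed)
  if (!is.null(stages)) config$stages <- stages
  if (!dir.exists(outDir)) dir.create(outDir, recursive = TRUE)
  radii <- radiusLadder(config$radii$from, config$radii$to, config$radii$by)
  written <- character(0)
  stamp <- function(stage, expr) {
    t0 <- proc.time()[["elapsed"]]
    res <- force(expr)
    message(sprintf("[tmespat] %-9s %6.1fs", stage, proc.time()[["elapsed"]] - t0))
    res
  }
  for (stage in config$stages) {
    switch(stage,
      simulate = stamp("simulate", {
        simCfg <- do.call(simConfig, c(config$simulate, list(seed = config$seed)))
        writeCohort(simulateCohort(simCfg), outDir)
        written <- c(written, c("cells.csv", "areas.csv", "clinical.csv",
                                "annotations.csv", "truth.csv"))
      }),
      phenotype = stamp("phenotype", {
        cells <- .readStageCsv(outDir, "cells.csv", stage)
        annPath <- file.path(outDir, "annotations.csv")
        ann <- if (file.exists(annPath)) utils::read.csv(annPath, stringsAsFactors = FALSE) else NULL
        res <- phenotypeCells(cells, annotations = ann)
        .writeStageCsv(res$cutoffs, outDir, "cutoffs.csv")
        .writeStageCsv(res$cells, outDir, "classified_cells.csv")
        written <- c(written, "cutoffs.csv", "classified_cells.csv")
      }),
      dtils = stamp("dtils", {
        cells <- .readStageCsv(outDir, "classified_cells.csv", stage)
        areas <- .readStageCsv(outDir, "areas.csv", stage)
        inputs <- dtilsInputsFromCells(cells, areas,
                                       tilCellAreaUm2 = config$tilCellAreaUm2)
        .writeStageCsv(computeDTILs(inputs, config$etTilsIncludesTils),
                       outDir, "dtils.csv")
        written <- c(written, "dtils.csv")
      }),
      densities = stamp("densities", {
        cells <- .readStageCsv(outDir, "classified_cells.csv", stage)
        areas <- .readStageCsv(outDir, "areas.csv", stage)
        .writeStageCsv(computeDensities(cells, areas, pseudocount = config$pseudocount),
                       outDir, "densities.csv")
        written <- c(written, "densities.csv")
      }),
      spatial = stamp("spatial", {
        cells <- .readStageCsv(outDir, "classified_cells.csv", stage)
        refs <- lapply(config$references, unlist)
        res <- spatialCurves(cells, references = refs, target = config$target,
                             radii = radii, eps = config$eps)
        .writeStageCsv(res$curves, outDir, "spatial_curves.csv")
        .writeStageCsv(res$patterns, outDir, "patterns.csv")
        written <- c(written, "spatial_curves.csv", "patterns.csv")
      }),
      report = stamp("report", {
        written <- c(written, .reportStage(outDir, config))
      }),
      stop("unknown stage: ", stage)
    )
  }
  manifest <- list(package = "tmespat",
                   version = as.character(utils::packageVersion("tmespat")),
                   seed = config$seed,
                   config_hash = rlang::hash(config),
                   stages = config$stages,
                   files = sort(unique(written)))
  jsonlite::write_json(manifest, file.path(outDir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(manifest)
}

## descriptive/test layer over the pipeline outputs
.reportStage <- function(outDir, config) {
  clinical <- .readStageCsv(outDir, "clinical.csv", "report")
  dtils <- .readStageCsv(outDir, "dtils.csv", "report")
  dens <- .readStageCsv(outDir, "densities.csv", "report")
  curves <- .readStageCsv(outDir, "spatial_curves.csv", "report")
  patterns <- .readStageCsv(outDir, "patterns.csv", "report")

  pcr <- clinical$pcr[match(dtils$patient_id, clinical$patient_id)]
  cmpRows <- list()
  addCmp <- function(metric, values, groups, grouping) {
    ok <- !is.na(values) & !is.na(groups)
    if (length(unique(groups[ok])) < 2) return()
    res <- compareMetricByGroup(values[ok], groups[ok])
    cmpRows[[length(cmpRows) + 1L]] <<- data.frame(
      metric = metric, grouping = grouping, test = res$test,
      statistic = res$statistic, p_value = res$p_value,
      stringsAsFactors = FALSE)
  }
  for (m in c("etils_pct", "ettils_pct", "estils_pct", "eatils_per_mm2", "eastils_pct")) {
    addCmp(m, dtils[[m]], pcr, "pcr")
    addCmp(m, dtils[[m]], clinical$subtype[match(dtils$patient_id, clinical$patient_id)],
           "subtype")
  }
  densAll <- dens[dens$checkpoint == "all", ]
  for (cl in unique(densAll$cell_class)) for (comp in unique(densAll$compartment)) {
    sub <- densAll[densAll$cell_class == cl & densAll$compartment == comp, ]
    addCmp(paste0("log2_density.", cl, ".", comp), sub$log2_density,
           clinical$pcr[match(sub$patient_id, clinical$patient_id)], "pcr")
  }
  comparisons <- if (length(cmpRows)) do.call(rbind, cmpRows) else
    data.frame(metric = character(0), grouping = character(0), test = character(0),
               statistic = numeric(0), p_value = numeric(0))
  .writeStageCsv(comparisons, outDir, "comparisons.csv")

  ## pattern x outcome contingency (immune reference)
  imm <- patterns[patterns$reference == "immune" &
                    patterns$pattern %in% c("attraction", "repulsion"), ]
  contRows <- data.frame(pattern = character(0), pcr = integer(0), n = integer(0),
                         method = character(0), p_value = numeric(0))
  if (nrow(imm)) {
    pg <- clinical$pcr[match(imm$patient_id, clinical$patient_id)]
    tab <- table(imm$pattern, pg)
    if (all(dim(tab) >= 2)) {
      tst <- patternTest(tab)
      contRows <- data.frame(
        pattern = rep(rownames(tab), ncol(tab)),
        pcr = rep(colnames(tab), each = nrow(tab)),
        n = as.vector(tab), method = tst$method, p_value = tst$p_value,
        stringsAsFactors = FALSE)
    } else {
      contRows <- data.frame(
        pattern = rep(rownames(tab), ncol(tab)),
        pcr = rep(colnames(tab), each = nrow(tab)),
        n = as.vector(tab), method = NA_character_, p_value = NA_real_,
        stringsAsFactors = FALSE)
    }
  }
  .writeStageCsv(contRows, outDir, "contingency.csv")

  cm <- correlationMatrix(dtils[c("etils_pct", "ettils_pct", "estils_pct",
                                  "eatils_per_mm2", "eastils_pct")])
  corLong <- expand.grid(metric_a = rownames(cm$rho), metric_b = colnames(cm$rho),
                         stringsAsFactors = FALSE)
  corLong$rho <- as.vector(cm$rho)
  corLong$p_value <- as.vector(cm$p_value)
  corLong$n <- as.vector(cm$n)
  .writeStageCsv(corLong, outDir, "correlations.csv")

  radar <- summarizeNmsByGroup(curves, clinical, groupCol = "pcr")
  .writeStageCsv(radar, outDir, "radar_table.csv")
  c("comparisons.csv", "contingency.csv", "correlations.csv", "radar_table.csv")
}
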