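## Compartment-normalized cell densities with multi-core merging.

#' log2 display transform for cell densities
#'
#' @param density Non-negative densities (cells/mm^2); `NA` passes through.
#' @param pseudocount Added before the log (default 1 cell/mm^2).
#' @return `log2(density + pseudocount)`.
#' @export
log2Density <- function(density, pseudocount = 1) {
  if (any(density < 0, na.rm = TRUE)) stop("density must be non-negative")
  log2(density + pseudocount)
}

.computeDensitiesDF <- function(cells, areas,
                                compartments = c("total", "tumor", "stroma"),
                                classes = NULL, pseudocount = 1) {
  stopifnot("cell_class" %in% names(cells))
  compartments <- match.arg(compartments, several.ok = TRUE)
  missingCore <- setdiff(unique(cells$core_id), areas$core_id)
  if (length(missingCore)) {
    stop("core(s) without an area row: ", paste(missingCore, collapse = ", "))
  }
  if (is.null(classes)) classes <- sort(unique(cells$cell_class))
  ## patient mapping for cores: prefer the areas table, fall back to the cells
  if (!"patient_id" %in% names(areas)) {
    map <- unique(cells[c("core_id", "patient_id")])
    areas$patient_id <- map$patient_id[match(areas$core_id, map$core_id)]
  }
  areas <- areas[!is.na(areas$patient_id), ]
  patients <- sort(unique(areas$patient_id))
  hasFlags <- all(c("pd1_pos", "pdl1_pos") %in% names(cells))
  checkpoints <- if (hasFlags) c("all", "pd1_pos", "pdl1_pos") else "all"
  rows <- list()
  for (p in patients) {
    aa <- areas[areas$patient_id == p, ]
    cc <- cells[cells$patient_id == p, ]
    for (comp in compartments) {
      area <- switch(comp,
                     total = sum(aa$total_area_mm2),
                     tumor = sum(aa$tumor_area_mm2),
                     stroma = sum(aa$stroma_area_mm2))
      sub <- if (comp == "total") cc else cc[cc$compartment == comp, ]
      for (cl in classes) {
        inClass <- sub$cell_class == cl
        for (cp in checkpoints) {
          n <- switch(cp,
                      all = sum(inClass),
                      pd1_pos = sum(inClass & sub$pd1_pos),
                      pdl1_pos = sum(inClass & sub$pdl1_pos))
          dens <- if (area > 0) n / area else NA_real_
          rows[[length(rows) + 1L]] <- data.frame(
            patient_id = p, cell_class = cl, checkpoint = cp,
            compartment = comp, n_cells = n, area_mm2 = area,
            density = dens, stringsAsFactors = FALSE)
        }
      }
    }
  }
  out <- do.call(rbind, rows)
  out$log2_density <- log2Density(out$density, pseudocount)
  out
}
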