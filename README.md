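# tmespat

Quantitative analysis of the tumor-immune microenvironment (TME) from
per-cell tables of tissue-microarray (TMA) multiplex immunofluorescence and
H&E cell-classifier output — for translational researchers who have
segmented-cell data (coordinates, compartment labels, region-wise marker
intensities) and want reproducible immune-infiltrate metrics and spatial
colocalization statistics per patient.

The package implements:

* **Digital TIL scores** from classifier cell annotations — with TILs,
  tumor cells, fibroblasts and "other" cells counted per sample:
  `eTILs = 100·TILs/(TILs+tumor)`, `etTILs = 100·TILs/all cells`,
  `esTILs = 100·TILs/(TILs+fibroblasts+other)`,
  `eaTILs = TILs/tumor-region area (mm²)`,
  `easTILs = 100·TIL area/stroma area`.
* **Marker cutoffs and phenotyping** — annotation-guided ECDF/kneepoint
  cutoffs per marker (read in the marker's cellular region: FoxP3 nuclear,
  CD4 whole-cell, others cytoplasmic), Otsu thresholding for the bimodal
  cytokeratin signal, and an ordered rule table assigning each cell one class
  (tumor, macrophage, regulatory/cytotoxic/helper T-cell, other) with
  orthogonal PD-1/PD-L1 flags.
* **Cell densities** (cells/mm²) per patient × class × compartment
  (total/tumor/stroma), pooling counts and areas across a patient's cores,
  with a `log2(x+1)` display transform.
* **Spatial statistics** over a radius ladder (50–600 µm, step 50): the
  normalized mixing score
  `NMS(r) = [I_rt · n_r(n_r−1)/2] / [I_rr · n_r · n_t]`
  (≈1 under complete spatial randomness, >1 for immune–tumor colocalization)
  and the aggregated entropy
  `H(r) = −p·log₂p − (1−p)·log₂(1−p)` of the pooled reference/target
  composition within r of the reference cells, whose slope at the smallest
  radii classifies each patient as *attraction* (negative), *repulsion*
  (positive) or *flat*. Multi-core patients are stitched with boundary gaps
  larger than the largest radius so cross-core pairs never contribute.
* **Cohort statistics** — Wilcoxon/Kruskal–Wallis group contrasts, pattern
  contingency tests (chi-squared or Fisher by expected counts), pairwise
  Spearman matrices, per-radius group medians (radar-plot tables).
* A **synthetic TMA generator** (0.6 mm disc cores / 0.93×0.7 mm imaging
  fields, tumor blobs, attraction/CSR/repulsion mixing regimes, bimodal
  log-normal marker intensities, logistic outcome labels) so the whole
  pipeline is testable without access to clinical data.

See `vignettes/tme-spatial-methods.Rmd` for the model details, parameter
choices and limitations.

## Worked example

Simulate a small attraction-regime cohort, phenotype it, and compute the
spatial statistics:

```r
library(tmespat)

cfg <- simConfig(nPatients = 4, coresPerPatient = 2,
                 mixingRegime = "attraction", mixingStrength = 30, seed = 42)
sim <- simulateCohort(cfg)

ce <- CellExperiment(sim$cells)                      # S4 container
ce <- phenotypeCells(ce, annotations = sim$annotations)
ce
#> CellExperiment: 1443 cells, 7 markers, 8 cores, 4 patients
#>   regions: nucleus, cytoplasm, whole
#>   compartments: stroma=100, tumor=1343
#>   classes: cytotoxic_t=94, macrophage=36, other=131, t_helper=61, t_regulatory=38, tumor=1083

S4Vectors::metadata(ce)$cutoffs[, 1:4]
#>  marker    region   method   cutoff
#>      CK cytoplasm     otsu 17.92975
#>     CD4     whole ecdf_min 18.12431
#>     CD8 cytoplasm ecdf_min 15.14089
#>   FoxP3   nucleus ecdf_min 13.67557
#>    CD68 cytoplasm ecdf_min 16.40601
#>     PD1 cytoplasm ecdf_min 18.18242
#>    PDL1 cytoplasm ecdf_min 17.25401

sp <- spatialCurves(ce, references = list(
  immune = c("t_helper", "cytotoxic_t", "t_regulatory", "macrophage")))
sp$patterns
#>  patient_id reference        slope    pattern
#>        P001    immune -0.001326853 attraction
#>        P002    immune -0.002069935 attraction
#>        P003    immune -0.002233443 attraction
#>        P004    immune -0.001623008 attraction
```

CK was thresholded by Otsu at 17.9 (between the negative component around 2
and the positive component around 30); the annotated markers all took the
minimal-positive-signal ECDF path. Against the generator's truth labels this
run recovers 96.5% of cell classes. All four patients of this
attraction-regime cohort show a negative aggregated-entropy slope between
50 and 100 µm — the colocalization ("attraction") pattern, as constructed.

The same stages run as a batch pipeline writing flat CSVs plus a manifest:

```r
runPipeline(defaultRunConfig(seed = 1), outDir = "out")
# simulate → phenotype → dtils → densities → spatial → report
```

or from a shell via the thin wrapper `inst/scripts/tmespat`
(`tmespat run --out out --seed 1 [--config cfg.yaml]`).

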