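---
title: "Methods: quantifying tumor-immune spatial organization from multiplex cell tables"
author: "tmespat"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantifying tumor-immune spatial organization}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tmespat)
```

# Scope

`tmespat` quantifies the tumor-immune microenvironment from per-cell tables of
the kind produced by multiplex immunofluorescence image analysis of tissue
microarrays (TMAs) and by H&E cell classifiers: each row a segmented cell with
coordinates in micrometres, a tumor/stroma compartment label, and marker
intensities per cellular region (nucleus, cytoplasm, whole cell). On top of
these tables the package computes

* digital tumor-infiltrating-lymphocyte (dTIL) scores,
* marker positivity cutoffs (annotation-guided ECDF rule, Otsu rule) and
  rule-based cell phenotypes with PD-1/PD-L1 co-expression flags,
* compartment-normalized cell densities with multi-core merging,
* two spatial colocalization statistics over a radius ladder: the normalized
  mixing score (NMS) and the aggregated-entropy gradient with an
  attraction/repulsion pattern call,
* a descriptive cohort-statistics layer (rank tests, contingency tests,
  Spearman matrices, per-radius group medians).

Because clinical trial cell tables cannot be redistributed, the package ships a
synthetic TMA generator that produces cohorts with the statistical structure
the analysis assumes. The generator is first-class, tested code: every
downstream stage is exercised end to end on its output.

# The five dTIL scores

With `n_tils` lymphocytes, `n_tumor` tumor cells, `n_fibro` fibroblasts and
`n_other` other cells detected in a sample, plus the summed lymphocyte area,
the stroma area and the analyzed tumor-region area (mm^2):

* eTILs (%) = 100 n_tils / (n_tils + n_tumor)
* etTILs (%) = 100 n_tils / (n_tils + n_tumor + n_fibro + n_other)
* esTILs (%) = 100 n_tils / (n_tils + n_fibro + n_other)
* eaTILs (cells/mm^2) = n_tils / tumor-region area
* easTILs (%) = 100 TIL area / stroma area

Two conventions required a decision. First, "all detected cells" in the etTILs
denominator is read literally as including the lymphocytes themselves; the
narrower reading (tumor + fibroblasts + other only) is available via
`etTilsIncludesTils = FALSE`. Second, easTILs is a ratio of areas treated as a
percentage, so it is capped at 100 with the uncapped ratio always reported in
`eastils_uncapped_pct`. A zero denominator returns `NA` for that metric,
never 0 -- excluding such samples is the caller's decision, silently reporting
zero infiltration is not.

# Marker cutoffs and phenotyping

Intensities are photon counts normalized to exposure time
(`normalizeIntensity()`). Each marker is read in one designated cellular
region: FoxP3 (a nuclear transcription factor) in the nucleus, CD4 (diffuse
membrane staining) in the whole cell, everything else in the cytoplasm.

**Annotation-guided ECDF rule** (`ecdfCutoff()`): given the intensities of
cells manually annotated positive for a marker, the cutoff is the minimal
recorded positive signal when the empirical CDF rises steeply and
monotonously. When the sorted sample instead shows a prominent kneepoint --
a handful of low-level outliers followed by the main positive mass -- the
cutoff moves to the kneepoint and the outliers are treated as negative.
Kneepoint detection is a kneedle criterion: the maximum perpendicular distance
of the ECDF from the chord joining its endpoints, both axes normalized to
[0, 1], searched over the lower region of the curve (cumulative height at
most 0.3) -- a knee that separates *individual low-level outliers* from the
positive mass necessarily sits in the lower tail, whereas the smooth
curvature of a clean unimodal sample peaks mid-curve and in simulation
essentially never places its maximum in the lower region. The prominence
threshold defaults to 0.25: the ECDF of a clean unimodal positive sample
deviates from its chord by roughly 0.1-0.2 through distributional curvature
alone, whereas an outlier-contaminated sample scores about 0.35-0.5. A
background diagnostic (fraction of all-negative annotated cells at or above
the cutoff) is reported with every cutoff.

**Otsu rule** (`otsuCutoff()`): used for cytokeratin, whose pooled intensity
distribution is bimodal (most cells are either epithelial or not). The
threshold minimizes the weighted intra-class variance over a fixed histogram
of 256 equal-width bins between the sample minimum and maximum; ties are
broken toward the smaller cutoff. The fixed binning makes the result
bit-stable, and the test suite holds it equal to an exhaustive search over
every candidate split.

**Positivity and classes**: positivity is inclusive (intensity >= cutoff; the
boundary convention is unstated upstream and had to be fixed somewhere).
Classes are assigned by an ordered rule table following lineage-marker
dominance -- tumor (CK+) before macrophage (CD68+) before regulatory T-cell
(FoxP3+) before cytotoxic T-cell (CD8+) before T-helper (CD4+), anything else
`other` -- which makes the classes disjoint and total: every cell receives
exactly one class, and a FoxP3+CD4+ cell is a regulatory T-cell. The table is
a reconstruction of common practice rather than a published standard and is
user-overridable. PD-1/PD-L1 calls are orthogonal flags on top of the class,
so checkpoint-positive subclasses overlap their parent class.

# Cell densities

Densities are cells/mm^2 per patient, class and compartment (total, tumor,
stroma). Cores of one patient are merged by pooling counts and pooling areas
-- never by averaging per-core densities, which would weight a tiny core as
much as a large one. A patient with zero area in a compartment across all
cores gets `NA` there. For display, `log2Density()` applies
`log2(density + 1)`; the pseudocount of 1 cell/mm^2 handles empty classes
(no zero-handling rule is standard, 1 keeps zero densities at zero on the log
scale).

# Spatial statistics

Both statistics are computed per patient over a radius ladder, by default 50
to 600 um in steps of 50 -- from close-distance interactions up to the scale
of a whole imaging frame. Multi-core patients are stitched onto a grid with
pairwise boundary gaps exceeding the largest radius, so cross-core pairs can
never contribute and stitched results equal the sum of per-core results.

**Normalized mixing score.** With `I_rt` the number of unordered
reference-target pairs within radius r, `I_rr` the unordered
reference-reference pairs, and n_r, n_t the cell counts,

NMS(r) = [I_rt * n_r (n_r - 1) / 2] / [I_rr * n_r * n_t],

i.e. the mixing ratio I_rt / I_rr normalized by the ratio of maximal pair
counts. Under complete spatial randomness the expected pair counts are
proportional to their maxima with the same geometric factor, so NMS is about 1
regardless of cell numbers; values above 1 indicate reference-target
colocalization. `I_rr = 0` yields `NA` (a sample with no co-located reference
pairs carries no mixing information at that radius), never infinity; `I_rt =
0` with `I_rr > 0` is a true 0. The distance boundary is inclusive and
coincident cells count as distinct.

**Aggregated entropy.** For each reference cell, reference and target cells
within r are counted, the center cell included; counts are pooled over all
reference cells into N_ref and N_tgt, and with p = N_ref / (N_ref + N_tgt)
the binary Shannon entropy H = -p log2 p - (1-p) log2 (1-p) (0 log 0 = 0) is
returned. H is 1 at perfect local balance of the two classes (maximal
colocalization) and 0 for single-class neighborhoods. The pooled-counts
aggregation is isolated in one function so the per-cell-averaged variant can
be swapped in; including the center cell guarantees N_ref >= n_r > 0.

**Pattern call.** The gradient is the slope of H between the two smallest
ladder radii. Negative slope (entropy highest close to the reference cells) is
`attraction`, positive is `repulsion`, and |slope| <= eps is `flat`, with eps
= 1e-4 per um by default -- about half a percentage point of entropy over one
50 um rung, below which sampling noise dominates at typical per-core cell
counts.

Two structural properties of these definitions matter for interpretation:

* *Center-cell bias.* Because each reference cell counts itself, small-radius
  composition is pulled toward the reference class. When the target class is
  locally denser than the reference, entropy therefore tends to rise with
  radius even under independent placement. Pattern calls are accordingly
  meaningful as contrasts -- between regimes, or between patient groups --
  rather than as absolute statements about a single sample.
* *Saturation.* Once the radius reaches the diameter of the frame holding a
  patient's cells, all pairs are counted and NMS is identically 1 whatever
  the spatial arrangement. Radii near the frame size carry little contrast;
  comparisons across the full 50-600 um ladder are only informative on frames
  larger than 600 um, such as the 0.93 x 0.7 mm imaging field.

# The synthetic TMA generator

`simConfig()` + `simulateCohort()` emulate the study material the analysis was
designed for:

* **Geometry.** Disc cores of 0.6 mm diameter (the TMA punch) or rectangular
  0.93 x 0.7 mm imaging fields, rasterized on a 1 um grid. Tumor is a union of
  random discs ("blobs") grown until a target area fraction is reached, the
  final blob bisected so the realized fraction lands on target; the same mask
  defines compartments and the area table, so total = tumor + stroma is exact.
  Defaults: tumor fraction 0.25 with blob radii 80-160 um, i.e. tumor nests of
  160-320 um diameter occupying a quarter of a tumor-rich core. For
  cohort-level contrasts on imaging fields, larger blobs (200-350 um radius)
  represent a tumor bed with macro-scale heterogeneity, for the saturation
  reason above.
* **Placement.** Tumor cells are uniform over the tumor mask. Each non-tumor
  class starts as a homogeneous Poisson candidate process with the configured
  intensity (cells/mm^2 of core area) and is thinned by an acceptance kernel
  on the distance d to the nearest tumor cell: exp(-d/tau) for attraction,
  1 - exp(-d/tau) for repulsion, no thinning for CSR. One mixing-strength knob
  tau (um) spans both regimes. The configured intensity is deliberately the
  *candidate* intensity: attraction and repulsion modulate realized abundance
  as well as placement, which is what makes their entropy-gradient signatures
  detectable (with abundances forced equal, the pooled composition at large
  radius is balanced for any arrangement, entropy tends to its maximum, and no
  arrangement can produce the attraction signature). Under CSR the realized
  density equals the configured one in expectation.
* **Intensities.** Two log-normal components per marker (negative meanlog
  log 2, positive meanlog log 30, sdlog 0.3): non-negative, right-skewed like
  photon counts, well separated, and bimodal when pooled -- the regime the
  cutoff rules assume. A truly expressing cell draws the positive component in
  the marker's designated region only; every other marker-region value is
  background. Regulatory T-cells co-express CD4, exercising rule priority.
  PD-1/PD-L1 positivity is drawn per class with probabilities highest on
  T-helpers, then cytotoxic T-cells.
* **Annotations.** A per-marker sample of truly positive cells plus cells
  negative for everything, emulating the manual annotation step that drives
  the ECDF cutoffs.
* **Outcomes.** pCR ~ Bernoulli(plogis(intercept + coefficients . features))
  on standardized patient features; subtype and TP53 labels are sampled from
  configurable frequencies. Truth labels (class, checkpoint flags) are written
  to a separate file and never enter the analysis input.

What the generator does *not* emulate: segmentation errors, staining
artifacts, necrosis, core-to-core staining batch effects, spatially varying
background, or cell-size variation (the TIL-area term uses a nominal 50 um^2
lymphocyte footprint). Passing tests therefore demonstrate correctness of the
computations and recoverability of clean effects, not robustness to the
failure modes of real slides -- those are handled upstream by QC in any real
application.

# Cohort statistics

Two-group comparisons use the Wilcoxon rank-sum test (exact distribution when
both groups have at most 25 tie-free observations, otherwise the
tie-corrected, continuity-corrected normal approximation); more than two
groups use Kruskal-Wallis. Contingency tables of pattern by outcome use
Pearson's chi-squared when all expected counts are at least 5 and Fisher's
exact test otherwise, with the path taken reported. Correlation matrices are
pairwise-complete Spearman. All tests are two-sided at the 5% level and no
multiplicity adjustment is applied anywhere -- the layer is descriptive.

# Reproducibility and problem sizes

Every stochastic step derives from a single integer seed (the generator
stages use fixed offsets from it), and the pipeline writes flat CSVs plus a
manifest with the seed and a configuration hash; re-running with the same
configuration reproduces byte-identical outputs.

The test suite and the acceptance script verify, among others: exact
agreement of the plane-sweep pair counter with the O(n^2) oracle (200 random
point sets up to 500 cells); NMS = 1 within 5% and a flat entropy gradient
under a common homogeneous Poisson null (100 + 100 cells in a 250 um square,
500 simulations); recovery of attraction and repulsion regimes from the
entropy-gradient pattern (100 cores per regime at tau = 30 um, 500
cells/mm^2/class); >= 95% phenotype recovery on about 10^4 cells; Wilcoxon
power for a 0.5-SD log2-density shift at 100 patients/group (500
simulations); and the pCR-group NMS dominance at every ladder radius over 50
simulated cohorts of 12 + 12 imaging fields. These sizes were chosen as the
smallest at which the corresponding properties are stable.

# Known limitations

* The aggregated-entropy pattern call uses only the two smallest ladder radii;
  non-monotone entropy profiles (e.g. periodic structures) are reduced to one
  slope.
* The NMS is undefined when no two reference cells co-occur within a radius;
  sparse reference populations produce missing curve segments that downstream
  summaries exclude pairwise.
* The phenotyping rule table is a reconstruction of lineage-dominance
  conventions, not a published standard; swap in your own table where your
  panel differs.
* Cohort-level statistics are descriptive; no outcome modeling (logistic, Cox,
  survival curves) is included.
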