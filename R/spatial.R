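## Spatial colocalization statistics: normalized mixing score and
## aggregated-entropy gradient over a radius ladder, with multi-core
## stitching. Pair counting runs through a compiled plane sweep whose
## exactness against the O(n^2) oracle is asserted in the test suite.

#' Radius ladder
#'
#' Interaction radii in micrometres, by default 50 to 600 in steps of 50
#' (close-distance interactions up to whole-core scale).
#'
#' @param from,to,by Ladder limits and step (um).
#' @return Strictly increasing numeric vector of radii.
#' @export
radiusLadder <- function(from = 50, to = 600, by = 50) {
  r <- seq(from, to, by = by)
  if (any(r <= 0) || any(diff(r) <= 0)) stop("radii must be positive and strictly increasing")
  r
}

.xy <- function(points) {
  if (is.matrix(points)) {
    stopifnot(ncol(points) >= 2)
    return(points[, 1:2, drop = FALSE])
  }
  cols <- if (all(c("x_um", "y_um") %in% names(points))) c("x_um", "y_um") else c("x", "y")
  stopifnot(all(cols %in% names(points)))
  cbind(points[[cols[1]]], points[[cols[2]]])
}

#' Count reference-target and reference-reference interactions
#'
#' `I_rt` is the number of unordered reference-target pairs at Euclidean
#' distance at most `radius` (boundary inclusive); `I_rr` the number of
#' unordered distinct reference-reference pairs (self-pairs excluded).
#' Coincident points count as distinct cells.
#'
#' @param ref,tgt Point sets: two-column matrices or data frames with
#'   `x_um`/`y_um` (or `x`/`y`) columns, coordinates in um.
#' @param radius Interaction radius in um, positive.
#' @return List `I_rt`, `I_rr`, `n_r`, `n_t`.
#' @export
countInteractions <- function(ref, tgt, radius) {
  if (radius <= 0) stop("radius must be positive")
  r <- .xy(ref); t <- .xy(tgt)
  list(I_rt = .countPairsCross(r[, 1], r[, 2], t[, 1], t[, 2], radius),
       I_rr = .countPairsSelf(r[, 1], r[, 2], radius),
       n_r = nrow(r), n_t = nrow(t))
}

#' Normalized mixing score
#'
#' `NMS = [I_rt * n_r (n_r - 1) / 2] / [I_rr * n_r * n_t]`: the ratio of
#' reference-target to reference-reference interactions, normalized by the
#' ratio of maximal pair counts so that the score is about 1 under complete
#' spatial randomness regardless of cell numbers. Higher values mean stronger
#' reference-target colocalization. When `I_rr = 0` the sample carries no
#' mixing information at that radius and the score is `NA` (never infinity).
#'
#' @param counts Interaction counts from [countInteractions()].
#' @return The score, or `NA` when undefined.
#' @export
nms <- function(counts) {
  if (counts$n_r < 2) stop("need at least 2 reference cells")
  if (counts$n_t < 1) stop("need at least 1 target cell")
  if (counts$I_rr == 0) return(NA_real_)
  (counts$I_rt * counts$n_r * (counts$n_r - 1) / 2) /
    (counts$I_rr * counts$n_r * counts$n_t)
}

#' Normalized mixing score along a radius ladder
#'
#' @param ref,tgt Point sets (see [countInteractions()]).
#' @param radii Radius ladder.
#' @return Data frame `radius`, `i_rt`, `i_rr`, `value` (NA where undefined).
#' @export
nmsCurve <- function(ref, tgt, radii = radiusLadder()) {
  rows <- lapply(radii, function(r) {
    cnt <- countInteractions(ref, tgt, r)
    data.frame(radius = r, i_rt = cnt$I_rt, i_rr = cnt$I_rr, value = nms(cnt))
  })
  do.call(rbind, rows)
}

#' Aggregated entropy at one radius
#'
#' For each reference cell, reference and target cells within `radius` are
#' counted (the center cell included); the counts are pooled over all
#' reference cells into `N_ref` and `N_tgt`, and the binary Shannon entropy of
#' the pooled composition `p = N_ref / (N_ref + N_tgt)` is returned
#' (`0 log2 0 = 0`). 1 at perfect reference/target balance (high
#' colocalization), 0 when only one class is present.
#'
#' @param ref,tgt Point sets.
#' @param radius Radius in um.
#' @return Entropy in `[0, 1]`.
#' @export
aggregatedEntropy <- function(ref, tgt, radius) {
  r <- .xy(ref); t <- .xy(tgt)
  if (nrow(r) < 1) stop("need at least 1 reference cell")
  cntRR <- .countPairsSelf(r[, 1], r[, 2], radius)
  cntRT <- .countPairsCross(r[, 1], r[, 2], t[, 1], t[, 2], radius)
  nRef <- 2 * cntRR + nrow(r)  # each pair seen from both centers, plus self
  nTgt <- cntRT
  p <- nRef / (nRef + nTgt)
  h <- function(q) if (q <= 0 || q >= 1) 0 else -q * log2(q) - (1 - q) * log2(1 - q)
  h(p)
}

#' Aggregated-entropy gradient and interaction pattern
#'
#' Computes the aggregated entropy along the ladder and classifies the
#' interaction from the slope between the two smallest radii: negative slope =
#' attraction (entropy, hence colocalization, highest close to the reference
#' cells), positive = repulsion, within `eps` of zero = flat.
#'
#' @param ref,tgt Point sets.
#' @param radii Radius ladder (length >= 2).
#' @param eps Flat-slope tolerance in entropy units per um (default 1e-4).
#' @return List with `curve` (data frame `radius`, `value`), `slope` and
#'   `pattern` (`attraction`/`repulsion`/`flat`/`undefined`).
#' @export
entropyGradient <- function(ref, tgt, radii = radiusLadder(), eps = 1e-4) {
  if (length(radii) < 2) stop("radius ladder must have length >= 2")
  vals <- vapply(radii, function(r) aggregatedEntropy(ref, tgt, r), 0)
  slope <- (vals[2] - vals[1]) / (radii[2] - radii[1])
  pattern <- if (is.na(slope)) "undefined"
    else if (slope < -eps) "attraction"
    else if (slope > eps) "repulsion"
    else "flat"
  list(curve = data.frame(radius = radii, value = vals),
       slope = slope, pattern = pattern)
}

#' Stitch multiple cores into one coordinate frame
#'
#' Places the cores of one patient on a grid with pairwise boundary gaps
#' larger than `maxRadius`, so no cross-core pair can fall within any ladder
#' radius and per-core statistics are preserved on the stitched frame.
#'
#' @param cells Cell table of one patient (column `core_id`).
#' @param maxRadius Largest interaction radius that will be used (um).
#' @return `cells` with shifted coordinates; the per-core offsets are attached
#'   as attribute `"offsets"`.
#' @export
stitchCores <- function(cells, maxRadius) {
  coreIds <- unique(cells$core_id)
  k <- length(coreIds)
  if (k <= 1) {
    attr(cells, "offsets") <- data.frame(core_id = coreIds, dx = 0, dy = 0)
    return(cells)
  }
  xy <- .xy(cells)
  w <- max(tapply(xy[, 1], cells$core_id, function(v) diff(range(v))), 0)
  h <- max(tapply(xy[, 2], cells$core_id, function(v) diff(range(v))), 0)
  gap <- maxRadius + 1
  cellW <- w + gap
  cellH <- h + gap
  ncol <- ceiling(sqrt(k))
  off <- data.frame(
    core_id = coreIds,
    dx = ((seq_len(k) - 1) %% ncol) * cellW,
    dy = ((seq_len(k) - 1) %/% ncol) * cellH,
    stringsAsFactors = FALSE)
  ## anchor each core at its own bounding-box origin before offsetting
  i <- match(cells$core_id, off$core_id)
  x0 <- tapply(xy[, 1], cells$core_id, min)[coreIds]
  y0 <- tapply(xy[, 2], cells$core_id, min)[coreIds]
  newx <- xy[, 1] - x0[i] + off$dx[i]
  newy <- xy[, 2] - y0[i] + off$dy[i]
  if (all(c("x_um", "y_um") %in% names(cells))) {
    cells$x_um <- newx; cells$y_um <- newy
  } else {
    cells$x <- newx; cells$y <- newy
  }
  attr(cells, "offsets") <- off
  cells
}

.spatialCurvesDF <- function(cells, references = list(immune = c("t_helper", "cytotoxic_t", "t_regulatory", "macrophage")),
                             target = "tumor", radii = radiusLadder(), eps = 1e-4) {
  stopifnot("cell_class" %in% names(cells))
  if (is.character(references)) references <- stats::setNames(
    list(references), paste(references, collapse = "+"))
  curves <- list(); patterns <- list()
  for (p in sort(unique(cells$patient_id))) {
    cc <- stitchCores(cells[cells$patient_id == p, ], max(radii))
    tgt <- cc[cc$cell_class %in% target, ]
    for (refName in names(references)) {
      ref <- cc[cc$cell_class %in% references[[refName]], ]
      if (nrow(ref) < 2 || nrow(tgt) < 1) {
        patterns[[length(patterns) + 1L]] <- data.frame(
          patient_id = p, reference = refName, slope = NA_real_,
          pattern = "undefined", stringsAsFactors = FALSE)
        next
      }
      nmsDf <- nmsCurve(ref, tgt, radii)
      eg <- entropyGradient(ref, tgt, radii, eps)
      curves[[length(curves) + 1L]] <- rbind(
        data.frame(patient_id = p, reference = refName, metric = "nms",
                   radius = nmsDf$radius, value = nmsDf$value,
                   stringsAsFactors = FALSE),
        data.frame(patient_id = p, reference = refName, metric = "entropy",
                   radius = eg$curve$radius, value = eg$curve$value,
                   stringsAsFactors = FALSE))
      patterns[[length(patterns) + 1L]] <- data.frame(
        patient_id = p, reference = refName, slope = eg$slope,
        pattern = eg$pattern, stringsAsFactors = FALSE)
    }
  }
  list(curves = do.call(rbind, curves), patterns = do.call(rbind, patterns))
}
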