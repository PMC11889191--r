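test_that("interaction counts match hand-computed and brute-force values", {
  ref <- cbind(c(0, 10), c(0, 0))
  tgt <- cbind(0, 5)
  cnt <- countInteractions(ref, tgt, 10)
  expect_equal(cnt$I_rt, 1)  # distances 5 and ~11.18
  expect_equal(cnt$I_rr, 1)  # distance exactly 10: boundary inclusive
  expect_equal(cnt$n_r, 2)
  expect_equal(cnt$n_t, 1)

  ## radius below every pairwise distance
  cnt0 <- countInteractions(ref, tgt, 1)
  expect_equal(cnt0$I_rt, 0)
  expect_equal(cnt0$I_rr, 0)

  ## coincident points are distinct cells
  dup <- cbind(c(1, 1, 1), c(2, 2, 2))
  expect_equal(countInteractions(dup, dup, 0.5)$I_rr, 3)
  expect_equal(countInteractions(dup, dup, 0.5)$I_rt, 9)

  expect_error(countInteractions(ref, tgt, -1), "positive")
})

test_that("plane-sweep counting equals the O(n^2) oracle on random patterns", {
  set.seed(55)
  for (i in 1:30) {
    nr <- sample(2:300, 1); nt <- sample(1:300, 1)
    ref <- cbind(runif(nr, 0, 500), runif(nr, 0, 500))
    tgt <- cbind(runif(nt, 0, 500), runif(nt, 0, 500))
    r <- runif(1, 5, 300)
    cnt <- countInteractions(ref, tgt, r)
    expect_identical(cnt$I_rt, bruteCountCross(ref, tgt, r))
    expect_identical(cnt$I_rr, bruteCountSelf(ref, r))
  }
})

test_that("NMS arithmetic, undefined cases, and rigid-motion invariance", {
  cnt <- countInteractions(cbind(c(0, 10), c(0, 0)), cbind(0, 5), 10)
  expect_equal(nms(cnt), 0.5)

  expect_equal(nms(list(I_rt = 0, I_rr = 3, n_r = 5, n_t = 4)), 0)
  expect_true(is.na(nms(list(I_rt = 2, I_rr = 0, n_r = 5, n_t = 4))))
  expect_error(nms(list(I_rt = 0, I_rr = 0, n_r = 1, n_t = 4)), "reference")

  set.seed(66)
  ref <- cbind(runif(80, 0, 300), runif(80, 0, 300))
  tgt <- cbind(runif(60, 0, 300), runif(60, 0, 300))
  v0 <- nms(countInteractions(ref, tgt, 75))
  th <- 0.7; R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2)
  move <- function(p) sweep(p %*% R, 2, c(-120, 45), "+")
  expect_equal(nms(countInteractions(move(ref), move(tgt), 75)), v0)
  ## relabeling / reordering cells changes nothing
  expect_equal(nms(countInteractions(ref[sample(80), ], tgt[sample(60), ], 75)), v0)
})

test_that("NMS curves contain monotone pair counts over the ladder", {
  set.seed(77)
  ref <- cbind(runif(100, 0, 600), runif(100, 0, 600))
  tgt <- cbind(runif(100, 0, 600), runif(100, 0, 600))
  cv <- nmsCurve(ref, tgt, radiusLadder())
  expect_equal(nrow(cv), 12)
  expect_true(all(diff(cv$i_rt) >= 0))
  expect_true(all(diff(cv$i_rr) >= 0))
  single <- nmsCurve(ref, tgt, 100)
  expect_equal(nrow(single), 1)
  expect_error(radiusLadder(by = -50))
  expect_error(radiusLadder(from = -50, to = 100, by = 50), "positive")
})

test_that("aggregated entropy: pooled counts with the center cell included", {
  ref <- cbind(c(0, 1), c(0, 0))
  tgt <- cbind(c(0, 1), c(1, 1))
  ## all four cells within radius 2 of each reference: N_ref = 4, N_tgt = 4
  expect_equal(aggregatedEntropy(ref, tgt, 2), 1.0)
  ## no targets in range: single-class neighborhood has zero entropy
  expect_equal(aggregatedEntropy(ref, tgt[0, , drop = FALSE], 2), 0)
  expect_equal(aggregatedEntropy(ref, tgt + 1000, 2), 0)
  ## symmetric composition: swapping the class counts leaves H unchanged
  expect_equal(aggregatedEntropy(tgt, ref, 2), aggregatedEntropy(ref, tgt, 2))
  expect_error(aggregatedEntropy(ref[0, , drop = FALSE], tgt, 2), "reference")
})

test_that("entropy gradient slope classifies attraction, repulsion and flat", {
  set.seed(7)
  ## paired ref/target at the same sites, pairs far apart: entropy 1 at every
  ## radius below the pair spacing -> flat
  g <- expand.grid(x = seq(0, 2000, by = 400), y = seq(0, 2000, by = 400))
  eg <- entropyGradient(g, g, radii = c(50, 100))
  expect_equal(eg$slope, 0)
  expect_identical(eg$pattern, "flat")

  ## target-rich neighborhoods that dilute with radius -> negative slope
  ref1 <- cbind(c(0, 3000), c(0, 0))
  tgt1 <- rbind(cbind(runif(40, -60, 60), runif(40, -60, 60)),
                cbind(3000 + runif(40, -60, 60), runif(40, -60, 60)))
  eg1 <- entropyGradient(ref1, tgt1, radii = c(50, 100))
  expect_identical(eg1$pattern, "attraction")

  ## targets only reachable at the larger radius -> positive slope
  ref2 <- cbind(runif(30, 0, 50), runif(30, 0, 50))
  tgt2 <- cbind(150 + runif(30, 0, 20), runif(30, 0, 50))
  eg2 <- entropyGradient(ref2, tgt2, radii = c(50, 200))
  expect_identical(eg2$pattern, "repulsion")

  expect_error(entropyGradient(ref1, tgt1, radii = 50), "length")
})

test_that("stitched cores keep cross-core pairs out of every ladder radius", {
  set.seed(88)
  mk <- function(core, n) data.frame(
    cell_id = sprintf("%s_%d", core, 1:n), patient_id = "P1", core_id = core,
    x_um = runif(n, 0, 600), y_um = runif(n, 0, 600),
    cell_class = sample(c("tumor", "cytotoxic_t"), n, TRUE))
  one <- mk("c1", 50)
  same <- stitchCores(one, 600)
  expect_equal(same$x_um, one$x_um)
  expect_equal(attr(same, "offsets")$dx, 0)

  for (i in 1:20) {
    cells <- rbind(mk("c1", sample(20:60, 1)), mk("c2", sample(20:60, 1)),
                   mk("c3", sample(20:60, 1)))
    st <- stitchCores(cells, 600)
    ## minimum distance between cells of different cores exceeds the ladder max
    xy <- cbind(st$x_um, st$y_um)
    d <- as.matrix(dist(xy))
    cross <- outer(st$core_id, st$core_id, "!=")
    expect_gt(min(d[cross]), 600)
    ## stitched-frame counts equal the sum of per-core counts
    for (r in c(100, 600)) {
      tot <- countInteractions(xy[st$cell_class == "cytotoxic_t", , drop = FALSE],
                               xy[st$cell_class == "tumor", , drop = FALSE], r)
      perCore <- lapply(unique(cells$core_id), function(cid) {
        cc <- cells[cells$core_id == cid, ]
        countInteractions(cbind(cc$x_um, cc$y_um)[cc$cell_class == "cytotoxic_t", , drop = FALSE],
                          cbind(cc$x_um, cc$y_um)[cc$cell_class == "tumor", , drop = FALSE], r)
      })
      expect_equal(tot$I_rt, sum(vapply(perCore, `[[`, 0, "I_rt")))
      expect_equal(tot$I_rr, sum(vapply(perCore, `[[`, 0, "I_rr")))
    }
  }
})

test_that("patient-level curves carry both metrics and undefined patterns", {
  set.seed(99)
  n <- 80
  cells <- data.frame(
    cell_id = sprintf("c%03d", 1:n), patient_id = rep(c("P1", "P2"), each = n / 2),
    core_id = rep(c("P1_c1", "P2_c1"), each = n / 2),
    x_um = runif(n, 0, 400), y_um = runif(n, 0, 400),
    cell_class = sample(c("tumor", "cytotoxic_t", "t_helper"), n, TRUE))
  res <- spatialCurves(cells, references = list(ctl = "cytotoxic_t"),
                       radii = radiusLadder(100, 300, 100))
  expect_setequal(unique(res$curves$metric), c("nms", "entropy"))
  expect_equal(nrow(res$patterns), 2)
  expect_true(all(res$curves$value[res$curves$metric == "entropy"] >= 0 &
                  res$curves$value[res$curves$metric == "entropy"] <= 1))

  ## a patient without enough reference cells is reported as undefined
  lone <- cells[cells$patient_id == "P1" & cells$cell_class != "cytotoxic_t", ]
  res2 <- spatialCurves(lone, references = list(ctl = "cytotoxic_t"),
                        radii = radiusLadder(100, 300, 100))
  expect_identical(res2$patterns$pattern, "undefined")
})
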