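test_that("intensity normalization is photons per unit exposure", {
  expect_identical(normalizeIntensity(1000, 2), 500)
  expect_identical(normalizeIntensity(0, 5), 0)
  expect_error(normalizeIntensity(1000, 0), "positive")
  expect_error(normalizeIntensity(-1, 1), "non-negative")
})

test_that("ECDF cutoff uses the minimal signal on steep monotone samples", {
  res <- ecdfCutoff(c(5.0, 6.2, 7.1), background = c(0.4, 1.3))
  expect_identical(res$cutoff, 5.0)
  expect_identical(res$method, "ecdf_min")
  expect_identical(res$diagnostics$backgroundExceedance, 0)

  deg <- ecdfCutoff(rep(4.2, 10))
  expect_identical(deg$cutoff, 4.2)
  expect_identical(deg$method, "ecdf_min")

  expect_error(ecdfCutoff(c(1, 2)), "at least 3")
})

test_that("low-level outliers move the cutoff to the kneepoint of the ECDF", {
  set.seed(17)
  mass <- stats::rnorm(200, mean = 10, sd = 1)
  outliers <- stats::runif(5, 0.4, 0.6)
  x <- c(mass, outliers)
  res <- ecdfCutoff(x)
  expect_identical(res$method, "kneepoint")
  ## cutoff sits above the outliers, inside the low edge of the main mass
  expect_gt(res$cutoff, max(outliers))
  expect_lt(res$cutoff, stats::median(mass))
  ## exact agreement with a brute-force kneedle search over all ECDF points
  oracle <- bruteKnee(x)
  expect_identical(res$cutoff, oracle$x[oracle$index])
  expect_equal(res$diagnostics$kneeScore, oracle$score)
  ## the outliers are called negative at this cutoff
  expect_true(all(outliers < res$cutoff))
})

test_that("Otsu cutoff separates bimodal samples and matches the exhaustive search", {
  x <- c(1, 1, 2, 8, 9, 9)
  cut <- otsuCutoff(x)
  expect_identical(x >= cut, c(FALSE, FALSE, FALSE, TRUE, TRUE, TRUE))

  sep <- otsuCutoff(c(rep(0, 50), rep(10, 50)))
  expect_true(sep > 0 && sep <= 10)
  expect_identical(c(rep(0, 50), rep(10, 50)) >= sep, rep(c(FALSE, TRUE), each = 50))

  expect_error(otsuCutoff(rep(3, 10)), "distinct")

  set.seed(42)
  for (i in 1:25) {
    y <- c(stats::rlnorm(300, 1, 0.4), stats::rlnorm(200 + 50 * (i %% 4), 4, 0.4))
    expect_identical(otsuCutoff(y), bruteOtsu(y))
  }
})

test_that("Otsu recovers the generating components of a lognormal mixture", {
  set.seed(7)
  x <- c(stats::rlnorm(5000, 1, 0.3), stats::rlnorm(5000, 4, 0.3))
  truth <- rep(c(FALSE, TRUE), each = 5000)
  cut <- otsuCutoff(x)
  expect_gte(mean((x >= cut) == truth), 0.95)
})

test_that("cutoff application is inclusive, deterministic and order-invariant", {
  cutoffs <- data.frame(marker = c("CK", "FoxP3"),
                        region = c("cytoplasm", "nucleus"),
                        method = "manual", cutoff = c(10, 5))
  cells <- data.frame(cell_id = c("a", "b", "c"),
                      CK_cytoplasm = c(10, 9.999, 20),
                      FoxP3_nucleus = c(5, 4, 0))
  calls <- applyCutoffs(cells, cutoffs)
  expect_identical(calls["a", ], c(CK = TRUE, FoxP3 = TRUE))  # boundary is positive
  expect_identical(calls["b", ], c(CK = FALSE, FoxP3 = FALSE))
  expect_identical(unname(calls["c", "FoxP3"]), FALSE)

  ## random table equals a brute-force per-cell loop, regardless of row order
  set.seed(9)
  n <- 200
  rnd <- data.frame(cell_id = sprintf("c%03d", 1:n),
                    CK_cytoplasm = stats::rlnorm(n, 2, 1),
                    FoxP3_nucleus = stats::rlnorm(n, 1, 1))
  callsRnd <- applyCutoffs(rnd, cutoffs)
  for (i in seq_len(n)) {
    expect_identical(unname(callsRnd[i, "CK"]), rnd$CK_cytoplasm[i] >= 10)
    expect_identical(unname(callsRnd[i, "FoxP3"]), rnd$FoxP3_nucleus[i] >= 5)
  }
  shuf <- rnd[sample(n), ]
  expect_identical(applyCutoffs(shuf, cutoffs)[rnd$cell_id, ], callsRnd)

  ## flagged low-level outliers are forced negative
  forced <- applyCutoffs(cells, cutoffs,
                         negativeOverrides = data.frame(cell_id = "a", marker = "CK"))
  expect_false(forced["a", "CK"])

  expect_error(applyCutoffs(cells[, 1:2], cutoffs), "missing intensity column")
})

test_that("the rule engine matches a truth-table enumeration over all call vectors", {
  grid <- expand.grid(CK = c(FALSE, TRUE), CD68 = c(FALSE, TRUE),
                      FoxP3 = c(FALSE, TRUE), CD8 = c(FALSE, TRUE),
                      CD4 = c(FALSE, TRUE), PD1 = c(FALSE, TRUE),
                      PDL1 = c(FALSE, TRUE))
  calls <- callMatrix(grid)
  got <- classifyCells(calls)
  want <- mapply(ruleOracle, grid$CK, grid$CD68, grid$FoxP3, grid$CD8, grid$CD4)
  expect_identical(got$cell_class, unname(want))
  ## every cell gets exactly one class; checkpoint flags are orthogonal
  expect_false(anyNA(got$cell_class))
  expect_identical(got$pd1_pos, unname(calls[, "PD1"]))
  expect_identical(got$pdl1_pos, unname(calls[, "PDL1"]))
})

test_that("specific phenotype calls follow lineage-marker dominance", {
  calls <- callMatrix(data.frame(
    CK = c(TRUE, FALSE, FALSE), CD68 = FALSE, FoxP3 = c(FALSE, FALSE, TRUE),
    CD8 = c(FALSE, TRUE, FALSE), CD4 = c(FALSE, FALSE, TRUE),
    PD1 = c(FALSE, TRUE, FALSE), PDL1 = FALSE))
  got <- classifyCells(calls)
  expect_identical(got$cell_class, c("tumor", "cytotoxic_t", "t_regulatory"))
  expect_identical(got$pd1_pos, c(FALSE, TRUE, FALSE))  # CD8+PD-1+ keeps its flag
  expect_error(
    classifyCells(calls, rules = data.frame(class = "x", requires_pos = "CD3",
                                            requires_neg = "")),
    "unknown marker")
})

test_that("marker cutoffs route CK to Otsu and annotated markers to the ECDF rule", {
  cfg <- simConfig(nPatients = 2, coresPerPatient = 1, seed = 51L)
  sim <- simulateCohort(cfg)
  cuts <- markerCutoffs(sim$cells, sim$annotations)
  expect_identical(cuts$method[cuts$marker == "CK"], "otsu")
  expect_true(all(cuts$method[cuts$marker != "CK"] %in% c("ecdf_min", "kneepoint")))
  expect_identical(cuts$region[cuts$marker == "FoxP3"], "nucleus")
  expect_identical(cuts$region[cuts$marker == "CD4"], "whole")
  expect_true(all(cuts$region[!cuts$marker %in% c("FoxP3", "CD4")] == "cytoplasm"))
  expect_true(all(cuts$cutoff >= 0))
})
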