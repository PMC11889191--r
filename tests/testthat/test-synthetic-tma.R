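test_that("seeded generation is reproducible and validated", {
  cfg <- quickConfig(seed = 11L)
  a <- generateCores(cfg)
  b <- generateCores(cfg)
  expect_identical(a, b)

  expect_error(simConfig(tumorFraction = 0), "tumorFraction")
  expect_error(simConfig(tumorFraction = 1.2), "tumorFraction")
  expect_error(simConfig(cellDensity = c(tumor = -5)), "non-negative")
  expect_error(simConfig(coresPerPatient = 4), "coresPerPatient")
})

test_that("tumor blob geometry hits the requested area fraction", {
  cfg <- simConfig(nPatients = 1, coresPerPatient = 1, tumorFraction = 0.5,
                   cellDensity = c(tumor = 100), seed = 3L)
  sim <- generateCores(cfg)
  discArea <- pi * 0.3^2
  expect_equal(sim$areas$tumor_area_mm2, 0.5 * discArea, tolerance = 0.02)
  ## area bookkeeping comes from one shared mask, so the identity is exact
  expect_identical(sim$areas$total_area_mm2,
                   sim$areas$tumor_area_mm2 + sim$areas$stroma_area_mm2)
})

test_that("cells respect the core geometry and the compartment masks", {
  cfg <- simConfig(nPatients = 2, coresPerPatient = 2, seed = 5L)
  sim <- generateCores(cfg)
  r <- 300
  d <- sqrt((sim$cells$x_um - r)^2 + (sim$cells$y_um - r)^2)
  expect_true(all(d <= r + 1))  # 1 um mask discretization slack
  ## tumor cells are placed only inside tumor blobs
  tum <- sim$truth$true_class[match(sim$cells$cell_id, sim$truth$cell_id)] == "tumor"
  expect_true(all(sim$cells$compartment[tum] == "tumor"))
})

test_that("attraction pulls immune cells toward tumor cells relative to csr", {
  medNearest <- function(regime, seed) {
    sim <- generateCores(quickConfig(mixingRegime = regime, mixingStrength = 30,
                                     seed = seed))
    cls <- sim$truth$true_class[match(sim$cells$cell_id, sim$truth$cell_id)]
    tum <- sim$cells[cls == "tumor", ]
    imm <- sim$cells[cls == "cytotoxic_t", ]
    if (nrow(imm) == 0 || nrow(tum) == 0) return(NA_real_)
    d <- sqrt(outer(imm$x_um, tum$x_um, "-")^2 + outer(imm$y_um, tum$y_um, "-")^2)
    stats::median(apply(d, 1, min))
  }
  seeds <- 1:100
  att <- vapply(seeds, function(s) medNearest("attraction", s), 0)
  csr <- vapply(seeds, function(s) medNearest("csr", s + 1000L), 0)
  expect_lt(stats::median(att, na.rm = TRUE), stats::median(csr, na.rm = TRUE))
})

test_that("intensities follow the two-component region-specific models", {
  cfg <- quickConfig(seed = 21L)
  ## degenerate noise: the components are perfectly separable
  sharp <- cfg
  sharp$markerModels <- defaultMarkerModels(negMeanLog = log(1), negSdLog = 1e-8,
                                            posMeanLog = log(100), posSdLog = 1e-8)
  sim <- generateCores(sharp)
  cells <- generateIntensities(sim$cells, sim$truth, sharp)
  isCd8 <- sim$truth$true_class[match(cells$cell_id, sim$truth$cell_id)] == "cytotoxic_t"
  expect_true(all(cells$CD8_cytoplasm[isCd8] > 50))
  expect_true(all(cells$CD8_cytoplasm[!isCd8] < 50))

  ## FoxP3 positivity is confined to the nuclear region
  cfg2 <- simConfig(nPatients = 1, coresPerPatient = 1,
                    coreShape = coreShapeRect(0.3, 0.3),
                    cellDensity = c(tumor = 300, t_regulatory = 300), seed = 22L)
  sim2 <- generateCores(cfg2)
  cells2 <- generateIntensities(sim2$cells, sim2$truth, cfg2)
  treg <- sim2$truth$true_class[match(cells2$cell_id, sim2$truth$cell_id)] == "t_regulatory"
  negMax <- exp(log(2) + 5 * 0.3)  # far tail of the negative component
  expect_true(all(cells2$FoxP3_cytoplasm < negMax))
  expect_gt(stats::median(cells2$FoxP3_nucleus[treg]), negMax)

  expect_error(generateIntensities(sim2$cells, sim2$truth, cfg2, markers = "CD3"),
               "no intensity model")
})

test_that("pooled CK intensities are bimodal", {
  cfg <- simConfig(nPatients = 2, coresPerPatient = 1,
                   coreShape = coreShapeRect(0.93, 0.7),
                   cellDensity = c(tumor = 800, cytotoxic_t = 800), seed = 31L)
  sim <- generateCores(cfg)
  cells <- generateIntensities(sim$cells, sim$truth, cfg, markers = "CK")
  x <- log(cells$CK_cytoplasm)
  suppressMessages(library(mclust))
  fit1 <- Mclust(x, G = 1, verbose = FALSE)
  fit2 <- Mclust(x, G = 2, modelNames = "V", verbose = FALSE)
  expect_gt(fit2$bic - fit1$bic, 10)  # decisive evidence for two components
})

test_that("outcome generation follows the logistic model", {
  base <- quickConfig(seed = 41L)
  feats <- matrix(0, nrow = 1e4, ncol = 0)
  out <- generateOutcomes(feats, base)
  expect_equal(mean(out$pcr), 0.5, tolerance = 0.013)  # binomial 99% CI at n = 1e4

  allNeg <- base
  allNeg$outcomeModel$intercept <- -40
  expect_true(all(generateOutcomes(feats, allNeg)$pcr == 0))

  lifted <- base
  lifted$outcomeModel <- list(intercept = 0, coefficients = c(nms = 1))
  set.seed(123)
  wins <- vapply(1:50, function(s) {
    cfgS <- lifted; cfgS$seed <- s
    f <- matrix(stats::rnorm(200), dimnames = list(NULL, "nms"))
    o <- generateOutcomes(f, cfgS)
    stats::median(f[o$pcr == 1, 1]) > stats::median(f[o$pcr == 0, 1])
  }, TRUE)
  expect_gte(sum(wins), 48)

  bad <- base
  bad$outcomeModel <- list(intercept = 0, coefficients = c(unknown_feature = 1))
  expect_error(generateOutcomes(feats, bad), "coefficients")
})
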