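test_that("a zero mutation rate yields only monomorphic blocks", {
  m <- onePopModel(mu = 0)
  lay <- sampleLayout(2, blockLength = 1000)
  tab <- simulateDataset(simulationSpec(m, lay, 200, seed = 31))
  expect_equal(totalBlocks(tab), 200)
  expect_equal(nrow(configMatrix(tab)), 1)
  expect_true(all(configMatrix(tab) == 0))
})

test_that("the empirical pairwise bSFS matches the geometric law", {
  m <- onePopModel()
  lay <- layoutWithTheta(m, theta = 1, sampleSizes = 2)
  n <- 30000
  tab <- simulateDataset(simulationSpec(m, lay, n, seed = 32))
  counts <- configCounts(tab)
  for (k in 0:4) {
    p <- geomBsfs(k, 1)
    obs <- sum(counts[names(counts) == as.character(k)])
    se <- sqrt(n * p * (1 - p))
    expect_lt(abs(obs - n * p), 3 * se + 1)
  }
})

test_that("mean block diversity matches the model's scaled mutation rate", {
  m <- onePopModel()
  lay <- layoutWithTheta(m, theta = 0.8, sampleSizes = 2)
  n <- 10000
  tab <- simulateDataset(simulationSpec(m, lay, n, seed = 33))
  k <- as.numeric(names(configCounts(tab)))
  meanK <- sum(k * configCounts(tab)) / n
  # E[k] = theta, Var[k] = theta + 2 theta^2 for the pairwise sample
  se <- sqrt((0.8 + 2 * 0.8^2) / n)
  expect_lt(abs(meanK - 0.8), 3 * se)
})

test_that("stretch linkage with one block per stretch degenerates to unlinked", {
  f <- m2Fixture()
  a <- simulateDataset(simulationSpec(f$model, f$lay, 500, seed = 34))
  b <- simulateDataset(simulationSpec(f$model, f$lay, 500,
                                      linkage = "stretches",
                                      stretchLength = 2000, seed = 34))
  expect_equal(configCounts(a), configCounts(b))
})

test_that("stretch-linked blocks keep the unlinked marginal expectations", {
  f <- m2Fixture()
  n <- 4000
  a <- simulateDataset(simulationSpec(f$model, f$lay, n, seed = 35))
  b <- simulateDataset(simulationSpec(f$model, f$lay, n,
                                      linkage = "stretches",
                                      stretchLength = 50 * 2000,
                                      seed = 36))
  meanSnps <- function(tab) {
    K <- configMatrix(tab)
    sum(rowSums(K) * tab@counts) / totalBlocks(tab)
  }
  # marginal per-block expectations agree; only cross-block covariance
  # differs, so compare means with a generous linked-data standard error
  expect_lt(abs(meanSnps(a) - meanSnps(b)), 0.12 * meanSnps(a))
  expect_equal(totalBlocks(b), n)
})

test_that("record output reproduces the tabulated spectrum pathway", {
  m <- onePopModel()
  lay <- layoutWithTheta(m, theta = 1, sampleSizes = c(2))
  rec <- simulateDataset(simulationSpec(m, lay, 2000, seed = 37),
                         output = "records")
  expect_length(rec$blocks, 2000)
  tab <- tabulateBlocks(rec$blocks, lay)
  expect_equal(totalBlocks(tab), 2000)
  # mean segregating sites close to theta
  k <- as.numeric(names(configCounts(tab)))
  meanK <- sum(k * configCounts(tab)) / 2000
  expect_lt(abs(meanK - 1), 3 * sqrt(3 / 2000))
  # positions are distinct integers within the callable length
  g <- Filter(Negate(is.null), rec$blocks)[[1]]
  pos <- attr(g, "positions")
  expect_false(anyDuplicated(pos) > 0)
  expect_true(all(pos >= 1 & pos <= effectiveLength(lay)))
})

test_that("records support the cbSFS path end to end", {
  f <- m2Fixture()
  rec <- simulateDataset(simulationSpec(f$model, f$lay, 300, seed = 38),
                         output = "records")
  sch <- subsamplingScheme(f$lay, "consecutive", unitSize = 2)
  pooled <- buildCbsfs(rec$blocks, sch, f$lay)
  expect_equal(totalBlocks(pooled), 300)
  expect_equal(sampleSizes(tableLayout(pooled)), c(2L, 2L))
})

test_that("a deterministic surrogate bootstrap has zero variance", {
  tpl <- modelTemplate("onePop")
  center <- c(N_e = 8000)
  res <- parametricBootstrap(center, tpl, layout = sampleLayout(2),
                             numBlocks = 10, replicates = 4,
                             localSpec = searchSpec("local",
                                                    argsPerEval = 1,
                                                    replicates = 1,
                                                    evalBudget = 150,
                                                    seed = 39),
                             seed = 40,
                             objective = function(p)
                               -((log(p[["N_e"]]) - log(8000))^2))
  expect_lt(res$sd[["N_e"]], 8000 * 1e-3)
  expect_equal(nrow(res$estimates), 4)
  expect_true(all(res$ci["lower", ] <= res$ci["upper", ]))
})

test_that("nested models never fit simulated data better than the truth on average", {
  f <- m2Fixture()
  tplM1 <- modelTemplate("M1", fixed = c(r = 2e-8))
  exp <- misspecificationExperiment(
    trueModels = list(M2 = list(template = f$tpl, params = f$truth)),
    fitModels = list(
      M2 = list(template = f$tpl, params = f$truth),
      M1 = list(template = tplM1,
                params = c(N_A = f$truth[["N_A"]], T = f$truth[["T"]]))),
    datasetsPerModel = 3, layout = f$lay, numBlocks = 3000,
    settings = likelihoodSettings(400), seed = 41)
  byModel <- tapply(exp$loglik, exp$candidate, median)
  expect_gte(byModel[["M2"]], byModel[["M1"]])
  expect_equal(nrow(exp), 6)
})

test_that("every simulation is reproducible from its seed", {
  f <- m2Fixture()
  a <- simulateDataset(simulationSpec(f$model, f$lay, 100, seed = 42))
  b <- simulateDataset(simulationSpec(f$model, f$lay, 100, seed = 42))
  expect_identical(configCounts(a), configCounts(b))
  r1 <- simulateDataset(simulationSpec(f$model, f$lay, 30, seed = 43),
                        output = "records")
  r2 <- simulateDataset(simulationSpec(f$model, f$lay, 30, seed = 43),
                        output = "records")
  expect_identical(r1$blocks, r2$blocks)
})
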