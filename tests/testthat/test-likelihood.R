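test_that("configuration probabilities follow the Poisson product and zero-branch rules", {
  expect_equal(configProbGivenLengths(0, 2, theta = 1), exp(-2))
  expect_equal(configProbGivenLengths(3, 2, theta = 1), dpois(3, 2))
  # all classes of zero length: the monomorphic configuration is certain
  expect_equal(configProbGivenLengths(c(0, 0), c(0, 0), theta = 1), 1)
  # mutations on a zero-length class are impossible
  expect_equal(configProbGivenLengths(c(2, 0), c(0, 1), theta = 1), 0)
  # lumped entry takes the upper tail
  expect_equal(configProbGivenLengths(-1, 3, theta = 1, kmax = 4),
               ppois(4, 3, lower.tail = FALSE))
  # product across classes
  expect_equal(configProbGivenLengths(c(1, 2), c(0.5, 1.5), theta = 2),
               dpois(1, 1) * dpois(2, 3))
})

test_that("a single fixed ARG collapses the Monte-Carlo mean exactly", {
  lay <- sampleLayout(c(2, 2), blockLength = 1000)
  K <- rbind(c(0, 0, 0, 0), c(1, 0, 0, 0), c(0, 1, 2, 0))
  tab <- bsfsTable(lay, K, c(10, 4, 1))
  t1 <- matrix(c(1.2, 0.3, 0.9, 0.4), 1)
  m <- imModel()
  res <- approximateConfigProbs(tab, m, likelihoodSettings(1),
                                draws = structure(t1, thetaBlock = 0.8))
  byHand <- vapply(seq_len(nrow(K)), function(j)
    configProbGivenLengths(K[j, ], t1[1, ], 0.8), 0)
  expect_equal(unname(res$perConfig), byHand)
  expect_equal(res$loglik, sum(c(10, 4, 1) * log(byHand)))
  expect_lte(res$loglik, 0)
})

test_that("the Monte-Carlo bSFS converges to the pairwise geometric law", {
  m <- onePopModel()
  lay <- layoutWithTheta(m, theta = 1, sampleSizes = 2)
  M <- 10000
  draws <- sampleArgs(m, lay, M, seed = 201)
  K <- matrix(0:7, ncol = 1)
  tab <- bsfsTable(lay, K, rep(1, 8))
  p <- approximateConfigProbs(tab, m, likelihoodSettings(M),
                              draws = draws)$perConfig
  truth <- geomBsfs(0:7, 1)
  # per-draw probabilities are bounded by 1, so Var(p-hat) <= p/M
  expect_true(all(abs(p - truth) < 3 * sqrt(truth / M) + 1e-6))
})

test_that("lumped probabilities sum to one for any fixed ARG and k_max", {
  lay <- sampleLayout(c(2, 2), blockLength = 1000)
  set.seed(202)
  for (km in c(0, 1, 4, 25)) {
    t1 <- runif(4, 0, 3)
    t1[sample(4, 1)] <- 0 # exercise the zero-branch convention
    p <- lumpedProbsGivenLengths(t1, lay, km, theta = 0.7)
    expect_lt(abs(sum(p) - 1), 1e-12)
  }
  # and for the Monte-Carlo average over many ARGs
  p <- exhaustiveLumpedProbs(imModel(), lay, 3,
                             likelihoodSettings(200, seed = 203))
  expect_lt(abs(sum(p) - 1), 1e-12)
})

test_that("the non-recombining enumeration captures all mass at rho = 0", {
  lay <- sampleLayout(c(2, 2), blockLength = 1000)
  draws <- sampleArgs(imModel(), lay, 100, seed = 204)
  pFull <- lumpedProbsGivenLengths(draws, lay, 4, theta = 1)
  pNoRec <- lumpedProbsGivenLengths(draws, lay, 4, theta = 1,
                                    noRecombination = TRUE)
  expect_lt(abs(sum(pFull) - 1), 1e-12)
  # excluded configurations carry zero probability on single genealogies
  expect_lt(abs(sum(pNoRec) - 1), 1e-12)
})

test_that("the composite log-likelihood is additive and exchangeable", {
  lay <- sampleLayout(c(2, 2), blockLength = 1000)
  m <- imModel()
  draws <- sampleArgs(m, lay, 300, seed = 205)
  K <- rbind(c(0, 0, 0, 0), c(1, 0, 0, 0), c(0, 0, 1, 0), c(2, 1, 0, 0))
  n <- c(50, 10, 7, 2)
  tabAll <- bsfsTable(lay, K, n)
  s <- likelihoodSettings(300)
  llAll <- approximateConfigProbs(tabAll, m, s, draws = draws)$loglik
  # partition the counts
  tabA <- bsfsTable(lay, K, c(30, 4, 7, 0))
  tabB <- bsfsTable(lay, K, c(20, 6, 0, 2))
  llA <- approximateConfigProbs(tabA, m, s, draws = draws)$loglik
  llB <- approximateConfigProbs(tabB, m, s, draws = draws)$loglik
  expect_equal(llAll, llA + llB, tolerance = 1e-10)
  # permuting table rows changes nothing
  perm <- c(3, 1, 4, 2)
  tabP <- bsfsTable(lay, K[perm, ], n[perm])
  expect_equal(approximateConfigProbs(tabP, m, s, draws = draws)$loglik,
               llAll, tolerance = 1e-12)
})

test_that("the rho = 0 ARG path equals single-tree sampling draw for draw", {
  m <- imModel(T = 1.2, M = 0.5, r = 0)
  lay <- sampleLayout(c(2, 2), blockLength = 1000)
  a <- sampleArgs(m, lay, 500, seed = 206)
  b <- sampleArgs(m, lay, 500, seed = 206, singleTree = TRUE)
  expect_identical(unclass(a), unclass(b))
  tab <- bsfsTable(lay, rbind(c(0, 0, 0, 0), c(1, 1, 0, 0)), c(8, 2))
  s <- likelihoodSettings(500, seed = 206)
  expect_equal(blockLoglik(tab, m, s), blockLoglik(tab, m, s))
  expect_error(sampleArgs(imModel(r = 1e-8), lay, 5, singleTree = TRUE),
               "recombination")
})

test_that("observed configurations with zero Monte-Carlo mass are floored and flagged", {
  lay <- sampleLayout(c(2, 2), blockLength = 1000)
  m <- imModel(r = 0)
  # shared polymorphism and fixed difference cannot co-occur at rho = 0
  impossible <- c(0, 1, 0, 1)
  tab <- bsfsTable(lay, rbind(c(0, 0, 0, 0), impossible), c(10, 1))
  res <- approximateConfigProbs(tab, m, likelihoodSettings(200, seed = 207))
  expect_equal(res$zeroMassConfigs, 1)
  expect_equal(unname(res$perConfig[2]), 1 / (10 * 200))
  expect_true(is.finite(res$loglik))
})

test_that("likelihood noise shrinks like one over the square root of the ARG count", {
  m <- onePopModel()
  lay <- layoutWithTheta(m, theta = 1, sampleSizes = 2)
  K <- matrix(0:5, ncol = 1)
  tab <- bsfsTable(lay, K, c(500, 250, 125, 60, 30, 35))
  Ms <- c(1000, 10000, 100000)
  sds <- vapply(Ms, function(M) {
    lls <- vapply(1:8, function(r)
      blockLoglik(tab, m, likelihoodSettings(M, seed = 300 + r)), 0)
    sd(lls)
  }, 0)
  slope <- coef(lm(log(sds) ~ log(Ms)))[2]
  expect_gt(slope, -0.7)
  expect_lt(slope, -0.3)
})

test_that("Watterson's theta summarizes per-population block diversity", {
  # one block with 3 sites segregating in population 1 only, b = (2,2)
  lay <- sampleLayout(c(2, 2), blockLength = 100)
  tab <- bsfsTable(lay, rbind(c(0, 0, 3, 0)), 1)
  thw <- wattersonTheta(tab)
  expect_equal(thw[1], 3) # a_2 = 1
  expect_equal(thw[2], 0)
  # fixed differences segregate in neither population
  tab2 <- bsfsTable(lay, rbind(c(0, 2, 0, 0)), 1)
  expect_equal(unname(wattersonTheta(tab2)), c(0, 0))
})
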