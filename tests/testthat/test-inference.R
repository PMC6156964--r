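# a smooth deterministic surrogate with optimum at a known point, used to
# test optimizer mechanics separately from Monte-Carlo noise
quadSurrogate <- function(opt, noise = 0) {
  force(opt)
  function(p) {
    z <- log(p[names(opt)]) - log(opt)
    -sum(z^2) + if (noise > 0) rnorm(1, 0, noise) else 0
  }
}

onePopMapFixture <- function() modelTemplate("onePop")

test_that("the global stage is deterministic given its seed", {
  tpl <- modelTemplate("M2", fixed = c(r = 2e-8))
  opt <- c(N_A = 1500, T = 2, N_S = 20000, N_B = 9000)
  spec <- searchSpec("global", argsPerEval = 1, replicates = 2,
                     evalBudget = 150, seed = 5)
  a <- globalSearch(NULL, tpl$template, tpl$map, spec,
                    objective = quadSurrogate(opt))
  b <- globalSearch(NULL, tpl$template, tpl$map, spec,
                    objective = quadSurrogate(opt))
  expect_identical(a$trace, b$trace)
  expect_true(all(c("N_A", "T", "N_S", "N_B") %in% names(a$trace)))
})

test_that("local refinement of a noisy quadratic lands near the optimum", {
  tpl <- onePopMapFixture()
  opt <- c(N_e = 12000)
  spec <- searchSpec("local", argsPerEval = 1, replicates = 3,
                     evalBudget = 200, seed = 6)
  res <- localSearch(NULL, tpl$template, tpl$map, spec,
                     objective = quadSurrogate(opt, noise = 0.01))
  expect_lt(abs(log(res$bestParams[["N_e"]]) - log(12000)), 0.2)
})

test_that("a start box collapsed to a point evaluates that point", {
  tpl <- onePopMapFixture()
  spec <- searchSpec("local", argsPerEval = 1, replicates = 1,
                     evalBudget = 50, seed = 7)
  res <- localSearch(NULL, tpl$template, tpl$map, spec,
                     startBox = list(lower = 4321, upper = 4321),
                     objective = quadSurrogate(c(N_e = 9999)))
  expect_equal(unname(res$bestParams), 4321)
})

test_that("bounds excluding the truth push the estimate to the boundary", {
  tpl <- modelTemplate("onePop")
  map <- tpl$map
  map@lower[] <- 100; map@upper[] <- 1000 # truth at 12000 lies outside
  spec <- searchSpec("global", argsPerEval = 1, replicates = 1,
                     evalBudget = 200, seed = 8)
  res <- globalSearch(NULL, tpl$template, map, spec,
                      objective = quadSurrogate(c(N_e = 12000)))
  expect_gt(res$bestParams[["N_e"]], 900) # at/near the upper bound
})

test_that("returned points always satisfy the nonlinear constraints", {
  tpl <- modelTemplate("M6", fixed = c(r = 2e-8, N_A = 1400, N_S = 22000,
                                       N_B = 8900))
  opt <- c(T = 0.5, T_2 = 0.45, f_SB = 0.1, f_BS = 0.25)
  spec <- searchSpec("global", argsPerEval = 1, replicates = 3,
                     evalBudget = 250, seed = 9)
  res <- globalSearch(NULL, tpl$template, tpl$map, spec,
                      objective = quadSurrogate(opt[c("T", "T_2")]))
  for (r in seq_len(nrow(res$trace)))
    expect_lt(res$trace$T_2[r], res$trace$T[r])
})

test_that("rescaling a parameter rescales its estimate by the same constant", {
  tpl <- onePopMapFixture()
  c0 <- 1000
  mapA <- tpl$map
  mapB <- parameterMap("N_e", mapA@lower / c0, mapA@upper / c0,
                       bind = function(template, p) template)
  spec <- searchSpec("global", argsPerEval = 1, replicates = 1,
                     evalBudget = 120, seed = 10)
  objA <- function(p) -((log(p[["N_e"]]) - log(12000))^2)
  objB <- function(p) -((log(p[["N_e"]] * c0) - log(12000))^2)
  resA <- globalSearch(NULL, tpl$template, mapA, spec, objective = objA)
  resB <- globalSearch(NULL, tpl$template, mapB, spec, objective = objB)
  # identical search problem after the log-space shift: exact rescaling
  expect_equal(resA$bestParams[["N_e"]], resB$bestParams[["N_e"]] * c0,
               tolerance = 1e-10)
})

test_that("a one-parameter mutation-rate model is recovered from synthetic data", {
  tpl <- onePopMapFixture()
  truthN <- 10000
  m <- buildModel(c(N_e = truthN), tpl$map, tpl$template)
  lay <- sampleLayout(2, blockLength = 1000)
  tab <- simulateDataset(simulationSpec(m, lay, 5000, seed = 11))
  res <- fit(tab, tpl, schedule = list(
    searchSpec("global", argsPerEval = 300, replicates = 2,
               evalBudget = 120, seed = 12)),
    finalArgs = 2000, seed = 13)
  expect_lt(abs(res$bestParams[["N_e"]] / truthN - 1), 0.2)
})

test_that("more ARGs per evaluation do not systematically hurt recovery", {
  tpl <- onePopMapFixture()
  lay <- sampleLayout(2, blockLength = 1000)
  errs <- vapply(c(small = 40, large = 400), function(M) {
    relErr <- vapply(1:10, function(r) {
      m <- buildModel(c(N_e = 10000), tpl$map, tpl$template)
      tab <- simulateDataset(simulationSpec(m, lay, 800, seed = 500 + r))
      res <- globalSearch(tab, tpl$template, tpl$map,
                          searchSpec("global", argsPerEval = M,
                                     replicates = 1, evalBudget = 60,
                                     seed = 600 + r))
      abs(res$bestParams[["N_e"]] / 10000 - 1)
    }, 0)
    median(relErr)
  }, 0)
  expect_lte(errs[["large"]], errs[["small"]] + 0.02)
})

test_that("the two-stage driver narrows bounds and reports provenance", {
  tpl <- modelTemplate("M2", fixed = c(r = 2e-8))
  opt <- c(N_A = 1500, T = 2, N_S = 20000, N_B = 9000)
  res <- fit(NULL, tpl, schedule = list(
    searchSpec("global", argsPerEval = 1, replicates = 2,
               evalBudget = 250, seed = 20),
    searchSpec("local", argsPerEval = 1, replicates = 2,
               evalBudget = 200, seed = 21)),
    objective = quadSurrogate(opt), seed = 22)
  expect_length(res$stages, 2 + (length(res$stages) > 2)) # second round allowed
  expect_lt(max(abs(log(res$bestParams / opt[names(res$bestParams)]))), 0.1)
  expect_equal(res$seed, 22)
})
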