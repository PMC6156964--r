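test_that("site-type counts match the joint-SFS combinatorics", {
  expect_equal(numSiteTypes(sampleLayout(c(2, 2), polarized = TRUE)), 7)
  expect_equal(numSiteTypes(sampleLayout(c(2, 2))), 4)
  expect_equal(numSiteTypes(sampleLayout(4)), 2) # (1)~(3), (2)
  b <- c(3, 2, 4)
  expect_equal(numSiteTypes(sampleLayout(b, polarized = TRUE)),
               prod(b + 1) - 2)
})

test_that("folding is canonical and idempotent", {
  cls <- mutationClasses(sampleLayout(c(2, 2)))
  b <- c(2, 2)
  for (r in seq_len(nrow(cls))) {
    v <- cls[r, ]
    w <- b - v
    # the stored representative is already the lexicographically smaller
    expect_false(blockLik:::.lexLess(w, v))
  }
  # folding the canonical representative again changes nothing
  fold <- attr(cls, "fold")
  expect_equal(sum(lengths(fold)), 7) # partitions the unfolded classes
})

test_that("lumped enumeration has the expected cardinalities", {
  lay2 <- sampleLayout(2)
  expect_equal(nrow(configMatrix(enumerateConfigurations(lay2, 4))), 6)
  lay22 <- sampleLayout(c(2, 2))
  expect_equal(nrow(configMatrix(enumerateConfigurations(lay22, 4))), 1296)
  # (kmax + 2)^C in general
  for (km in 0:2)
    expect_equal(nrow(configMatrix(enumerateConfigurations(lay22, km))),
                 (km + 2)^4)
  # excluding single-genealogy-incompatible configurations
  expect_equal(nrow(configMatrix(
    enumerateConfigurations(lay22, 4, noRecombination = TRUE))), 396)
})

test_that("tabulation maps blocks to configurations with the documented conventions", {
  lay <- sampleLayout(c(2, 2), blockLength = 100)
  cls <- rownames(mutationClasses(lay)) # 0-1, 0-2, 1-0, 1-1
  blocks <- list(
    NULL,                                  # no variants: k_0
    matrix(0L, 0, 4),                      # empty matrix: k_0
    rbind(c(1, 0, 0, 0),                   # frequency (1,0): class 1-0
          c(1, 0, 1, 0),                   # shared (1,1)
          c(0, 1, 1, 0)),                  # shared (1,1)
    rbind(c(1, 1, 0, 0),                   # polarized (2,0) -> folded 0-2
          c(0, 0, 1, 1)))                  # (0,2) -> same folded class
  tab <- tabulateBlocks(blocks, lay)
  counts <- configCounts(tab)
  expect_equal(totalBlocks(tab), 4)
  k0 <- paste(rep(0, 4), collapse = ",")
  expect_equal(unname(counts[k0]), 2)
  # block 3: one 1-0 site, two 1-1 sites -> (0,0,1,2) in class order
  expect_equal(unname(counts[paste(c(0, 0, 1, 2), collapse = ",")]), 1)
  # block 4: both sites fold into the fixed-difference class 0-2
  expect_equal(unname(counts[paste(c(0, 2, 0, 0), collapse = ",")]), 1)
})

test_that("tabulation ignores block order and within-population relabeling", {
  lay <- sampleLayout(c(2, 2), blockLength = 100)
  set.seed(42)
  blocks <- lapply(1:30, function(i)
    matrix(rbinom(5 * 4, 1, 0.4), 5, 4))
  tabA <- tabulateBlocks(blocks, lay)
  tabB <- tabulateBlocks(rev(blocks), lay)
  expect_equal(configCounts(tabA), configCounts(tabB))
  # swap genomes within each population (phase/labels are irrelevant)
  swapped <- lapply(blocks, function(g) g[, c(2, 1, 4, 3)])
  tabC <- tabulateBlocks(swapped, lay)
  expect_equal(configCounts(tabA), configCounts(tabC))
})

test_that("missing and multi-allelic sites are dropped and counted", {
  lay <- sampleLayout(c(2, 2), blockLength = 100)
  blocks <- list(rbind(c(1, 0, 0, 0),
                       c(NA, 1, 0, 0),    # missing: dropped
                       c(2, 0, 1, 0)))    # multi-allelic code: dropped
  tab <- tabulateBlocks(blocks, lay)
  expect_equal(attr(tab, "droppedSites"), 2)
  expect_equal(unname(configCounts(tab)[paste(c(0, 0, 1, 0),
                                              collapse = ",")]), 1)
  expect_error(tabulateBlocks(list(matrix(0L, 1, 3)), lay), "block 1")
})

test_that("k_max lumping caps per-class counts in tabulated tables", {
  lay <- sampleLayout(2, blockLength = 100)
  blocks <- list(matrix(1L, 6, 2) * cbind(rep(1L, 6), rep(0L, 6)))
  tab <- tabulateBlocks(blocks, lay, kmax = 4)
  expect_equal(unname(configMatrix(tab)[1, 1]), -1L) # 6 singletons > 4
})

test_that("bSFS tables round-trip through the plain-text format", {
  lay <- sampleLayout(c(2, 2), blockLength = 2000, effectiveLength = 1600)
  K <- rbind(c(0, 0, 0, 0), c(1, 0, 2, 0), c(-1, 0, 1, 4))
  tab <- bsfsTable(lay, K, c(9000, 12, 3), kmax = 4)
  path <- withr::local_tempfile()
  writeBsfsTable(tab, path)
  tab2 <- readBsfsTable(path)
  expect_equal(configMatrix(tab2), configMatrix(tab))
  expect_equal(configCounts(tab2), configCounts(tab))
  expect_equal(sampleSizes(tableLayout(tab2)), sampleSizes(lay))
  expect_equal(effectiveLength(tableLayout(tab2)), 1600)
  expect_equal(kMax(tab2), 4L)

  # empty tables are valid and round-trip
  e <- bsfsTable(lay, matrix(0L, 0, 4), numeric(0))
  writeBsfsTable(e, path)
  e2 <- readBsfsTable(path)
  expect_equal(totalBlocks(e2), 0)

  # malformed lines are reported with their line number
  lines <- readLines(path)
  writeLines(c(lines, "1\t2\t3"), path)
  expect_error(readBsfsTable(path), "line 8")
})

test_that("a table from one layout refuses draws from another", {
  lay <- sampleLayout(c(2, 2), blockLength = 1000)
  tab <- bsfsTable(lay, rbind(c(0, 0, 0, 0)), 5)
  m <- onePopModel()
  draws <- sampleArgs(m, sampleLayout(2, blockLength = 1000), 10, seed = 1)
  expect_error(approximateConfigProbs(tab, m, draws = draws),
               "class columns")
})

test_that("the cbSFS with the full sample as single subsample equals the bSFS", {
  lay <- sampleLayout(c(2, 2), blockLength = 100)
  set.seed(7)
  blocks <- lapply(1:40, function(i) matrix(rbinom(3 * 4, 1, 0.3), 3, 4))
  scheme <- subsamplingScheme(lay, "explicit", subsamples = list(1:4))
  direct <- tabulateBlocks(blocks, lay)
  pooled <- buildCbsfs(blocks, scheme, lay)
  expect_equal(configCounts(pooled), configCounts(direct))
})

test_that("subsampling schemes count and pool as documented", {
  # 5 diploids (10 genomes) per population, all subsets of 2 diploids
  lay <- sampleLayout(c(10, 10), blockLength = 100)
  sch <- subsamplingScheme(lay, "all_subsets", unitSize = 2,
                           unitsPerSubsample = 2)
  expect_length(sch$subsamples, choose(5, 2)^2) # 100
  expect_equal(sampleSizes(sch$layout), c(4L, 4L))

  # consecutive diploids: one complete pair per population here
  lay2 <- sampleLayout(c(2, 2), blockLength = 100)
  sch2 <- subsamplingScheme(lay2, "consecutive", unitSize = 2)
  expect_length(sch2$subsamples, 1)
  set.seed(11)
  blocks <- lapply(1:25, function(i) matrix(rbinom(2 * 4, 1, 0.4), 2, 4))
  expect_equal(configCounts(buildCbsfs(blocks, sch2, lay2)),
               configCounts(tabulateBlocks(blocks, lay2)))

  # pooled total is blocks x subsamples
  lay3 <- sampleLayout(c(4, 4), blockLength = 100)
  sch3 <- subsamplingScheme(lay3, "all_subsets", unitSize = 2,
                            unitsPerSubsample = 1)
  set.seed(12)
  blocks3 <- lapply(1:10, function(i) matrix(rbinom(2 * 8, 1, 0.3), 2, 8))
  pooled <- buildCbsfs(blocks3, sch3, lay3)
  expect_equal(totalBlocks(pooled), 10 * length(sch3$subsamples))
  expect_error(buildCbsfs(blocks3, list(subsamples = list(1:2, 9:10),
                                        layout = sch3$layout),
                          sampleLayout(c(1, 1), blockLength = 100)),
               "absent")
})
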