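test_that("the generator is reproducible and respects degenerate limits", {
  c1 <- syntheticConfig(nm = 15, nl = 20, seed = 3)
  d1 <- generateSyntheticData(c1)
  d2 <- generateSyntheticData(c1)
  expect_identical(interactionPairs(d1$network),
                   interactionPairs(d2$network))
  expect_identical(profileMatrix(d1$lncrnaExpression),
                   profileMatrix(d2$lncrnaExpression))
  expect_identical(as.character(d1$mirnaSequences@sequences),
                   as.character(d2$mirnaSequences@sequences))
  expect_error(syntheticConfig(pIn = 0.01, pOut = 0.2), "pIn > pOut")
  expect_error(syntheticConfig(nm = 2, nl = 2, pIn = 1e-4, pOut = 1e-5),
               "degenerate")
})

test_that("one block at pIn = 1 yields the complete bipartite graph", {
  d <- generateSyntheticData(syntheticConfig(nm = 5, nl = 7, nBlocks = 1,
                                             pIn = 1, pOut = 0, seed = 1))
  expect_equal(nrow(interactionPairs(d$network)), 35L)
  expect_equal(unname(networkDensity(d$network)["percent"]), 100)
})

test_that("noiseless expression makes within-block profiles identical", {
  d <- generateSyntheticData(syntheticConfig(nm = 12, nl = 16, nBlocks = 2,
                                             exprNoise = 0,
                                             missingFrac = c(mirna = 0,
                                                             lncrna = 0),
                                             seed = 2))
  s <- similarityValues(expressionSimilarity(d$lncrnaExpression))
  same <- outer(d$blocks$lncrna, d$blocks$lncrna, "==")
  expect_equal(unname(s[same]), rep(1, sum(same)), tolerance = 1e-12)
})

test_that("realized density concentrates near its expectation", {
  cfg <- syntheticConfig(seed = 7)
  d <- generateSyntheticData(cfg)
  expected <- cfg$pIn / cfg$nBlocks + cfg$pOut * (1 - 1 / cfg$nBlocks)
  got <- networkDensity(d$network)[["fraction"]]
  expect_gt(got, 0.5 * expected)
  expect_lt(got, 2 * expected)
})

test_that("within-block expression correlation exceeds cross-block", {
  wins <- 0L
  for (seed in 1:20) {
    d <- generateSyntheticData(syntheticConfig(nm = 10, nl = 24,
                                               nBlocks = 3, seed = seed))
    s <- similarityValues(expressionSimilarity(d$lncrnaExpression))
    ok <- validMask(expressionSimilarity(d$lncrnaExpression))
    same <- outer(d$blocks$lncrna, d$blocks$lncrna, "==") &
      outer(ok, ok, "&")
    diag(same) <- FALSE
    cross <- !outer(d$blocks$lncrna, d$blocks$lncrna, "==") &
      outer(ok, ok, "&")
    if (mean(s[same]) > mean(s[cross])) wins <- wins + 1L
  }
  expect_equal(wins, 20L)
})

test_that("generated data satisfy the container invariants end to end", {
  d <- generateSyntheticData(syntheticConfig(nm = 12, nl = 18, seed = 4))
  expect_true(validObject(d$network))
  expect_true(validObject(d$mirnaExpression))
  expect_true(validObject(d$mirnaTargets))
  expect_true(validObject(d$mirnaSequences))
  expect_true(validObject(expressionSimilarity(d$lncrnaExpression)))
  expect_true(validObject(functionSimilarity(d$mirnaTargets, "AA")))
})

test_that("reference-scale configuration reproduces the real-data shape", {
  cfg <- referenceScaleConfig()
  expect_equal(cfg$nm, 275L)
  expect_equal(cfg$nl, 780L)
  expect_equal(cfg$missingFrac[["mirna"]], 0.164)
  expect_equal(cfg$missingFrac[["lncrna"]], 0.423)
  expect_equal(cfg$exprDims[["mirna"]], 172L)
  expect_equal(cfg$exprDims[["lncrna"]], 22L)
  dens <- cfg$pIn / cfg$nBlocks + cfg$pOut * (1 - 1 / cfg$nBlocks)
  expect_equal(dens, 0.0249, tolerance = 1e-12)
  # expected pair count = 0.0249 * 275 * 780
  expect_equal(dens * 275 * 780, 0.0249 * 275 * 780, tolerance = 1e-9)
})

test_that("fixture files written by the generator load back consistently", {
  d <- generateSyntheticData(syntheticConfig(nm = 8, nl = 10, seed = 6))
  dir <- withr::local_tempdir()
  paths <- writeSyntheticData(d, dir)
  net <- readInteractions(paths[["interactions"]])
  expect_equal(nrow(interactionPairs(net)),
               nrow(interactionPairs(d$network)))
  expr <- readExpressionProfiles(paths[["lncrnaExpression"]])
  expect_equal(sum(profileAvailable(expr)),
               sum(profileAvailable(d$lncrnaExpression)))
  seqs <- readSequences(paths[["mirnaSequences"]])
  expect_identical(as.character(seqs@sequences),
                   as.character(d$mirnaSequences@sequences))
  tg <- readTargetGenes(paths[["mirnaTargets"]])
  expect_equal(nrow(tg@edges), nrow(d$mirnaTargets@edges))
})
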