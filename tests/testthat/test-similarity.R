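test_that("expression similarity is the Pearson correlation of profiles", {
  X <- rbind(a = c(1, 2, 3), b = c(2, 4, 6), c = c(3, 2, 1))
  s <- expressionSimilarity(ExpressionProfileSet(X))
  v <- similarityValues(s)
  expect_equal(v["a", "b"], 1, ignore_attr = TRUE)
  expect_equal(v["a", "c"], -1, ignore_attr = TRUE)
  expect_equal(diag(v), rep(1, 3), ignore_attr = TRUE)

  Y <- rbind(a = c(1, 2, 3, 4), b = c(1, 3, 2, 4))
  s2 <- expressionSimilarity(ExpressionProfileSet(Y))
  expect_equal(similarityValues(s2)[1, 2], 0.8)
})

test_that("expression similarity matches stats::cor on random profiles", {
  set.seed(11)
  for (rep in 1:5) {
    X <- matrix(rnorm(15 * 8), 15, 8,
                dimnames = list(paste0("r", 1:15), NULL))
    s <- expressionSimilarity(ExpressionProfileSet(X))
    expect_lt(max(abs(similarityValues(s) - cor(t(X)))), 1e-10)
  }
})

test_that("missing and zero-variance profiles yield invalid zero rows", {
  X <- rbind(a = c(1, 2, 3), b = c(0, 0, 0), c = c(2, 1, 4), d = c(NA, 1, 2))
  s <- expressionSimilarity(ExpressionProfileSet(X))
  expect_equal(validMask(s), c(TRUE, FALSE, TRUE, FALSE),
               ignore_attr = TRUE)
  expect_true(all(similarityValues(s)[c(2, 4), ] == 0))
  expect_error(
    expressionSimilarity(ExpressionProfileSet(rbind(a = 1, b = 2))),
    "fewer than 2")
})

test_that("function similarity reproduces the worked neighbor-overlap examples", {
  tg <- TargetGeneNetwork(data.frame(
    rna = c("i", "i", "i", "j", "j", "j"),
    gene = c("g1", "g2", "g3", "g2", "g3", "g4")))
  expect_equal(similarityValues(functionSimilarity(tg, "CN"))[1, 2], 2)
  expect_equal(similarityValues(functionSimilarity(tg, "JA"))[1, 2], 0.5)
  expect_equal(similarityValues(functionSimilarity(tg, "SA"))[1, 2], 2 / 3)

  # AA with one shared gene of RNA-degree 3: 1/ln(3)
  tg2 <- TargetGeneNetwork(data.frame(
    rna = c("i", "i", "j", "j", "z"),
    gene = c("g1", "g2", "g2", "g3", "g2")))
  expect_equal(similarityValues(functionSimilarity(tg2, "AA"))[1, 2],
               1 / log(3))

  # disjoint neighborhoods: every index 0
  tg3 <- TargetGeneNetwork(data.frame(rna = c("i", "j"),
                                      gene = c("g1", "g2")))
  for (ix in c("CN", "AA", "JA", "SA"))
    expect_equal(similarityValues(functionSimilarity(tg3, ix))[1, 2], 0)
})

test_that("all four indices agree with set enumeration on random graphs", {
  set.seed(5)
  for (rep in 1:20) {
    nr <- sample(3:20, 1); ng <- sample(3:30, 1)
    ne <- sample.int(nr * ng, 1)
    e <- unique(cbind(sample.int(nr, ne, TRUE), sample.int(ng, ne, TRUE)))
    tg <- TargetGeneNetwork(
      data.frame(rna = paste0("r", e[, 1]), gene = paste0("g", e[, 2])),
      rnaIds = paste0("r", 1:nr), geneIds = paste0("g", 1:ng))
    for (ix in c("CN", "AA", "JA", "SA")) {
      got <- similarityValues(functionSimilarity(tg, ix))
      expect_equal(unname(got), oracleFunctionMatrix(tg, ix),
                   tolerance = 1e-12)
    }
  }
})

test_that("sequence similarity normalizes self-alignment to exactly 1", {
  ss <- SequenceSet(c(a = "ACGT", b = "ACGT", c = "AAAA"))
  s <- similarityValues(sequenceSimilarity(ss))
  expect_equal(s["a", "b"], 1, ignore_attr = TRUE)  # raw 8 / (2 * 4)
  expect_equal(diag(s), rep(1, 3), ignore_attr = TRUE)
  set.seed(3)
  seqs <- vapply(1:6, function(i) paste(
    sample(c("A", "C", "G", "T"), sample(8:14, 1), TRUE), collapse = ""),
    character(1))
  names(seqs) <- paste0("s", 1:6)
  v <- similarityValues(sequenceSimilarity(SequenceSet(seqs)))
  expect_equal(diag(v), rep(1, 6), ignore_attr = TRUE)
  expect_true(all(v >= 0 & v <= 1))
  expect_identical(v, t(v))
})

test_that("alignment raw scores equal the affine-gap DP oracle", {
  set.seed(17)
  params <- alignmentParams()
  for (rep in 1:25) {
    a <- paste(sample(c("A", "C", "G", "T", "N"), sample(2:12, 1), TRUE),
               collapse = "")
    b <- paste(sample(c("A", "C", "G", "T"), sample(2:12, 1), TRUE),
               collapse = "")
    ss <- SequenceSet(c(x = a, y = b))
    got <- similarityValues(sequenceSimilarity(ss, params))[1, 2]
    raw <- oracleAlignScore(a, b)
    want <- min(max(raw, 0) / (2 * min(nchar(a), nchar(b))), 1)
    expect_equal(got, want, tolerance = 1e-6,
                 label = sprintf("%s vs %s", a, b))
  }
})

test_that("alignment parameter validation enforces the scoring contract", {
  expect_error(alignmentParams(gapOpen = 0.5))
  expect_error(alignmentParams(match = -2, mismatch = 0))
  expect_error(sequenceSimilarity(SequenceSet(c(a = "ACGT"))), "at least 2")
})

test_that("selectSimilarity assembles the configured S_m and S_l", {
  d <- generateSyntheticData(syntheticConfig(nm = 10, nl = 12, nBlocks = 2,
                                             pIn = 0.6, pOut = 0.1,
                                             seed = 21))
  sims <- selectSimilarity(d$network,
                           mirnaTargets = d$mirnaTargets,
                           lncrnaExpression = d$lncrnaExpression)
  expect_equal(similarityKind(sims$Sm), "function")
  expect_equal(similarityKind(sims$Sl), "expression")
  expect_equal(rnaIds(sims$Sm), mirnaIds(d$network))
  expect_equal(rnaIds(sims$Sl), lncrnaIds(d$network))
  expect_error(selectSimilarity(d$network,
                                lncrnaExpression = d$lncrnaExpression),
               "no target-gene data")

  # an RNA absent from the source gets a zero, invalid row
  expr <- d$lncrnaExpression
  keep <- rnaIds(expr) != "lnc-003"
  sub <- ExpressionProfileSet(profileMatrix(expr)[keep, ],
                              rnaIds = rnaIds(expr)[keep])
  sims2 <- selectSimilarity(d$network, mirnaTargets = d$mirnaTargets,
                            lncrnaExpression = sub)
  jpos <- match("lnc-003", rnaIds(sims2$Sl))
  expect_false(validMask(sims2$Sl)[jpos])
  expect_true(all(similarityValues(sims2$Sl)[jpos, ] == 0))
})
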