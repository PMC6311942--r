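test_that("scoring functions follow their closed forms", {
  m <- randomModel(4, 5, 2, seed = 1)
  m@U[1, ] <- c(1, 0); m@V[2, ] <- c(2, 3); m@b[2] <- 0.5
  expect_equal(predictScore(m, 1, 2), 2.5)
  zero <- m; zero@U[] <- 0; zero@V[] <- 0; zero@b[] <- 0
  expect_equal(predictScore(zero, 3, 4), 0)
  # random model equals an elementwise multiply-sum oracle
  for (r in 1:10) {
    i <- sample(4, 1); j <- sample(5, 1)
    expect_equal(predictScore(m, i, j),
                 sum(vapply(1:2, function(c) m@U[i, c] * m@V[j, c],
                            numeric(1))) + m@b[j])
  }
  expect_error(predictScore(m, 9, 1), "out of range")
  expect_error(predictScore(m, "nope", 1), "unknown")
})

test_that("group score is the arithmetic mean of member scores", {
  m <- randomModel(5, 6, 3, seed = 2)
  j <- 4
  expect_equal(groupScore(m, 2, j), predictScore(m, 2, j))
  G <- c(1, 3, 5)
  expect_equal(groupScore(m, G, j),
               mean(vapply(G, function(i) predictScore(m, i, j),
                           numeric(1))))
  expect_error(groupScore(m, integer(0), 1), "nonempty")
})

test_that("fused score interpolates group and individual preference", {
  m <- randomModel(5, 6, 3, seed = 3)
  G <- c(1, 2, 4)
  expect_equal(fusedScore(m, G, 1, 2, rho = 0),
               predictScore(m, 1, 2))
  expect_equal(fusedScore(m, G, 1, 2, rho = 1), groupScore(m, G, 2))
  expect_equal(fusedScore(m, G, 1, 2, rho = 0.5),
               0.5 * groupScore(m, G, 2) + 0.5 * predictScore(m, 1, 2))
  expect_error(fusedScore(m, G, 1, 2, rho = 1.2), "rho")
  expect_error(fusedScore(m, G, 3, 2), "belong")
})

test_that("triple loss equals the stated objective and is stable", {
  m <- randomModel(4, 6, 2, seed = 4)
  zero <- m; zero@U[] <- 0; zero@V[] <- 0; zero@b[] <- 0
  tr <- list(i = 1, j = 2, k = 3, G = c(1, 2))
  expect_equal(tripleLoss(zero, tr), log(2))
  # saturation: a huge positive margin drives the loss term to 0
  sat <- zero; sat@b[2] <- 60
  p0 <- bprParams(alphaM = 0, alphaL = 0, betaL = 0)
  expect_equal(tripleLoss(sat, tr, p0), 0, tolerance = 1e-20)
  sat@b[2] <- 800  # beyond exp() range; log1p-exp form must not overflow
  expect_true(is.finite(tripleLoss(sat, tr, p0)))
  # random model matches direct evaluation of the formula
  p <- bprParams(alphaM = 0.03, alphaL = 0.02, betaL = 0.05)
  s <- fusedScore(m, tr$G, tr$i, tr$j, p$rho) - predictScore(m, tr$i, tr$k)
  direct <- log(1 + exp(-s)) +
    p$alphaM / 2 * (sum(m@U[1, ]^2) + sum(m@U[2, ]^2)) +
    p$alphaL / 2 * (sum(m@V[2, ]^2) + sum(m@V[3, ]^2)) +
    p$betaL / 2 * (m@b[2]^2 + m@b[3]^2)
  expect_equal(tripleLoss(m, tr, p), direct, tolerance = 1e-12)
})

test_that("analytic SGD gradients match central finite differences", {
  set.seed(6)
  worst <- 0
  for (rep in 1:30) {
    d <- sample(2:4, 1)
    m <- randomModel(3 + sample(3, 1), 4 + sample(3, 1), d, seed = rep)
    nm <- nrow(m@U); nl <- nrow(m@V)
    G <- sample(nm, sample(min(4, nm), 1))
    j <- sample(nl, 1)
    tr <- list(i = G[1], j = j, k = sample(setdiff(seq_len(nl), j), 1),
               G = G)
    p <- bprParams(rho = runif(1), alphaM = runif(1, 0.001, 0.1),
                   alphaL = runif(1, 0.001, 0.1),
                   betaL = runif(1, 0.001, 0.1))
    worst <- max(worst, maxGradRelError(m, tr, p))
  }
  expect_lt(worst, 1e-5)
})

test_that("one SGD step moves the biases toward the preference order", {
  zero <- randomModel(3, 5, 2, seed = 7)
  zero@U[] <- 0; zero@V[] <- 0; zero@b[] <- 0
  tr <- list(i = 1, j = 2, k = 4, G = 1)
  p <- bprParams()
  stepped <- sgdStep(zero, tr, p)
  expect_gt(stepped@b[2], 0)   # observed lncRNA bias increases
  expect_lt(stepped@b[4], 0)   # unobserved lncRNA bias decreases
  # gamma = 0 leaves the model unchanged (loss gradient applied with 0 rate)
  p0 <- p; p0$gamma <- 0
  frozen <- sgdStep(zero, tr, p0)
  expect_identical(frozen@U, zero@U)
  expect_identical(frozen@b, zero@b)
})

test_that("sampled triples satisfy the membership contracts", {
  net <- randomNetwork(8, 15, 40, seed = 9)
  p <- interactionPairs(net)
  idx <- mirlnclink:::.networkIndex(net)
  set.seed(1)
  for (r in 1:200) {
    tr <- mirlnclink:::.sampleTripleIdx(idx, 3L)
    Li <- p[p[, 1] == tr$i, 2]
    Mj <- p[p[, 2] == tr$j, 1]
    expect_true(tr$j %in% Li)
    expect_false(tr$k %in% Li)
    expect_true(tr$i %in% tr$G)
    expect_true(all(tr$G %in% Mj))
    expect_lte(length(tr$G), 3L)
    expect_equal(length(tr$G), min(3L, length(Mj)))
  }
})

test_that("the observed-partner marginal of sampled triples is uniform", {
  # fixed miRNA with 6 partners; chi-squared on the j draws
  net <- InteractionNetwork(data.frame(
    m = c(rep("m1", 6), "m2"),
    l = c(paste0("l", 1:6), "l7")))
  idx <- mirlnclink:::.networkIndex(net)
  set.seed(123)
  js <- integer(0)
  for (r in 1:20000) {
    tr <- mirlnclink:::.sampleTripleIdx(idx, 3L)
    if (tr$i == 1L) js <- c(js, tr$j)
  }
  counts <- tabulate(js, 7)[1:6]
  expect_gt(chisq.test(counts)$p.value, 0.01)
})

test_that("training is deterministic, records loss, and honors T = 0", {
  net <- randomNetwork(10, 15, 45, seed = 10)
  p <- bprParams(iters = 5L, seed = 33L)
  m1 <- trainGroupBPR(net, params = p)
  m2 <- trainGroupBPR(net, params = p)
  expect_identical(m1@U, m2@U)
  expect_identical(m1@V, m2@V)
  expect_identical(m1@b, m2@b)
  expect_identical(m1@epochLoss, m2@epochLoss)
  expect_length(m1@epochLoss, 5L)

  p0 <- bprParams(iters = 0L, seed = 33L)
  init <- trainGroupBPR(net, params = p0)
  set.seed(33L)
  expect_identical(init@U, matrix(rnorm(10 * 16, sd = 0.01), 10, 16))
  expect_length(init@epochLoss, 0L)
})

test_that("epoch loss trends downward on synthetic data", {
  d <- generateSyntheticData(syntheticConfig(nm = 20, nl = 30, seed = 5))
  p <- bprParams(iters = 40L, seed = 5L, d = 8L)
  m <- trainGroupBPR(d$network, params = p)
  late <- mean(tail(m@epochLoss, 10))
  expect_lt(late, m@epochLoss[1])
})

test_that("with a singleton group the trajectory is bitwise plain BPR", {
  net <- randomNetwork(8, 12, 35, seed = 12)
  p <- bprParams(d = 4L, iters = 4L, groupSize = 1L, seed = 77L)
  got <- trainGroupBPR(net, params = p)
  want <- oraclePairwiseBPR(net, p)
  expect_identical(got@U, want$U)
  expect_identical(got@V, want$V)
  expect_identical(got@b, want$b)
  expect_identical(got@epochLoss, want$epochLoss)
})

test_that("training is equivariant under relabeling of the RNAs", {
  net <- randomNetwork(6, 9, 20, seed = 14)
  p <- bprParams(d = 3L, iters = 1L, seed = 5L)
  set.seed(41)
  trs <- lapply(1:40, function(x) sampleTriple(net, 3L))
  set.seed(8)
  init <- list(U = matrix(rnorm(6 * 3), 6, 3),
               V = matrix(rnorm(9 * 3), 9, 3), b = rnorm(9))
  m <- trainGroupBPR(net, params = p, initState = init, triples = trs)

  pm <- sample(6); pl <- sample(9)   # permutation: old index -> new index
  pr <- interactionPairs(net)
  net2 <- InteractionNetwork(
    cbind(pm[pr[, 1]], pl[pr[, 2]]),
    mirnaIds = mirnaIds(net)[order(pm)], lncrnaIds = lncrnaIds(net)[order(pl)])
  trs2 <- lapply(trs, function(t)
    list(i = pm[t$i], j = pl[t$j], k = pl[t$k], G = pm[t$G]))
  init2 <- list(U = init$U[order(pm), ], V = init$V[order(pl), ],
                b = init$b[order(pl)])
  m2 <- trainGroupBPR(net2, params = p, initState = init2, triples = trs2)
  expect_equal(m2@U[pm, ], m@U, tolerance = 1e-12)
  expect_equal(m2@V[pl, ], m@V, tolerance = 1e-12)
  expect_equal(m2@b[pl], m@b, tolerance = 1e-12)
})

test_that("stronger regularization shrinks the trained parameter norms", {
  net <- randomNetwork(10, 15, 45, seed = 15)
  norms <- vapply(c(0.001, 0.01, 0.1), function(a) {
    p <- bprParams(iters = 30L, seed = 3L, d = 4L,
                   alphaM = a, alphaL = a, betaL = a)
    m <- trainGroupBPR(net, params = p)
    sqrt(sum(m@U^2) + sum(m@V^2) + sum(m@b^2))
  }, numeric(1))
  expect_true(all(diff(norms) < 0))
})

test_that("model checkpoints round-trip through JSON", {
  net <- randomNetwork(5, 7, 15, seed = 16)
  m <- trainGroupBPR(net, params = bprParams(iters = 2L, d = 3L, seed = 2L))
  f <- withr::local_tempfile(fileext = ".json")
  writeModel(m, f)
  back <- readModel(f)
  expect_equal(back@U, m@U, tolerance = 1e-12)
  expect_equal(back@b, m@b, tolerance = 1e-12)
  expect_equal(back@mirnaIds, m@mirnaIds)
  expect_equal(back@params$rho, m@params$rho)
})

test_that("aggregated scores add the clamped neighbor-similarity means", {
  net <- toyNetwork()  # m1-{l1,l2}, m2-{l1,l3}, m3-{l4}
  m <- randomModel(3, 4, 2, seed = 17)
  m@mirnaIds <- mirnaIds(net); m@lncrnaIds <- lncrnaIds(net)
  Sm <- SimilarityMatrix(matrix(c(1, .4, .6, .4, 1, -.9, .6, -.9, 1), 3),
                         rnaIds = mirnaIds(net), kind = "expression")
  Sl <- SimilarityMatrix(diag(4) * 0 + .2, rnaIds = lncrnaIds(net),
                         kind = "expression")
  base <- predictScore(m, 3, 1)   # (m3, l1) unobserved
  got <- aggregateScore(m, net, Sm, Sl, 3, 1, deltaM = 1, deltaL = 1)
  # M_l1 = {m1, m2}: mean of max(0, .6), max(0, -.9) = .3
  # L_m3 = {l4}: mean Sl(l1, l4) = .2
  expect_equal(got, base + 0.3 + 0.2)
  expect_equal(aggregateScore(m, net, Sm, Sl, 3, 1, deltaM = 0,
                              deltaL = 0), base)
  # invalid lncRNA similarity row contributes only the miRNA term
  SlBad <- SimilarityMatrix(matrix(.2, 4, 4), rnaIds = lncrnaIds(net),
                            valid = c(FALSE, TRUE, TRUE, TRUE),
                            kind = "expression")
  expect_equal(aggregateScore(m, net, Sm, SlBad, 3, 1), base + 0.3)
})

test_that("candidate ranking excludes observed partners and breaks ties by id", {
  net <- toyNetwork()
  m <- randomModel(3, 4, 2, seed = 18)
  m@mirnaIds <- mirnaIds(net); m@lncrnaIds <- lncrnaIds(net)
  r <- rankCandidates(m, net, NULL, NULL, "m1", k = 10)
  expect_setequal(r$candidate, c("l3", "l4"))  # l1, l2 observed
  expect_equal(r$rank, seq_len(nrow(r)))
  # forced tie: all-zero model scores everything b_j; equal biases tie
  zero <- m; zero@U[] <- 0; zero@V[] <- 0; zero@b[] <- 0
  r2 <- rankCandidates(zero, net, NULL, NULL, "m1", k = 10)
  expect_equal(r2$candidate, c("l3", "l4"))
  expect_error(rankCandidates(m, net, NULL, NULL, "mX", 5), "unknown")
})
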