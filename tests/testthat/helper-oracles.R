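# Independent oracles. Each is coded directly from the defining formula /
# protocol, without reusing the package's implementation paths.

# --- global affine-gap alignment, Gotoh dynamic programming --------------
# Convention (same as the package states): a gap of length L costs
# |gapOpen| + L * |gapExtend|; any base pair involving N scores 0.
oracleAlignScore <- function(a, b, match = 2, mismatch = -1,
                             gapOpen = 0.5, gapExt = 0.1) {
  a <- strsplit(a, "")[[1]]; b <- strsplit(b, "")[[1]]
  n <- length(a); m <- length(b)
  sub <- function(x, y) {
    if (x == "N" || y == "N") 0 else if (x == y) match else mismatch
  }
  NEG <- -1e18
  M <- matrix(NEG, n + 1, m + 1)  # last op aligned pair
  X <- matrix(NEG, n + 1, m + 1)  # last op gap in b (consumes a)
  Y <- matrix(NEG, n + 1, m + 1)  # last op gap in a (consumes b)
  M[1, 1] <- 0
  for (i in seq_len(n)) X[i + 1, 1] <- -(gapOpen + i * gapExt)
  for (j in seq_len(m)) Y[1, j + 1] <- -(gapOpen + j * gapExt)
  for (i in seq_len(n)) {
    for (j in seq_len(m)) {
      M[i + 1, j + 1] <- max(M[i, j], X[i, j], Y[i, j]) + sub(a[i], b[j])
      X[i + 1, j + 1] <- max(M[i, j + 1] - gapOpen - gapExt,
                             X[i, j + 1] - gapExt,
                             Y[i, j + 1] - gapOpen - gapExt)
      Y[i + 1, j + 1] <- max(M[i + 1, j] - gapOpen - gapExt,
                             Y[i + 1, j] - gapExt,
                             X[i + 1, j] - gapOpen - gapExt)
    }
  }
  max(M[n + 1, m + 1], X[n + 1, m + 1], Y[n + 1, m + 1])
}

# --- neighbor-overlap indices by explicit set enumeration ----------------
oracleFunctionIndex <- function(geneSets, rnaDegreeOfGene, i, j, index) {
  gi <- geneSets[[i]]; gj <- geneSets[[j]]
  inter <- intersect(gi, gj)
  switch(index,
    CN = length(inter),
    AA = {
      s <- 0
      for (z in inter) {
        dz <- rnaDegreeOfGene[[z]]
        if (dz > 1) s <- s + 1 / log(dz)
      }
      s
    },
    JA = if (length(union(gi, gj)) == 0) 0 else
      length(inter) / length(union(gi, gj)),
    SA = if (length(gi) == 0 || length(gj) == 0) 0 else
      length(inter) / sqrt(length(gi) * length(gj)))
}

# full oracle matrix for one index over a TargetGeneNetwork
oracleFunctionMatrix <- function(tg, index) {
  e <- tg@edges
  n <- length(tg@rnaIds)
  geneSets <- lapply(seq_len(n), function(r) e[e[, 1L] == r, 2L])
  gdeg <- tabulate(e[, 2L], length(tg@geneIds))
  M <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n))
    M[i, j] <- oracleFunctionIndex(geneSets, gdeg, i, j, index)
  M
}

# --- all-pairs concordance AUC -------------------------------------------
oracleAUC <- function(pos, neg) {
  conc <- 0
  for (p in pos) for (q in neg)
    conc <- conc + if (p > q) 1 else if (p == q) 0.5 else 0
  conc / (length(pos) * length(neg))
}

# --- central finite differences of the triple loss -----------------------
# returns the numerical gradient for every parameter the triple touches
oracleNumericalGradient <- function(model, triple, params, h = 1e-6) {
  f <- function(m) tripleLoss(m, triple, params)
  grads <- list()
  bump <- function(m, slot, idx, delta) {
    x <- slot(m, slot); x[idx] <- x[idx] + delta
    `slot<-`(m, slot, value = x)
  }
  for (t in unique(triple$G)) {
    g <- numeric(ncol(model@U))
    for (c in seq_len(ncol(model@U))) {
      up <- model; up@U[t, c] <- up@U[t, c] + h
      dn <- model; dn@U[t, c] <- dn@U[t, c] - h
      g[c] <- (f(up) - f(dn)) / (2 * h)
    }
    grads[[paste0("U", t)]] <- g
  }
  for (j in c(triple$j, triple$k)) {
    g <- numeric(ncol(model@V))
    for (c in seq_len(ncol(model@V))) {
      up <- model; up@V[j, c] <- up@V[j, c] + h
      dn <- model; dn@V[j, c] <- dn@V[j, c] - h
      g[c] <- (f(up) - f(dn)) / (2 * h)
    }
    grads[[paste0("V", j)]] <- g
    up <- model; up@b[j] <- up@b[j] + h
    dn <- model; dn@b[j] <- dn@b[j] - h
    grads[[paste0("b", j)]] <- (f(up) - f(dn)) / (2 * h)
  }
  grads
}

# analytic gradient recovered from one SGD step: grad = (old - new) / gamma
analyticGradient <- function(model, triple, params) {
  stepped <- sgdStep(model, triple, params)
  grads <- list()
  for (t in unique(triple$G))
    grads[[paste0("U", t)]] <- (model@U[t, ] - stepped@U[t, ]) / params$gamma
  for (j in c(triple$j, triple$k)) {
    grads[[paste0("V", j)]] <- (model@V[j, ] - stepped@V[j, ]) / params$gamma
    grads[[paste0("b", j)]] <- (model@b[j] - stepped@b[j]) / params$gamma
  }
  grads
}

maxGradRelError <- function(model, triple, params) {
  ga <- analyticGradient(model, triple, params)
  gn <- oracleNumericalGradient(model, triple, params)
  m <- 0
  for (nm in names(ga)) {
    rel <- abs(ga[[nm]] - gn[[nm]]) /
      pmax(abs(ga[[nm]]), abs(gn[[nm]]), 1e-4)
    m <- max(m, rel)
  }
  m
}

# --- independent pairwise-only Bayesian ranking trainer ------------------
# Plain BPR with item bias and L2 regularization: no group machinery at
# all. Consumes the RNG exactly as a |G|=1 configuration of the package
# trainer does (init draws, then i, j, k per step).
oraclePairwiseBPR <- function(net, params) {
  p <- interactionPairs(net)
  nm <- length(mirnaIds(net)); nl <- length(lncrnaIds(net))
  d <- params$d
  Li <- lapply(seq_len(nm), function(i) p[p[, 1L] == i, 2L])
  nonLi <- lapply(Li, function(L) (seq_len(nl))[!(seq_len(nl) %in% L)])
  deg <- lengths(Li)
  elig <- which(deg > 0L & deg < nl)
  set.seed(params$seed)
  U <- matrix(rnorm(nm * d, sd = 0.01), nm, d)
  V <- matrix(rnorm(nl * d, sd = 0.01), nl, d)
  b <- numeric(nl)
  epochLoss <- numeric(params$iters)
  for (ep in seq_len(params$iters)) {
    tot <- 0
    for (step in seq_len(nrow(p))) {
      i <- elig[sample.int(length(elig), 1L)]
      j <- Li[[i]][sample.int(deg[i], 1L)]
      k <- nonLi[[i]][sample.int(nl - deg[i], 1L)]
      Ui <- U[i, ]; Vj <- V[j, ]; Vk <- V[k, ]
      s <- (sum(Ui * Vj) + b[j]) - (sum(Ui * Vk) + b[k])
      cc <- -1 / (1 + exp(s))
      loss <- (if (s >= 0) log1p(exp(-s)) else -s + log1p(exp(s))) +
        params$alphaM / 2 * sum(Ui^2) +
        params$alphaL / 2 * (sum(Vj^2) + sum(Vk^2)) +
        params$betaL / 2 * (b[j]^2 + b[k]^2)
      dUi <- cc * Vj + params$alphaM * Ui
      dUi <- dUi - cc * Vk
      U[i, ] <- Ui - params$gamma * dUi
      V[j, ] <- Vj - params$gamma * (cc * Ui + params$alphaL * Vj)
      V[k, ] <- Vk - params$gamma * (-cc * Ui + params$alphaL * Vk)
      b[j] <- b[j] - params$gamma * (cc + params$betaL * b[j])
      b[k] <- b[k] - params$gamma * (-cc + params$betaL * b[k])
      tot <- tot + loss
    }
    epochLoss[ep] <- tot / nrow(p)
  }
  list(U = U, V = V, b = b, epochLoss = epochLoss)
}
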