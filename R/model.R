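# Group-preference Bayesian pairwise-ranking model: scoring functions,
# sampled-triple loss, analytic SGD updates and the training loop.

#' Hyperparameters for the group-preference ranking model
#'
#' @param d latent dimension of the factor vectors (the scoring function is
#'   bilinear, \eqn{Score_{ij} = U_i \cdot V_j + b_j}).
#' @param rho group/individual preference tradeoff in [0, 1]; 0.5 weighs
#'   the group mean and the anchor miRNA equally.
#' @param gamma SGD learning rate (> 0).
#' @param iters maximum number of training epochs T; one epoch samples as
#'   many triples as there are observed pairs.
#' @param alphaM,alphaL,betaL L2 regularization weights for the miRNA
#'   factors, lncRNA factors and lncRNA biases; sensible values lie in
#'   [0.001, 0.1], default 0.01 (log-scale midpoint).
#' @param deltaM,deltaL tradeoffs of the miRNA- and lncRNA-similarity terms
#'   in the final aggregated score (default 1 each).
#' @param groupSize target miRNA group size |G| (>= 1); groups are capped
#'   by the number of observed partners of the sampled lncRNA.
#' @param seed RNG seed used for initialization and triple sampling.
#' @return a validated list of class \code{bprParams}.
#' @export
bprParams <- function(d = 16L, rho = 0.5, gamma = 0.1, iters = 500L,
                      alphaM = 0.01, alphaL = 0.01, betaL = 0.01,
                      deltaM = 1, deltaL = 1, groupSize = 3L, seed = 1L) {
  stopifnot(d >= 1, rho >= 0, rho <= 1, gamma > 0, iters >= 0,
            alphaM >= 0, alphaL >= 0, betaL >= 0, groupSize >= 1)
  structure(list(d = as.integer(d), rho = rho, gamma = gamma,
                 iters = as.integer(iters), alphaM = alphaM, alphaL = alphaL,
                 betaL = betaL, deltaM = deltaM, deltaL = deltaL,
                 groupSize = as.integer(groupSize), seed = as.integer(seed)),
            class = "bprParams")
}

#' @export
print.bprParams <- function(x, ...) {
  cat(sprintf(
    "bprParams: d=%d rho=%g gamma=%g iters=%d alpha=(%g,%g) beta=%g delta=(%g,%g) |G|=%d seed=%d\n",
    x$d, x$rho, x$gamma, x$iters, x$alphaM, x$alphaL, x$betaL,
    x$deltaM, x$deltaL, x$groupSize, x$seed))
  invisible(x)
}

.resolveIdx <- function(x, ids, what) {
  if (is.character(x)) {
    i <- match(x, ids)
    if (anyNA(i)) stop("unknown ", what, " id: ", paste(x[is.na(i)],
                                                        collapse = ", "))
    return(i)
  }
  i <- as.integer(x)
  if (any(i < 1L | i > length(ids))) stop(what, " index out of range")
  i
}

#' Individual prediction score
#'
#' \eqn{Score_{ij} = U_i \cdot V_j + b_j}: the inner product of the miRNA
#' and lncRNA latent factors plus the lncRNA bias.
#'
#' @param model a [GroupBPRModel-class].
#' @param i miRNA index or id.
#' @param j lncRNA index or id.
#' @return a single finite number.
#' @export
predictScore <- function(model, i, j) {
  i <- .resolveIdx(i, model@mirnaIds, "miRNA")
  j <- .resolveIdx(j, model@lncrnaIds, "lncRNA")
  sum(model@U[i, ] * model@V[j, ]) + model@b[j]
}

#' Group preference score
#'
#' The overall preference of a miRNA group G on lncRNA j: the arithmetic
#' mean of the members' individual scores,
#' \eqn{Score_{Gj} = |G|^{-1} \sum_{i \in G} Score_{ij}}.
#'
#' @param model a [GroupBPRModel-class].
#' @param G nonempty vector of miRNA indices or ids.
#' @param j lncRNA index or id.
#' @return a single number.
#' @export
groupScore <- function(model, G, j) {
  if (!length(G)) stop("group must be nonempty")
  G <- .resolveIdx(G, model@mirnaIds, "miRNA")
  j <- .resolveIdx(j, model@lncrnaIds, "lncRNA")
  sum(colMeans(model@U[G, , drop = FALSE]) * model@V[j, ]) + model@b[j]
}

#' Fused group/individual score
#'
#' Convex combination \eqn{Score_{Gij} = \rho Score_{Gj} +
#' (1-\rho) Score_{ij}} of the group preference and the anchor miRNA's
#' individual preference.
#'
#' @param model a [GroupBPRModel-class].
#' @param G miRNA group containing \code{i}.
#' @param i anchor miRNA index or id.
#' @param j lncRNA index or id.
#' @param rho tradeoff in [0, 1]; defaults to the model's trained value.
#' @return a single number.
#' @export
fusedScore <- function(model, G, i, j, rho = model@params$rho) {
  if (rho < 0 || rho > 1) stop("rho must lie in [0, 1]")
  Gi <- .resolveIdx(G, model@mirnaIds, "miRNA")
  ii <- .resolveIdx(i, model@mirnaIds, "miRNA")
  if (!(ii %in% Gi)) stop("anchor miRNA must belong to the group")
  rho * groupScore(model, Gi, j) + (1 - rho) * predictScore(model, ii, j)
}

# numerically stable ln(1 + exp(-s))
.softplusNeg <- function(s) {
  if (s >= 0) log1p(exp(-s)) else -s + log1p(exp(s))
}

#' Sampled-triple objective value
#'
#' For a training triple (G, i, j, k) — j an observed partner of the anchor
#' miRNA i, k an unobserved lncRNA — the pairwise-ranking loss
#' \deqn{f = \ln(1 + e^{-(Score_{Gij} - Score_{ik})})
#'  + \frac{\alpha_m}{2}\sum_{t \in G}\|U_t\|^2
#'  + \frac{\alpha_l}{2}\|V_j\|^2 + \frac{\alpha_l}{2}\|V_k\|^2
#'  + \frac{\beta_l}{2}b_j^2 + \frac{\beta_l}{2}b_k^2,}
#' evaluated with a log1p-exp form that is stable for large |s|.
#'
#' @param model a [GroupBPRModel-class].
#' @param triple list with elements \code{i}, \code{j}, \code{k}, \code{G}
#'   (as produced by [sampleTriple()]).
#' @param params a [bprParams()] list (defaults to the model's).
#' @return a nonnegative finite number.
#' @export
tripleLoss <- function(model, triple, params = model@params) {
  s <- fusedScore(model, triple$G, triple$i, triple$j, params$rho) -
    predictScore(model, triple$i, triple$k)
  G <- .resolveIdx(triple$G, model@mirnaIds, "miRNA")
  j <- .resolveIdx(triple$j, model@lncrnaIds, "lncRNA")
  k <- .resolveIdx(triple$k, model@lncrnaIds, "lncRNA")
  .softplusNeg(s) +
    params$alphaM / 2 * sum(model@U[G, , drop = FALSE]^2) +
    params$alphaL / 2 * sum(model@V[j, ]^2) +
    params$alphaL / 2 * sum(model@V[k, ]^2) +
    params$betaL / 2 * model@b[j]^2 +
    params$betaL / 2 * model@b[k]^2
}

#' One stochastic gradient step
#'
#' Updates the parameters touched by one training triple with the exact
#' analytic gradients of the triple loss: with
#' \eqn{s = Score_{Gij} - Score_{ik}} and loss coefficient
#' \eqn{c = -\sigma(-s)}, each member t of G receives gradient
#' \eqn{c\,\rho/|G|\,V_j} (the anchor i additionally
#' \eqn{c\,(1-\rho)V_j - c\,V_k}), \eqn{V_j} receives
#' \eqn{c(\rho \bar U_G + (1-\rho)U_i)}, \eqn{V_k} receives \eqn{-c\,U_i},
#' and the biases \eqn{b_j, b_k} receive \eqn{c} and \eqn{-c}; plus the L2
#' terms. All gradients are evaluated at the pre-update parameters and
#' applied together as \eqn{\Theta \leftarrow \Theta - \gamma
#' \partial f / \partial \Theta}.
#'
#' @inheritParams tripleLoss
#' @return the updated [GroupBPRModel-class].
#' @export
sgdStep <- function(model, triple, params = model@params) {
  G <- .resolveIdx(triple$G, model@mirnaIds, "miRNA")
  i <- .resolveIdx(triple$i, model@mirnaIds, "miRNA")
  j <- .resolveIdx(triple$j, model@lncrnaIds, "lncRNA")
  k <- .resolveIdx(triple$k, model@lncrnaIds, "lncRNA")
  if (!(i %in% G)) stop("anchor miRNA must belong to the group")
  st <- .sgdStepCore(model@U, model@V, model@b, G, i, j, k, params)
  if (!all(is.finite(st$Uj)) || !all(is.finite(st$Vj)) ||
      !all(is.finite(st$Vk)) || !is.finite(st$bj) || !is.finite(st$bk))
    stop("non-finite gradient update (divergence)")
  model@U[G, ] <- st$Uj
  model@V[j, ] <- st$Vj
  model@V[k, ] <- st$Vk
  model@b[j] <- st$bj
  model@b[k] <- st$bk
  model
}

# Core update shared by sgdStep() and the training loop. Returns the new
# values of the touched parameters, computed from the old ones.
.sgdStepCore <- function(U, V, b, G, i, j, k, params) {
  rho <- params$rho; gamma <- params$gamma
  UG <- U[G, , drop = FALSE]
  meanU <- colMeans(UG)
  Vj <- V[j, ]; Vk <- V[k, ]; Ui <- U[i, ]
  sGj <- sum(meanU * Vj) + b[j]
  sij <- sum(Ui * Vj) + b[j]
  sik <- sum(Ui * Vk) + b[k]
  s <- rho * sGj + (1 - rho) * sij - sik
  cc <- -1 / (1 + exp(s))           # = -sigma(-s)
  coef <- rep(rho / length(G), length(G))
  coef[G == i] <- coef[G == i] + (1 - rho)
  # dU_t = cc*coef_t*V_j (- cc*V_k for the anchor) + alphaM*U_t
  dUG <- (cc * coef) %o% Vj + params$alphaM * UG
  dUG[G == i, ] <- dUG[G == i, ] - cc * Vk
  list(Uj = UG - gamma * dUG,
       Vj = Vj - gamma * (cc * (rho * meanU + (1 - rho) * Ui) +
                            params$alphaL * Vj),
       Vk = Vk - gamma * (-cc * Ui + params$alphaL * Vk),
       bj = b[j] - gamma * (cc + params$betaL * b[j]),
       bk = b[k] - gamma * (-cc + params$betaL * b[k]),
       loss = .softplusNeg(s) +
         params$alphaM / 2 * sum(UG^2) +
         params$alphaL / 2 * (sum(Vj^2) + sum(Vk^2)) +
         params$betaL / 2 * (b[j]^2 + b[k]^2))
}

# Precomputed index of a network for fast sampling/training.
.networkIndex <- function(net) {
  p <- interactionPairs(net)
  nm <- length(mirnaIds(net)); nl <- length(lncrnaIds(net))
  adjL <- lapply(seq_len(nm), function(i) p[p[, 1L] == i, 2L])
  adjM <- lapply(seq_len(nl), function(j) p[p[, 2L] == j, 1L])
  nonAdjL <- lapply(adjL, function(L) setdiff(seq_len(nl), L))
  degL <- lengths(adjL)
  eligible <- which(degL > 0L & degL < nl)
  if (any(degL == nl))
    warning(sum(degL == nl),
            " miRNA(s) with no unobserved lncRNA skipped during sampling")
  list(adjL = adjL, adjM = adjM, nonAdjL = nonAdjL, eligible = eligible,
       nm = nm, nl = nl, npairs = nrow(p))
}

#' Sample one training triple
#'
#' Draws uniformly: an anchor miRNA i among miRNAs with at least one
#' observed and one unobserved lncRNA, an observed partner j of i, an
#' unobserved lncRNA k of i, and a miRNA group G = {i} plus up to
#' \code{groupSize - 1} other observed partners of j (all of them when
#' fewer exist). Uses the current RNG state.
#'
#' @param net an [InteractionNetwork-class].
#' @param groupSize target |G|.
#' @return list with elements \code{i}, \code{j}, \code{k} (indices) and
#'   \code{G} (index vector containing \code{i}).
#' @export
sampleTriple <- function(net, groupSize = 3L) {
  idx <- .networkIndex(net)
  if (!length(idx$eligible))
    stop("no miRNA with both observed and unobserved lncRNAs")
  .sampleTripleIdx(idx, groupSize)
}

.sampleTripleIdx <- function(idx, groupSize) {
  i <- idx$eligible[sample.int(length(idx$eligible), 1L)]
  Li <- idx$adjL[[i]]
  j <- Li[sample.int(length(Li), 1L)]
  nonL <- idx$nonAdjL[[i]]
  k <- nonL[sample.int(length(nonL), 1L)]
  Mj <- idx$adjM[[j]]
  extra <- min(groupSize - 1L, length(Mj) - 1L)
  G <- if (extra > 0L) {
    others <- Mj[Mj != i]
    c(i, others[sample.int(length(others), extra)])
  } else i
  list(i = i, j = j, k = k, G = G)
}

#' Train the group-preference Bayesian ranking model
#'
#' Minimizes the sampled pairwise-ranking objective by stochastic gradient
#' descent. One epoch draws as many triples as there are observed pairs;
#' training runs for \code{params$iters} epochs, recording the mean triple
#' loss per epoch. With the same seed the trajectory is fully reproducible.
#'
#' @param net an [InteractionNetwork-class] of training pairs.
#' @param Sm,Sl optional [SimilarityMatrix-class] objects over the miRNA
#'   and lncRNA id universes; used only when \code{init = "similarity"}
#'   (and later by [aggregateScore()] / [rankCandidates()]).
#' @param params a [bprParams()] list.
#' @param init "random" (zero-mean normal entries, sd 0.01) or
#'   "similarity" (U and V from the top-d eigenvectors of Sm and Sl,
#'   rescaled to entry-sd 0.01).
#' @param initState optional explicit initialization: list with elements
#'   \code{U}, \code{V}, \code{b} (overrides \code{init}).
#' @param triples optional explicit list of training triples; when given,
#'   they are consumed in order instead of being sampled (epochs of
#'   |pairs| triples).
#' @return a [GroupBPRModel-class].
#' @export
trainGroupBPR <- function(net, Sm = NULL, Sl = NULL, params = bprParams(),
                          init = c("random", "similarity"),
                          initState = NULL, triples = NULL) {
  stopifnot(inherits(params, "bprParams"))
  init <- match.arg(init)
  idx <- .networkIndex(net)
  if (idx$npairs < 1L) stop("network has no observed pairs")
  nm <- idx$nm; nl <- idx$nl; d <- params$d
  set.seed(params$seed)
  if (!is.null(initState)) {
    U <- initState$U; V <- initState$V; b <- initState$b
  } else if (init == "similarity") {
    if (is.null(Sm) || is.null(Sl))
      stop("similarity initialization requires Sm and Sl")
    U <- .eigenInit(similarityValues(Sm), d)
    V <- .eigenInit(similarityValues(Sl), d)
    b <- numeric(nl)
  } else {
    U <- matrix(stats::rnorm(nm * d, sd = 0.01), nm, d)
    V <- matrix(stats::rnorm(nl * d, sd = 0.01), nl, d)
    b <- numeric(nl)
  }
  stopifnot(nrow(U) == nm, nrow(V) == nl, length(b) == nl)

  useFixed <- !is.null(triples)
  perEpoch <- idx$npairs
  nEpoch <- if (useFixed) ceiling(length(triples) / perEpoch)
            else params$iters
  epochLoss <- numeric(nEpoch)
  tpos <- 0L
  for (ep in seq_len(nEpoch)) {
    tot <- 0
    nstep <- if (useFixed) min(perEpoch, length(triples) - tpos) else perEpoch
    for (sidx in seq_len(nstep)) {
      tr <- if (useFixed) triples[[tpos + sidx]]
            else .sampleTripleIdx(idx, params$groupSize)
      st <- .sgdStepCore(U, V, b, tr$G, tr$i, tr$j, tr$k, params)
      U[tr$G, ] <- st$Uj
      V[tr$j, ] <- st$Vj
      V[tr$k, ] <- st$Vk
      b[tr$j] <- st$bj
      b[tr$k] <- st$bk
      tot <- tot + st$loss
    }
    if (useFixed) tpos <- tpos + nstep
    if (nstep > 0) epochLoss[ep] <- tot / nstep
    if (!all(is.finite(U)) || !all(is.finite(V)) || !all(is.finite(b)))
      stop("training diverged at epoch ", ep)
  }
  new("GroupBPRModel", U = U, V = V, b = b, params = unclass(params),
      epochLoss = epochLoss, mirnaIds = mirnaIds(net),
      lncrnaIds = lncrnaIds(net))
}

# top-d eigenvectors of a symmetric similarity matrix, rescaled so the
# entries have sd ~= 0.01 (same magnitude as the random initialization)
.eigenInit <- function(S, d) {
  n <- nrow(S)
  ev <- eigen((S + t(S)) / 2, symmetric = TRUE)$vectors
  k <- min(d, n)
  M <- matrix(0, n, d)
  M[, seq_len(k)] <- ev[, seq_len(k)]
  sdv <- stats::sd(as.vector(M))
  if (sdv > 0) M <- M * (0.01 / sdv)
  M
}

#' Save / load a model checkpoint
#'
#' The checkpoint is a single self-describing JSON file holding the latent
#' factors, biases, hyperparameters and id lists.
#'
#' @param model a [GroupBPRModel-class].
#' @param path checkpoint path.
#' @return \code{writeModel}: invisibly, \code{path}; \code{readModel}: the
#'   restored [GroupBPRModel-class].
#' @export
writeModel <- function(model, path) {
  jsonlite::write_json(
    list(format = "mirlnclink-model-1",
         mirnaIds = model@mirnaIds, lncrnaIds = model@lncrnaIds,
         d = ncol(model@U),
         U = as.vector(model@U), V = as.vector(model@V), b = model@b,
         params = model@params, epochLoss = model@epochLoss),
    path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname writeModel
#' @export
readModel <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(x$format, "mirlnclink-model-1"))
    stop("not a model checkpoint: ", path)
  d <- x$d
  new("GroupBPRModel",
      U = matrix(x$U, ncol = d), V = matrix(x$V, ncol = d), b = x$b,
      params = as.list(x$params), epochLoss = as.numeric(x$epochLoss),
      mirnaIds = x$mirnaIds, lncrnaIds = x$lncrnaIds)
}
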