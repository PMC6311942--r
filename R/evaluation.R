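# Local (per-miRNA) AUC, k-fold and leave-one-out cross validation.

#' Local rank-based AUC
#'
#' Mann-Whitney AUC of positive versus negative scores within one query's
#' candidate set: (number of concordant pairs + half the ties) divided by
#' |pos| * |neg|.
#'
#' @param pos,neg nonempty numeric score vectors.
#' @return the AUC in [0, 1].
#' @export
localAUC <- function(pos, neg) {
  if (!length(pos) || !length(neg))
    stop("both score lists must be nonempty")
  np <- length(pos)
  r <- rank(c(pos, neg))
  (sum(r[seq_len(np)]) - np * (np + 1) / 2) / (np * length(neg))
}

# Default fold scorer: train the group-preference ranking model on the
# training split and return the similarity-aggregated score matrix.
.gbcfScorer <- function(params) {
  force(params)
  function(trainNet, Sm, Sl, seed) {
    p <- params
    p$seed <- as.integer(seed)
    model <- trainGroupBPR(trainNet, Sm, Sl, params = p)
    .scoreMatrix(model) +
      .aggregateMatrix(trainNet, Sm, Sl, p$deltaM, p$deltaL)
  }
}

# Macro-averaged local AUC for one train/test split given a full score
# matrix. For each miRNA with test positives, negatives are the lncRNAs it
# is never observed with (in train or any test fold).
.splitAUC <- function(scores, testPairs, fullAdj) {
  mis <- unique(testPairs[, 1L])
  aucs <- vapply(mis, function(i) {
    posJ <- testPairs[testPairs[, 1L] == i, 2L]
    negJ <- which(!fullAdj[i, ])
    if (!length(negJ)) return(NA_real_)
    localAUC(scores[i, posJ], scores[i, negJ])
  }, numeric(1))
  mean(aucs, na.rm = TRUE)
}

.adjacencyLogical <- function(net) {
  A <- matrix(FALSE, length(mirnaIds(net)), length(lncrnaIds(net)))
  A[interactionPairs(net)] <- TRUE
  A
}

.subNetwork <- function(net, keepRows) {
  new("InteractionNetwork", mirnaIds = mirnaIds(net),
      lncrnaIds = lncrnaIds(net),
      pairs = interactionPairs(net)[keepRows, , drop = FALSE])
}

#' k-fold cross validation with local ranking
#'
#' Observed pairs are partitioned uniformly at random into k folds. For
#' each fold the model is trained on the remaining pairs and every held-out
#' pair is ranked, within its miRNA, against that miRNA's unobserved
#' lncRNAs (other folds' held-out positives are excluded from the negative
#' set — they are known positives, not sampled negatives). Per-miRNA local
#' AUCs are macro-averaged into a fold AUC; mean and SD are reported over
#' folds x repeats.
#'
#' @param net an [InteractionNetwork-class].
#' @param Sm,Sl optional [SimilarityMatrix-class] objects.
#' @param params a [bprParams()] list for the per-fold trainings.
#' @param k number of folds (>= 2, <= number of pairs).
#' @param repeats independent repetitions with fresh fold assignments.
#' @param seed seed for fold assignment and per-fold training.
#' @param scorer optional custom scoring function
#'   \code{function(trainNet, Sm, Sl, seed)} returning an nm x nl score
#'   matrix; defaults to training the ranking model. Useful for null or
#'   oracle baselines.
#' @return a [CVResult-class].
#' @export
kfoldCV <- function(net, Sm = NULL, Sl = NULL, params = bprParams(),
                    k = 5L, repeats = 1L, seed = 1L, scorer = NULL) {
  p <- interactionPairs(net)
  if (k < 2L) stop("k must be at least 2")
  if (k > nrow(p)) stop("k exceeds the number of observed pairs")
  if (is.null(scorer)) scorer <- .gbcfScorer(params)
  fullAdj <- .adjacencyLogical(net)
  foldAUCs <- numeric(0)
  for (rep in seq_len(repeats)) {
    set.seed(seed + 7919L * (rep - 1L))
    fold <- sample(rep_len(seq_len(k), nrow(p)))
    for (f in seq_len(k)) {
      trainNet <- .subNetwork(net, fold != f)
      scores <- scorer(trainNet, Sm, Sl,
                       seed = seed + 7919L * (rep - 1L) + 131L * f)
      foldAUCs <- c(foldAUCs,
                    .splitAUC(scores, p[fold == f, , drop = FALSE], fullAdj))
    }
  }
  new("CVResult", scheme = sprintf("%d-fold", k), k = as.integer(k),
      repeats = as.integer(repeats), foldAUCs = foldAUCs,
      meanAUC = mean(foldAUCs),
      sdAUC = if (length(foldAUCs) > 1L) stats::sd(foldAUCs) else 0,
      seed = as.integer(seed))
}

#' Leave-one-out cross validation
#'
#' In exact mode each observed pair is held out in turn and the model is
#' retrained without it — feasible only for small networks (the retrain
#' count equals the pair count), so networks above \code{exactCap} pairs
#' are refused. The fold-approximate mode groups the singleton tests into
#' \code{nRetrains} retrains (each pair still evaluated individually as the
#' lone positive of its query) and is labelled as an approximation in the
#' result. Per-pair AUCs are averaged per miRNA, then macro-averaged.
#'
#' @inheritParams kfoldCV
#' @param mode "exact" or "fold-approximate".
#' @param nRetrains number of retrains in fold-approximate mode.
#' @param exactCap maximum pair count accepted in exact mode.
#' @return a [CVResult-class]; \code{foldAUCs} holds the per-miRNA AUCs.
#' @export
loocv <- function(net, Sm = NULL, Sl = NULL, params = bprParams(),
                  mode = c("fold-approximate", "exact"), nRetrains = 20L,
                  exactCap = 200L, seed = 1L, scorer = NULL) {
  mode <- match.arg(mode)
  p <- interactionPairs(net)
  np <- nrow(p)
  if (mode == "exact" && np > exactCap)
    stop("exact LOOCV over ", np, " pairs exceeds the cap (", exactCap,
         "); use mode = \"fold-approximate\" or raise exactCap")
  if (is.null(scorer)) scorer <- .gbcfScorer(params)
  fullAdj <- .adjacencyLogical(net)
  groups <- if (mode == "exact") seq_len(np) else {
    set.seed(seed)
    sample(rep_len(seq_len(min(nRetrains, np)), np))
  }
  pairAUC <- numeric(np)
  for (g in unique(sort(groups))) {
    held <- which(groups == g)
    trainNet <- .subNetwork(net, -held)
    scores <- scorer(trainNet, Sm, Sl, seed = seed + 131L * g)
    for (h in held) {
      i <- p[h, 1L]
      negJ <- which(!fullAdj[i, ])
      pairAUC[h] <- if (length(negJ))
        localAUC(scores[i, p[h, 2L]], scores[i, negJ]) else NA_real_
    }
  }
  perMirna <- tapply(pairAUC, p[, 1L], mean, na.rm = TRUE)
  perMirna <- perMirna[is.finite(perMirna)]
  scheme <- if (mode == "exact") "LOOCV (exact)"
            else sprintf("LOOCV (fold-approximate, %d retrains)", nRetrains)
  new("CVResult", scheme = scheme, k = NA_integer_, repeats = 1L,
      foldAUCs = as.numeric(perMirna), meanAUC = mean(perMirna),
      sdAUC = if (length(perMirna) > 1L) stats::sd(perMirna) else 0,
      seed = as.integer(seed))
}
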