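# Similarity-aggregated final scores and top-k candidate ranking.

# Base score matrix S[i, j] = U_i . V_j + b_j
.scoreMatrix <- function(model) {
  tcrossprod(model@U, model@V) +
    matrix(model@b, nrow(model@U), nrow(model@V), byrow = TRUE)
}

# Similarity evidence matrix added to the base scores:
# termM[i,j] = deltaM/|M_j| * sum_{i' in M_j} max(0, Sm[i,i'])
# termL[i,j] = deltaL/|L_i| * sum_{j' in L_i} max(0, Sl[j,j'])
# Empty neighbor sets and invalid similarity rows contribute 0.
.aggregateMatrix <- function(net, Sm, Sl, deltaM, deltaL) {
  nm <- length(mirnaIds(net)); nl <- length(lncrnaIds(net))
  A <- matrix(0, nm, nl)
  A[interactionPairs(net)] <- 1
  out <- matrix(0, nm, nl)
  if (!is.null(Sm) && deltaM != 0) {
    SmC <- pmax(similarityValues(Sm), 0)
    colDeg <- colSums(A)
    termM <- SmC %*% A
    termM <- sweep(termM, 2L, pmax(colDeg, 1), "/")
    out <- out + deltaM * termM
  }
  if (!is.null(Sl) && deltaL != 0) {
    SlC <- pmax(similarityValues(Sl), 0)
    rowDeg <- rowSums(A)
    termL <- A %*% SlC
    termL <- sweep(termL, 1L, pmax(rowDeg, 1), "/")
    out <- out + deltaL * termL
  }
  out
}

#' Similarity-aggregated prediction score
#'
#' Adds the neighbor-similarity evidence to the latent-factor score of an
#' unobserved pair (i, j):
#' \deqn{Score_{ij} \mathrel{+}= \frac{\delta_m}{|M_j|}
#'   \sum_{i' \in M_j} \max(0, S_m(i, i')) + \frac{\delta_l}{|L_i|}
#'   \sum_{j' \in L_i} \max(0, S_l(j, j'))}
#' where \eqn{M_j} are the observed miRNA partners of lncRNA j and
#' \eqn{L_i} the observed lncRNA partners of miRNA i. Negative similarity
#' entries are clamped to 0 here only (they remain informative elsewhere);
#' empty neighbor sets and invalid similarity rows contribute 0.
#'
#' @param model a [GroupBPRModel-class].
#' @param net the training [InteractionNetwork-class].
#' @param Sm,Sl [SimilarityMatrix-class] over the network's id universes
#'   (either may be NULL to drop its term).
#' @param i miRNA index or id.
#' @param j lncRNA index or id.
#' @param deltaM,deltaL similarity tradeoffs (default from the model).
#' @return the aggregated score, a single number.
#' @export
aggregateScore <- function(model, net, Sm = NULL, Sl = NULL, i, j,
                           deltaM = model@params$deltaM,
                           deltaL = model@params$deltaL) {
  i <- .resolveIdx(i, model@mirnaIds, "miRNA")
  j <- .resolveIdx(j, model@lncrnaIds, "lncRNA")
  p <- interactionPairs(net)
  s <- predictScore(model, i, j)
  if (!is.null(Sm) && deltaM != 0) {
    Mj <- p[p[, 2L] == j, 1L]
    if (length(Mj))
      s <- s + deltaM / length(Mj) *
        sum(pmax(similarityValues(Sm)[i, Mj], 0))
  }
  if (!is.null(Sl) && deltaL != 0) {
    Li <- p[p[, 1L] == i, 2L]
    if (length(Li))
      s <- s + deltaL / length(Li) *
        sum(pmax(similarityValues(Sl)[j, Li], 0))
  }
  s
}

#' Rank candidate lncRNAs for a query miRNA
#'
#' Scores every lncRNA that is not an observed partner of the query with
#' the similarity-aggregated score and returns the top k in descending
#' order, ties broken by candidate id (lexicographic).
#'
#' @param model a [GroupBPRModel-class].
#' @param net the training [InteractionNetwork-class].
#' @param Sm,Sl optional [SimilarityMatrix-class] objects.
#' @param query miRNA id or index.
#' @param k number of candidates to return (all candidates when fewer).
#' @param deltaM,deltaL similarity tradeoffs.
#' @return data.frame with columns query, candidate, score, rank.
#' @export
rankCandidates <- function(model, net, Sm = NULL, Sl = NULL, query, k = 50L,
                           deltaM = model@params$deltaM,
                           deltaL = model@params$deltaL) {
  i <- .resolveIdx(query, model@mirnaIds, "miRNA")
  p <- interactionPairs(net)
  observed <- p[p[, 1L] == i, 2L]
  cand <- setdiff(seq_along(model@lncrnaIds), observed)
  if (!length(cand)) stop("query miRNA has no unobserved candidates")
  scores <- (.scoreMatrix(model) +
               .aggregateMatrix(net, Sm, Sl, deltaM, deltaL))[i, cand]
  ids <- model@lncrnaIds[cand]
  o <- order(-scores, ids)
  take <- o[seq_len(min(k, length(o)))]
  data.frame(query = model@mirnaIds[i], candidate = ids[take],
             score = scores[take], rank = seq_along(take))
}
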