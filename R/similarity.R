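# Expression-profile and biological-function RNA-RNA similarities, and the
# selector assembling the per-class matrices the ranking model consumes.

#' Expression-profile similarity (Pearson correlation)
#'
#' For every pair of RNAs with usable profiles, the similarity is the
#' Pearson correlation coefficient of their attribute vectors
#' \deqn{ES(i,j) = \frac{\sum_k (e_{ik}-\bar e_i)(e_{jk}-\bar e_j)}
#'   {\sqrt{\sum_k (e_{ik}-\bar e_i)^2 \sum_k (e_{jk}-\bar e_j)^2}}.}
#' RNAs with a missing or zero-variance profile get an all-zero row flagged
#' invalid. The diagonal of valid RNAs is 1.
#'
#' @param profiles an [ExpressionProfileSet-class] with at least 2 usable
#'   profiles and N >= 2 attributes.
#' @return a [SimilarityMatrix-class] of kind "expression".
#' @export
expressionSimilarity <- function(profiles) {
  if (ncol(profiles@profiles) < 2L)
    stop("correlation undefined for fewer than 2 attributes")
  usable <- .usableProfiles(profiles)
  if (sum(usable) < 2L) stop("need at least 2 usable profiles")
  n <- length(profiles@rnaIds)
  X <- profiles@profiles[usable, , drop = FALSE]
  Xc <- X - rowMeans(X)
  d <- sqrt(rowSums(Xc^2))
  S <- tcrossprod(Xc) / outer(d, d)   # exactly symmetric
  S <- pmin(pmax(S, -1), 1)
  diag(S) <- 1
  v <- matrix(0, n, n)
  v[usable, usable] <- S
  SimilarityMatrix(v, rnaIds = profiles@rnaIds, valid = usable,
                   kind = "expression")
}

#' Biological-function similarity from target-gene overlap
#'
#' Local neighbor-overlap indices on the RNA-target gene bipartite network.
#' With \eqn{\Gamma_i} the gene neighborhood of RNA i and
#' \eqn{|\Gamma_z|} the RNA-degree of gene z:
#' \itemize{
#'   \item CN: \eqn{|\Gamma_i \cap \Gamma_j|}
#'   \item AA: \eqn{\sum_{z \in \Gamma_i \cap \Gamma_j} 1/\ln|\Gamma_z|}
#'     (natural log; genes with RNA-degree <= 1 are skipped, they carry no
#'     co-neighbor evidence and would divide by log 1)
#'   \item JA: \eqn{|\Gamma_i \cap \Gamma_j| / |\Gamma_i \cup \Gamma_j|}
#'   \item SA: \eqn{|\Gamma_i \cap \Gamma_j| /
#'     \sqrt{|\Gamma_i||\Gamma_j|}} (Salton cosine)
#' }
#' Pairs with an empty neighborhood score 0; the diagonal is the index's
#' self-value (1 for JA/SA when \eqn{\Gamma_i} is nonempty).
#'
#' @param tg a [TargetGeneNetwork-class].
#' @param index one of "CN", "AA", "JA", "SA".
#' @return a [SimilarityMatrix-class] of kind "function".
#' @export
functionSimilarity <- function(tg, index = c("CN", "AA", "JA", "SA")) {
  index <- match.arg(index)
  B <- .incidenceMatrix(tg)
  deg <- rowSums(B)
  inter <- tcrossprod(B)
  v <- switch(index,
    CN = inter,
    AA = {
      gdeg <- colSums(B)
      wz <- ifelse(gdeg > 1, 1 / log(gdeg), 0)
      B %*% (wz * t(B))    # 0/1 incidence keeps this exactly symmetric
    },
    JA = {
      un <- outer(deg, deg, "+") - inter
      ifelse(un > 0, inter / un, 0)
    },
    SA = {
      den <- sqrt(outer(deg, deg))
      ifelse(den > 0, inter / den, 0)
    })
  SimilarityMatrix(v, rnaIds = tg@rnaIds, kind = "function")
}

# Re-index a similarity matrix onto a target id universe; ids absent from
# the source get zero rows flagged invalid.
.expandSimilarity <- function(sim, ids) {
  n <- length(ids)
  pos <- match(ids, rnaIds(sim))
  v <- matrix(0, n, n)
  valid <- rep(FALSE, n)
  have <- !is.na(pos)
  valid[have] <- validMask(sim)[pos[have]]
  v[have, have] <- similarityValues(sim)[pos[have], pos[have]]
  v[!valid, ] <- 0
  v[, !valid] <- 0
  SimilarityMatrix(v, rnaIds = ids, valid = valid, kind = similarityKind(sim))
}

#' Assemble the per-class similarity matrices S_m and S_l
#'
#' Builds the miRNA-miRNA and lncRNA-lncRNA similarity matrices from the
#' requested source kind on each side and re-indexes them onto the
#' interaction network's id universes. The defaults follow the similarity
#' choices that performed best in cross-validation: biological-function
#' similarity (Adamic-Adar index) for miRNAs, expression-profile similarity
#' for lncRNAs; when a function-based lncRNA similarity is requested, the
#' Salton index is the default. Any RNA absent from the chosen source gets
#' an all-zero row flagged invalid.
#'
#' @param net an [InteractionNetwork-class] supplying the id universes.
#' @param kindMirna,kindLncrna "sequence", "expression" or "function".
#' @param mirnaExpression,lncrnaExpression [ExpressionProfileSet-class]
#'   sources.
#' @param mirnaTargets,lncrnaTargets [TargetGeneNetwork-class] sources.
#' @param mirnaSequences,lncrnaSequences [SequenceSet-class] sources.
#' @param indexMirna,indexLncrna function-similarity index per side.
#' @param alignParams [alignmentParams()] for sequence similarity.
#' @return list with elements \code{Sm} and \code{Sl}
#'   ([SimilarityMatrix-class]).
#' @export
selectSimilarity <- function(net,
                             kindMirna = "function",
                             kindLncrna = "expression",
                             mirnaExpression = NULL, lncrnaExpression = NULL,
                             mirnaTargets = NULL, lncrnaTargets = NULL,
                             mirnaSequences = NULL, lncrnaSequences = NULL,
                             indexMirna = "AA", indexLncrna = "SA",
                             alignParams = alignmentParams()) {
  build <- function(kind, expr, targets, seqs, index, side) {
    switch(kind,
      expression = {
        if (is.null(expr)) stop("no expression data supplied for ", side)
        expressionSimilarity(expr)
      },
      "function" = {
        if (is.null(targets)) stop("no target-gene data supplied for ", side)
        functionSimilarity(targets, index)
      },
      sequence = {
        if (is.null(seqs)) stop("no sequence data supplied for ", side)
        sequenceSimilarity(seqs, alignParams)
      },
      stop("unknown similarity kind: ", kind))
  }
  Sm <- build(kindMirna, mirnaExpression, mirnaTargets, mirnaSequences,
              indexMirna, "miRNAs")
  Sl <- build(kindLncrna, lncrnaExpression, lncrnaTargets, lncrnaSequences,
              indexLncrna, "lncRNAs")
  list(Sm = .expandSimilarity(Sm, mirnaIds(net)),
       Sl = .expandSimilarity(Sl, lncrnaIds(net)))
}
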