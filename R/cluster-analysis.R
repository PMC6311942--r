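# Observed-vs-unobserved cluster similarity analysis.

#' Compare similarity within observed and unobserved partner clusters
#'
#' For every anchor RNA with at least \code{minDegree} observed partners,
#' the partners on the opposite side form the observed cluster and the
#' remaining RNAs of that side the unobserved cluster. The mean pairwise
#' similarity (off-diagonal) within the observed cluster is compared
#' against the unobserved cluster's mean, which serves as the baseline. An
#' anchor is "remarkable" when the absolute difference exceeds 0.3 times
#' the standard deviation of the observed cluster's pairwise similarities.
#' Anchors whose clusters retain fewer than two members with valid
#' similarity rows are counted as invalid and excluded from the reported
#' fractions.
#'
#' @param net an [InteractionNetwork-class].
#' @param sim a [SimilarityMatrix-class] over the cluster side's RNA class
#'   (miRNA similarity for \code{side = "mirna"}, etc.).
#' @param side which RNA class forms the clusters: "mirna" clusters are
#'   anchored by lncRNAs, "lncrna" clusters by miRNAs.
#' @param minDegree minimum observed-partner count for an anchor; defaults
#'   to 3 for miRNA clusters and 6 for lncRNA clusters (anchors
#'   interacting with more than 5 lncRNAs).
#' @param sdThreshold multiplier of the observed-cluster SD defining a
#'   remarkable difference (default 0.3).
#' @return a [ClusterAnalysisResult-class].
#' @export
clusterPCCAnalysis <- function(net, sim, side = c("mirna", "lncrna"),
                               minDegree = NULL, sdThreshold = 0.3) {
  side <- match.arg(side)
  if (is.null(minDegree)) minDegree <- if (side == "mirna") 3L else 6L
  minDegree <- as.integer(minDegree)
  if (minDegree < 2L) stop("minDegree must be at least 2")
  p <- interactionPairs(net)
  if (side == "mirna") {
    clusterIds <- mirnaIds(net); anchorIds <- lncrnaIds(net)
    members <- lapply(seq_along(anchorIds), function(a) p[p[, 2L] == a, 1L])
  } else {
    clusterIds <- lncrnaIds(net); anchorIds <- mirnaIds(net)
    members <- lapply(seq_along(anchorIds), function(a) p[p[, 1L] == a, 2L])
  }
  if (!identical(rnaIds(sim), clusterIds))
    stop("similarity matrix ids do not match the '", side, "' side of the network")
  S <- similarityValues(sim)
  ok <- validMask(sim)
  meanOffDiag <- function(idx) {
    if (length(idx) < 2L) return(c(NA_real_, NA_real_))
    M <- S[idx, idx]
    v <- M[upper.tri(M)]
    c(mean(v), stats::sd(v))
  }
  qualifying <- which(lengths(members) >= minDegree)
  if (!length(qualifying)) {
    warning("no anchors meet the minimum degree")
    return(new("ClusterAnalysisResult", side = side,
               anchors = data.frame(), invalidShare = NA_real_,
               higherShare = NA_real_, minDegree = minDegree))
  }
  rows <- lapply(qualifying, function(a) {
    obs <- members[[a]][ok[members[[a]]]]
    uno <- setdiff(which(ok), members[[a]])
    om <- meanOffDiag(obs)
    bm <- meanOffDiag(uno)
    valid <- !is.na(om[1L]) && !is.na(bm[1L])
    data.frame(id = anchorIds[a], degree = length(members[[a]]),
               observedMean = om[1L], baselineMean = bm[1L],
               observedSD = om[2L],
               higher = if (valid) om[1L] > bm[1L] else NA,
               remarkable = if (valid && is.finite(om[2L]))
                 abs(om[1L] - bm[1L]) > sdThreshold * om[2L] else NA,
               valid = valid)
  })
  anchors <- do.call(rbind, rows)
  nInvalid <- sum(!anchors$valid)
  nValid <- sum(anchors$valid)
  new("ClusterAnalysisResult", side = side, anchors = anchors,
      invalidShare = nInvalid / nrow(anchors),
      higherShare = if (nValid) sum(anchors$higher, na.rm = TRUE) / nValid
                    else NA_real_,
      minDegree = minDegree)
}

#' Write a cluster-analysis report
#'
#' Per-anchor tab-delimited table followed by no summary row; the summary
#' fractions are available from the object itself.
#'
#' @param result a [ClusterAnalysisResult-class].
#' @param path output path.
#' @return invisibly, \code{path}.
#' @export
writeClusterReport <- function(result, path) {
  utils::write.table(result@anchors, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
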