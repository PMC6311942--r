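#' @import methods
#' @importClassesFrom Biostrings DNAStringSet
#' @importFrom stats rnorm runif sd var
#' @importFrom utils read.table write.table
NULL

#' Bipartite miRNA-lncRNA interaction network
#'
#' Holds the observed positive interaction pairs between an ordered set of
#' miRNA identifiers and an ordered set of lncRNA identifiers. Only observed
#' (positive) pairs are stored; all remaining pairs are "unobserved", never
#' "negative".
#'
#' @slot mirnaIds character vector of unique miRNA identifiers (size nm).
#' @slot lncrnaIds character vector of unique lncRNA identifiers (size nl).
#' @slot pairs integer matrix with two columns \code{mirna} and \code{lncrna}
#'   holding 1-based indices into the id vectors; one row per observed pair,
#'   no duplicates.
#'
#' @seealso [InteractionNetwork()], [readInteractions()], [networkDensity()]
#' @export
setClass("InteractionNetwork",
  slots = c(mirnaIds = "character", lncrnaIds = "character",
            pairs = "matrix"))

setValidity("InteractionNetwork", function(object) {
  msg <- character()
  if (length(object@mirnaIds) < 1L) msg <- c(msg, "need at least one miRNA id")
  if (length(object@lncrnaIds) < 1L) msg <- c(msg, "need at least one lncRNA id")
  if (anyDuplicated(object@mirnaIds)) msg <- c(msg, "duplicated miRNA ids")
  if (anyDuplicated(object@lncrnaIds)) msg <- c(msg, "duplicated lncRNA ids")
  p <- object@pairs
  if (!is.matrix(p) || ncol(p) != 2L || !is.integer(p))
    msg <- c(msg, "'pairs' must be an integer matrix with 2 columns")
  else {
    if (nrow(p) > 0) {
      if (min(p) < 1L || max(p[, 1L]) > length(object@mirnaIds) ||
          max(p[, 2L]) > length(object@lncrnaIds))
        msg <- c(msg, "pair index out of range")
      if (anyDuplicated(p)) msg <- c(msg, "duplicate pairs")
    }
  }
  if (length(msg)) msg else TRUE
})

#' Per-RNA expression profiles
#'
#' Numeric expression vectors (one per RNA) over a fixed set of attributes
#' (tissues / cell lines). RNAs whose profile is missing from the source data
#' are retained with an all-NA row and \code{available = FALSE}, so that the
#' id universe stays aligned with the interaction network.
#'
#' @slot rnaIds character vector of RNA identifiers.
#' @slot profiles numeric matrix, one row per RNA, N columns of attributes.
#' @slot available logical; FALSE for RNAs with no (or incomplete) profile.
#' @export
setClass("ExpressionProfileSet",
  slots = c(rnaIds = "character", profiles = "matrix", available = "logical"))

setValidity("ExpressionProfileSet", function(object) {
  msg <- character()
  n <- length(object@rnaIds)
  if (anyDuplicated(object@rnaIds)) msg <- c(msg, "duplicated RNA ids")
  if (!is.numeric(object@profiles)) msg <- c(msg, "'profiles' must be numeric")
  if (nrow(object@profiles) != n) msg <- c(msg, "profile rows != number of ids")
  if (length(object@available) != n) msg <- c(msg, "'available' length mismatch")
  if (any(object@available & !stats::complete.cases(object@profiles)))
    msg <- c(msg, "rows flagged available must be complete")
  if (length(msg)) msg else TRUE
})

#' RNA to target-gene bipartite network
#'
#' Edges between RNAs (miRNAs or lncRNAs) and their target genes, the raw
#' material of the biological-function similarity indices. The gene neighbor
#' set of RNA i may be empty.
#'
#' @slot rnaIds character vector of RNA identifiers.
#' @slot geneIds character vector of gene identifiers.
#' @slot edges integer matrix with columns \code{rna}, \code{gene} (1-based
#'   indices), no duplicates.
#' @export
setClass("TargetGeneNetwork",
  slots = c(rnaIds = "character", geneIds = "character", edges = "matrix"))

setValidity("TargetGeneNetwork", function(object) {
  msg <- character()
  if (anyDuplicated(object@rnaIds)) msg <- c(msg, "duplicated RNA ids")
  if (anyDuplicated(object@geneIds)) msg <- c(msg, "duplicated gene ids")
  e <- object@edges
  if (!is.matrix(e) || ncol(e) != 2L || !is.integer(e))
    msg <- c(msg, "'edges' must be an integer matrix with 2 columns")
  else if (nrow(e) > 0) {
    if (min(e) < 1L || max(e[, 1L]) > length(object@rnaIds) ||
        max(e[, 2L]) > length(object@geneIds))
      msg <- c(msg, "edge index out of range")
    if (anyDuplicated(e)) msg <- c(msg, "duplicate edges")
  }
  if (length(msg)) msg else TRUE
})

#' Nucleotide sequence collection
#'
#' Sequences for one RNA class, normalized to the DNA alphabet (U mapped to
#' T) so that miRNA and lncRNA sequences are aligned under one convention.
#' Only A, C, G, T and N are accepted after normalization.
#'
#' @slot rnaIds character vector of RNA identifiers.
#' @slot sequences a [Biostrings::DNAStringSet] parallel to \code{rnaIds}.
#' @export
setClass("SequenceSet",
  slots = c(rnaIds = "character", sequences = "DNAStringSet"))

setValidity("SequenceSet", function(object) {
  msg <- character()
  if (anyDuplicated(object@rnaIds)) msg <- c(msg, "duplicated RNA ids")
  if (length(object@sequences) != length(object@rnaIds))
    msg <- c(msg, "sequence count != id count")
  if (length(object@sequences) && any(Biostrings::width(object@sequences) == 0L))
    msg <- c(msg, "empty sequence")
  if (length(object@sequences)) {
    af <- Biostrings::alphabetFrequency(object@sequences, collapse = TRUE)
    bad <- af[setdiff(names(af), c("A", "C", "G", "T", "N"))]
    if (sum(bad) > 0) msg <- c(msg, "non-nucleotide characters (other than N)")
  }
  if (length(msg)) msg else TRUE
})

#' Symmetric RNA-RNA similarity matrix
#'
#' A square similarity matrix over one RNA class together with a validity
#' mask: RNAs absent from the source data (e.g. no expression profile) keep
#' their row/column, filled with zeros and flagged invalid, so downstream
#' consumers can distinguish "no evidence" from "similarity zero".
#'
#' Value ranges by kind: \code{expression} in [-1, 1], \code{sequence} in
#' [0, 1], \code{function} nonnegative (CN and Adamic-Adar are unbounded
#' above).
#'
#' @slot rnaIds character vector of RNA identifiers.
#' @slot values numeric symmetric matrix.
#' @slot valid logical; FALSE rows/columns are all zero.
#' @slot kind one of "sequence", "expression", "function".
#' @export
setClass("SimilarityMatrix",
  slots = c(rnaIds = "character", values = "matrix", valid = "logical",
            kind = "character"))

setValidity("SimilarityMatrix", function(object) {
  msg <- character()
  n <- length(object@rnaIds)
  v <- object@values
  if (!identical(dim(v), c(n, n))) msg <- c(msg, "'values' must be n x n")
  if (length(object@valid) != n) msg <- c(msg, "'valid' length mismatch")
  if (!object@kind %in% c("sequence", "expression", "function"))
    msg <- c(msg, "unknown similarity kind")
  if (length(msg) == 0L && n > 0) {
    if (any(!is.finite(v))) msg <- c(msg, "non-finite values")
    else {
      if (max(abs(v - t(v))) > 1e-12) msg <- c(msg, "matrix not symmetric")
      eps <- 1e-9
      rng <- switch(object@kind,
        expression = c(-1 - eps, 1 + eps),
        sequence   = c(-eps, 1 + eps),
        "function" = c(-eps, Inf))
      if (min(v) < rng[1L] || max(v) > rng[2L])
        msg <- c(msg, sprintf("values outside declared range for kind '%s'",
                              object@kind))
      if (any(!object@valid) &&
          any(v[!object@valid, , drop = FALSE] != 0))
        msg <- c(msg, "invalid rows must be all zero")
    }
  }
  if (length(msg)) msg else TRUE
})

#' Trained group-preference Bayesian pairwise-ranking model
#'
#' Latent factors and item biases of the bilinear scoring function
#' \eqn{Score_{ij} = U_i \cdot V_j + b_j}, together with the hyperparameters
#' used to train them and the per-epoch mean triple loss.
#'
#' @slot U numeric matrix nm x d of miRNA latent factors.
#' @slot V numeric matrix nl x d of lncRNA latent factors.
#' @slot b numeric length-nl lncRNA bias vector.
#' @slot params the `bprParams()` list the model was trained with.
#' @slot epochLoss numeric; mean sampled-triple loss per training epoch.
#' @slot mirnaIds,lncrnaIds id vectors of the training network.
#' @export
setClass("GroupBPRModel",
  slots = c(U = "matrix", V = "matrix", b = "numeric", params = "list",
            epochLoss = "numeric", mirnaIds = "character",
            lncrnaIds = "character"))

setValidity("GroupBPRModel", function(object) {
  msg <- character()
  if (nrow(object@U) != length(object@mirnaIds))
    msg <- c(msg, "U rows != number of miRNAs")
  if (nrow(object@V) != length(object@lncrnaIds))
    msg <- c(msg, "V rows != number of lncRNAs")
  if (ncol(object@U) != ncol(object@V)) msg <- c(msg, "U/V dimension mismatch")
  if (length(object@b) != nrow(object@V)) msg <- c(msg, "bias length != nl")
  if (any(!is.finite(object@U)) || any(!is.finite(object@V)) ||
      any(!is.finite(object@b)))
    msg <- c(msg, "non-finite model parameters")
  if (length(msg)) msg else TRUE
})

#' Cross-validation result
#'
#' Per-fold local (per-miRNA macro-averaged) AUCs under a leave-one-out or
#' k-fold protocol, with their mean and standard deviation and the seed that
#' produced the fold assignment.
#'
#' @slot scheme character description, e.g. "5-fold" or
#'   "LOOCV (fold-approximate)".
#' @slot k number of folds (NA for exact LOOCV).
#' @slot repeats number of independent repeats.
#' @slot foldAUCs numeric vector of per-fold (or per-retrain) AUCs.
#' @slot meanAUC,sdAUC summary of \code{foldAUCs}.
#' @slot seed integer seed of the fold assignment.
#' @export
setClass("CVResult",
  slots = c(scheme = "character", k = "integer", repeats = "integer",
            foldAUCs = "numeric", meanAUC = "numeric", sdAUC = "numeric",
            seed = "integer"))

setValidity("CVResult", function(object) {
  msg <- character()
  a <- object@foldAUCs
  if (length(a) && (min(a) < 0 || max(a) > 1))
    msg <- c(msg, "AUC outside [0, 1]")
  if (length(a) && abs(object@meanAUC - mean(a)) > 1e-8)
    msg <- c(msg, "meanAUC inconsistent with foldAUCs")
  if (length(msg)) msg else TRUE
})

#' Observed-vs-unobserved cluster similarity analysis result
#'
#' For each anchor RNA with enough observed partners, the mean pairwise
#' similarity within its observed partner group is compared against the mean
#' pairwise similarity within the unobserved (non-partner) group, which
#' serves as the baseline. An anchor is "remarkable" when the absolute
#' difference exceeds 0.3 times the standard deviation of the observed
#' group's pairwise similarities.
#'
#' @slot side which RNA class forms the clusters ("mirna" or "lncrna").
#' @slot anchors data.frame with one row per qualifying anchor: id, degree,
#'   observedMean, baselineMean, observedSD, higher, remarkable, valid.
#' @slot invalidShare fraction of qualifying anchors excluded for lack of
#'   valid similarity data.
#' @slot higherShare fraction of valid anchors whose observed-group mean
#'   exceeds the baseline.
#' @slot minDegree the minimum observed-partner count an anchor needed.
#' @export
setClass("ClusterAnalysisResult",
  slots = c(side = "character", anchors = "data.frame",
            invalidShare = "numeric", higherShare = "numeric",
            minDegree = "integer"))
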