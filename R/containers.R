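# Constructors, accessors and show methods for the data containers.

#' Construct an InteractionNetwork
#'
#' @param edges a two-column data.frame (miRNA id, lncRNA id) of observed
#'   pairs, or an integer pair matrix when \code{mirnaIds}/\code{lncrnaIds}
#'   are given explicitly.
#' @param mirnaIds,lncrnaIds optional explicit id universes. Ids appearing
#'   in \code{edges} but not listed here are an error; ids listed here but
#'   absent from \code{edges} become zero-degree entities.
#' @return an [InteractionNetwork-class] object. Duplicate edges are
#'   collapsed with a warning.
#' @export
InteractionNetwork <- function(edges, mirnaIds = NULL, lncrnaIds = NULL) {
  if (is.data.frame(edges)) {
    stopifnot(ncol(edges) >= 2L)
    m <- as.character(edges[[1L]])
    l <- as.character(edges[[2L]])
    if (is.null(mirnaIds)) mirnaIds <- unique(m)
    if (is.null(lncrnaIds)) lncrnaIds <- unique(l)
    mi <- match(m, mirnaIds)
    li <- match(l, lncrnaIds)
    if (anyNA(mi) || anyNA(li))
      stop("edge refers to an id not present in the declared id universe")
    pairs <- cbind(mirna = as.integer(mi), lncrna = as.integer(li))
  } else {
    stopifnot(is.matrix(edges), !is.null(mirnaIds), !is.null(lncrnaIds))
    pairs <- cbind(mirna = as.integer(edges[, 1L]),
                   lncrna = as.integer(edges[, 2L]))
  }
  dup <- duplicated(pairs)
  if (any(dup)) {
    warning(sum(dup), " duplicate interaction pair(s) collapsed")
    pairs <- pairs[!dup, , drop = FALSE]
  }
  new("InteractionNetwork", mirnaIds = mirnaIds, lncrnaIds = lncrnaIds,
      pairs = pairs)
}

#' @rdname InteractionNetwork-class
#' @aliases mirnaIds,InteractionNetwork-method
setMethod("mirnaIds", "InteractionNetwork", function(x) x@mirnaIds)
#' @rdname InteractionNetwork-class
setMethod("lncrnaIds", "InteractionNetwork", function(x) x@lncrnaIds)
#' @rdname InteractionNetwork-class
setMethod("interactionPairs", "InteractionNetwork", function(x) x@pairs)
#' @rdname InteractionNetwork-class
setMethod("mirnaIds", "GroupBPRModel", function(x) x@mirnaIds)
#' @rdname InteractionNetwork-class
setMethod("lncrnaIds", "GroupBPRModel", function(x) x@lncrnaIds)

#' @describeIn networkDensity fraction and percent of realized pairs
setMethod("networkDensity", "InteractionNetwork", function(x) {
  f <- nrow(x@pairs) / (length(x@mirnaIds) * length(x@lncrnaIds))
  c(fraction = f, percent = 100 * f)
})

#' @describeIn averageMirnaDegree pairs per miRNA
setMethod("averageMirnaDegree", "InteractionNetwork", function(x) {
  nrow(x@pairs) / length(x@mirnaIds)
})

setMethod("show", "InteractionNetwork", function(object) {
  d <- networkDensity(object)
  cat(sprintf(
    "InteractionNetwork: %d miRNAs x %d lncRNAs, %d observed pairs (density %.2f%%)\n",
    length(object@mirnaIds), length(object@lncrnaIds), nrow(object@pairs),
    d[["percent"]]))
})

#' Construct an ExpressionProfileSet
#'
#' @param profiles numeric matrix (rows = RNAs) with rownames as RNA ids,
#'   or a data.frame whose first column holds ids.
#' @param rnaIds optional explicit ids overriding rownames.
#' @return an [ExpressionProfileSet-class]; rows containing any NA are
#'   flagged unavailable.
#' @export
ExpressionProfileSet <- function(profiles, rnaIds = NULL) {
  if (is.data.frame(profiles)) {
    rnaIds <- as.character(profiles[[1L]])
    profiles <- as.matrix(profiles[, -1L, drop = FALSE])
    storage.mode(profiles) <- "double"
  }
  if (is.null(rnaIds)) rnaIds <- rownames(profiles)
  stopifnot(!is.null(rnaIds))
  rownames(profiles) <- rnaIds
  available <- stats::complete.cases(profiles)
  new("ExpressionProfileSet", rnaIds = rnaIds, profiles = profiles,
      available = available)
}

#' @rdname ExpressionProfileSet-class
setMethod("rnaIds", "ExpressionProfileSet", function(x) x@rnaIds)
#' @rdname ExpressionProfileSet-class
setMethod("profileMatrix", "ExpressionProfileSet", function(x) x@profiles)
#' @rdname ExpressionProfileSet-class
setMethod("profileAvailable", "ExpressionProfileSet", function(x) x@available)

setMethod("show", "ExpressionProfileSet", function(object) {
  cat(sprintf(
    "ExpressionProfileSet: %d RNAs x %d attributes (%d profiles missing)\n",
    length(object@rnaIds), ncol(object@profiles), sum(!object@available)))
})

# profiles usable for correlation: available and non-constant
.usableProfiles <- function(profiles) {
  ok <- profiles@available
  if (any(ok)) {
    v <- apply(profiles@profiles[ok, , drop = FALSE], 1L, stats::var)
    ok[ok] <- v > 0
  }
  ok
}

#' Construct a TargetGeneNetwork
#'
#' @param edges two-column data.frame (RNA id, gene id).
#' @param rnaIds,geneIds optional explicit id universes (RNAs with no
#'   target genes are allowed and keep an empty neighborhood).
#' @return a [TargetGeneNetwork-class]; duplicate edges collapsed with a
#'   warning.
#' @export
TargetGeneNetwork <- function(edges, rnaIds = NULL, geneIds = NULL) {
  stopifnot(is.data.frame(edges), ncol(edges) >= 2L)
  r <- as.character(edges[[1L]])
  g <- as.character(edges[[2L]])
  if (is.null(rnaIds)) rnaIds <- unique(r)
  if (is.null(geneIds)) geneIds <- unique(g)
  ri <- match(r, rnaIds); gi <- match(g, geneIds)
  if (anyNA(ri) || anyNA(gi))
    stop("edge refers to an id not present in the declared id universe")
  e <- cbind(rna = as.integer(ri), gene = as.integer(gi))
  dup <- duplicated(e)
  if (any(dup)) {
    warning(sum(dup), " duplicate target-gene edge(s) collapsed")
    e <- e[!dup, , drop = FALSE]
  }
  new("TargetGeneNetwork", rnaIds = rnaIds, geneIds = geneIds, edges = e)
}

#' @rdname TargetGeneNetwork-class
#' @param x an object.
setMethod("rnaIds", "TargetGeneNetwork", function(x) x@rnaIds)

setMethod("show", "TargetGeneNetwork", function(object) {
  cat(sprintf("TargetGeneNetwork: %d RNAs, %d genes, %d edges\n",
              length(object@rnaIds), length(object@geneIds),
              nrow(object@edges)))
})

# RNA x gene 0/1 incidence matrix
.incidenceMatrix <- function(tg) {
  B <- matrix(0, length(tg@rnaIds), length(tg@geneIds),
              dimnames = list(tg@rnaIds, tg@geneIds))
  if (nrow(tg@edges)) B[tg@edges] <- 1
  B
}

#' Construct a SequenceSet
#'
#' Accepts a named character vector or any [Biostrings::XStringSet];
#' sequences are uppercased and U is normalized to T before validation, so
#' RNA and DNA input mix freely.
#'
#' @param sequences named character vector or XStringSet of nucleotide
#'   sequences (alphabet A, C, G, T, U, N).
#' @param rnaIds optional ids overriding the names.
#' @return a [SequenceSet-class].
#' @export
SequenceSet <- function(sequences, rnaIds = NULL) {
  s <- toupper(as.character(sequences))
  if (is.null(rnaIds)) rnaIds <- names(sequences)
  stopifnot(!is.null(rnaIds))
  s <- chartr("U", "T", s)
  bad <- grepl("[^ACGTN]", s)
  if (any(bad))
    stop("non-nucleotide characters (other than N) in sequence(s): ",
         paste(rnaIds[bad], collapse = ", "))
  dss <- Biostrings::DNAStringSet(s)
  names(dss) <- rnaIds
  new("SequenceSet", rnaIds = rnaIds, sequences = dss)
}

#' @rdname SequenceSet-class
#' @param x an object.
setMethod("rnaIds", "SequenceSet", function(x) x@rnaIds)

setMethod("show", "SequenceSet", function(object) {
  w <- Biostrings::width(object@sequences)
  cat(sprintf("SequenceSet: %d sequences, lengths %d-%d nt\n",
              length(object@rnaIds), min(w), max(w)))
})

#' Construct a SimilarityMatrix
#'
#' @param values numeric symmetric matrix.
#' @param rnaIds RNA ids (defaults to rownames of \code{values}).
#' @param valid logical mask; invalid rows/columns are zeroed.
#' @param kind "sequence", "expression" or "function".
#' @return a [SimilarityMatrix-class].
#' @export
SimilarityMatrix <- function(values, rnaIds = rownames(values),
                             valid = rep(TRUE, length(rnaIds)), kind) {
  stopifnot(!is.null(rnaIds))
  if (any(!valid)) {
    values[!valid, ] <- 0
    values[, !valid] <- 0
  }
  dimnames(values) <- list(rnaIds, rnaIds)
  new("SimilarityMatrix", rnaIds = rnaIds, values = values,
      valid = valid, kind = kind)
}

#' @rdname SimilarityMatrix-class
setMethod("rnaIds", "SimilarityMatrix", function(x) x@rnaIds)
#' @rdname SimilarityMatrix-class
setMethod("similarityValues", "SimilarityMatrix", function(x) x@values)
#' @rdname SimilarityMatrix-class
setMethod("similarityKind", "SimilarityMatrix", function(x) x@kind)
#' @rdname SimilarityMatrix-class
setMethod("validMask", "SimilarityMatrix", function(x) x@valid)

setMethod("show", "SimilarityMatrix", function(object) {
  cat(sprintf("SimilarityMatrix (%s): %d RNAs, %d invalid\n",
              object@kind, length(object@rnaIds), sum(!object@valid)))
})

#' @rdname GroupBPRModel-class
setMethod("latentFactors", "GroupBPRModel",
          function(x) list(U = x@U, V = x@V))
#' @rdname GroupBPRModel-class
setMethod("itemBias", "GroupBPRModel", function(x) x@b)
#' @rdname GroupBPRModel-class
setMethod("modelParams", "GroupBPRModel", function(x) x@params)

setMethod("show", "GroupBPRModel", function(object) {
  cat(sprintf(
    "GroupBPRModel: %d miRNAs x %d lncRNAs, d = %d, %d training epoch(s)\n",
    nrow(object@U), nrow(object@V), ncol(object@U),
    length(object@epochLoss)))
  if (length(object@epochLoss))
    cat(sprintf("  mean triple loss: %.4f (first) -> %.4f (last)\n",
                object@epochLoss[1L],
                object@epochLoss[length(object@epochLoss)]))
})

#' @rdname CVResult-class
setMethod("foldAUCs", "CVResult", function(x) x@foldAUCs)
#' @rdname CVResult-class
setMethod("meanAUC", "CVResult", function(x) x@meanAUC)
#' @rdname CVResult-class
setMethod("sdAUC", "CVResult", function(x) x@sdAUC)

setMethod("show", "CVResult", function(object) {
  cat(sprintf("CVResult [%s]: mean local AUC %.4f +/- %.4f over %d fold(s)\n",
              object@scheme, object@meanAUC, object@sdAUC,
              length(object@foldAUCs)))
})

setMethod("show", "ClusterAnalysisResult", function(object) {
  cat(sprintf(
    "ClusterAnalysisResult (%s clusters, min degree %d): %d anchors\n",
    object@side, object@minDegree, nrow(object@anchors)))
  cat(sprintf("  invalid share: %.1f%%; higher than baseline: %.1f%%\n",
              100 * object@invalidShare, 100 * object@higherShare))
})
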