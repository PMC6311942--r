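# Sequence-based RNA similarity via Needleman-Wunsch global alignment.

#' Alignment scoring parameters
#'
#' Scoring scheme for the global pairwise alignment behind the
#' sequence-based similarity: match reward 2, gap-open penalty -0.5 and
#' gap-extension penalty -0.1 by default. The mismatch penalty is not fixed
#' by that scheme and defaults to the standard nucleotide value -1. A gap of
#' length L costs |gapOpen| + L * |gapExtend|. Any base pair involving N
#' scores 0.
#'
#' @param match match score (> mismatch).
#' @param mismatch mismatch score.
#' @param gapOpen gap-opening penalty (<= 0).
#' @param gapExtend gap-extension penalty (<= 0).
#' @return a validated list of class \code{alignmentParams}.
#' @export
alignmentParams <- function(match = 2, mismatch = -1, gapOpen = -0.5,
                            gapExtend = -0.1) {
  stopifnot(gapOpen <= 0, gapExtend <= 0, match > mismatch)
  structure(list(match = match, mismatch = mismatch, gapOpen = gapOpen,
                 gapExtend = gapExtend), class = "alignmentParams")
}

# explicit substitution matrix over A,C,G,T,N; N is neutral (0)
.substitutionMatrix <- function(params) {
  letters <- c("A", "C", "G", "T", "N")
  m <- matrix(params$mismatch, 5L, 5L, dimnames = list(letters, letters))
  diag(m) <- params$match
  m["N", ] <- 0
  m[, "N"] <- 0
  m
}

#' Sequence-based similarity matrix
#'
#' Computes all pairwise global (Needleman-Wunsch) alignment scores under
#' affine-gap scoring and normalizes each raw score to [0, 1] by
#' \code{max(0, raw) / (match * min(length_i, length_j))}, so that the
#' self-similarity of any sequence is exactly 1. The diagonal is set to 1.
#'
#' @param seqs a [SequenceSet-class] with at least 2 sequences.
#' @param params an [alignmentParams()] list.
#' @return a [SimilarityMatrix-class] of kind "sequence".
#' @export
sequenceSimilarity <- function(seqs, params = alignmentParams()) {
  stopifnot(inherits(params, "alignmentParams"))
  n <- length(seqs@rnaIds)
  if (n < 2L) stop("need at least 2 sequences")
  sub <- .substitutionMatrix(params)
  dss <- seqs@sequences
  w <- Biostrings::width(dss)
  raw <- matrix(0, n, n)
  for (j in 2:n) {
    raw[seq_len(j - 1L), j] <- Biostrings::pairwiseAlignment(
      dss[seq_len(j - 1L)], dss[[j]], type = "global",
      substitutionMatrix = sub, gapOpening = abs(params$gapOpen),
      gapExtension = abs(params$gapExtend), scoreOnly = TRUE)
  }
  raw <- raw + t(raw)
  denom <- params$match * outer(w, w, pmin)
  v <- pmin(pmax(raw / denom, 0), 1)
  diag(v) <- 1
  SimilarityMatrix(v, rnaIds = seqs@rnaIds, kind = "sequence")
}
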