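# Readers and writers for the plain-text interchange formats: edge lists,
# expression matrices, FASTA sequences, similarity matrices, ranking lists.

# Split a delimited edge-list file into a 2-column character matrix.
# Delimiter (tab/comma) is auto-detected; a header row is dropped when its
# tokens reappear nowhere in the respective columns below it.
.readEdgeFile <- function(path, what = "edge") {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) stop("empty ", what, " file: ", path)
  delim <- if (any(grepl("\t", lines))) "\t" else ","
  toks <- strsplit(lines, delim, fixed = TRUE)
  nt <- lengths(toks)
  if (any(nt != 2L))
    stop(sprintf("malformed line %d in %s: expected 2 fields, got %d",
                 which(nt != 2L)[1L], path, nt[which(nt != 2L)[1L]]))
  m <- matrix(trimws(unlist(toks)), ncol = 2L, byrow = TRUE)
  if (nrow(m) > 1L &&
      !(m[1L, 1L] %in% m[-1L, 1L]) && !(m[1L, 2L] %in% m[-1L, 2L]))
    m <- m[-1L, , drop = FALSE]
  m
}

#' Read an observed miRNA-lncRNA edge list
#'
#' Two-column delimited text (miRNA id, lncRNA id); tab or comma delimited,
#' auto-detected, optional header. Ids are deduplicated preserving
#' first-seen order; duplicate edges are collapsed with a warning.
#'
#' @param path path to the edge-list file.
#' @return an [InteractionNetwork-class].
#' @export
readInteractions <- function(path) {
  m <- .readEdgeFile(path, "interaction")
  InteractionNetwork(data.frame(mirna = m[, 1L], lncrna = m[, 2L]))
}

#' Write an interaction network as a tab-delimited edge list
#'
#' @param net an [InteractionNetwork-class].
#' @param path output path.
#' @return invisibly, \code{path}.
#' @export
writeInteractions <- function(net, path) {
  p <- interactionPairs(net)
  utils::write.table(
    data.frame(mirna = mirnaIds(net)[p[, 1L]],
               lncrna = lncrnaIds(net)[p[, 2L]]),
    path, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read an RNA-to-target-gene edge list
#'
#' Same format and conventions as [readInteractions()], with columns
#' (RNA id, gene id).
#'
#' @param path path to the edge-list file.
#' @param rnaIds optional RNA id universe (RNAs absent from the file keep
#'   an empty gene neighborhood).
#' @return a [TargetGeneNetwork-class].
#' @export
readTargetGenes <- function(path, rnaIds = NULL) {
  m <- .readEdgeFile(path, "target-gene")
  TargetGeneNetwork(data.frame(rna = m[, 1L], gene = m[, 2L]),
                    rnaIds = if (is.null(rnaIds)) unique(m[, 1L]) else rnaIds)
}

#' Read an expression-profile matrix
#'
#' Delimited text; first column RNA id, remaining columns numeric
#' attributes. Empty cells mark missing values; any row containing one is
#' flagged as an unavailable profile.
#'
#' @param path path to the file.
#' @param header logical; default TRUE.
#' @return an [ExpressionProfileSet-class].
#' @export
readExpressionProfiles <- function(path, header = TRUE) {
  if (!file.exists(path)) stop("file not found: ", path)
  first <- readLines(path, n = 1L)
  delim <- if (grepl("\t", first)) "\t" else ","
  df <- utils::read.table(path, sep = delim, header = header,
                          stringsAsFactors = FALSE, check.names = FALSE,
                          na.strings = c("", "NA"))
  ExpressionProfileSet(df)
}

#' Write an expression-profile matrix
#'
#' @param profiles an [ExpressionProfileSet-class].
#' @param path output path (tab-delimited; missing profiles become empty
#'   cells).
#' @return invisibly, \code{path}.
#' @export
writeExpressionProfiles <- function(profiles, path) {
  m <- profileMatrix(profiles)
  df <- data.frame(rna_id = rnaIds(profiles), m, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "")
  invisible(path)
}

#' Read nucleotide sequences from FASTA
#'
#' @param path FASTA file path.
#' @return a [SequenceSet-class] (U normalized to T).
#' @export
readSequences <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  ss <- Biostrings::readBStringSet(path)
  SequenceSet(as.character(ss), rnaIds = sub("\\s.*$", "", names(ss)))
}

#' Write sequences as FASTA
#'
#' @param seqs a [SequenceSet-class].
#' @param path output path.
#' @return invisibly, \code{path}.
#' @export
writeSequences <- function(seqs, path) {
  Biostrings::writeXStringSet(seqs@sequences, path)
  invisible(path)
}

#' Read a similarity matrix from delimited text
#'
#' Expects an id header row and id first column, as produced by
#' [writeSimilarityMatrix()]. Rows that are entirely zero are flagged
#' invalid.
#'
#' @param path path to the file.
#' @param kind similarity kind: "sequence", "expression" or "function".
#' @return a [SimilarityMatrix-class].
#' @export
readSimilarityMatrix <- function(path, kind) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.table(path, sep = "\t", header = TRUE, row.names = 1L,
                          check.names = FALSE)
  v <- as.matrix(df)
  v <- (v + t(v)) / 2  # guard against last-digit asymmetry from printing
  SimilarityMatrix(v, rnaIds = rownames(v),
                   valid = unname(rowSums(v != 0) > 0), kind = kind)
}

#' Write a similarity matrix as delimited text
#'
#' @param sim a [SimilarityMatrix-class].
#' @param path output path (tab-delimited, id header row and column).
#' @return invisibly, \code{path}.
#' @export
writeSimilarityMatrix <- function(sim, path) {
  v <- similarityValues(sim)
  utils::write.table(
    data.frame(rna_id = rnaIds(sim), v, check.names = FALSE),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write per-query top-k ranking lists
#'
#' For each query RNA, up to k candidates sorted by descending score with
#' ties broken by candidate id (lexicographic). Output columns: query_id,
#' candidate_id, score, rank.
#'
#' @param rankings data.frame with columns \code{query}, \code{candidate},
#'   \code{score} (e.g. rbind-ed outputs of [rankCandidates()]).
#' @param k maximum candidates kept per query.
#' @param path output path (tab-delimited with header).
#' @return invisibly, the data.frame written.
#' @export
writeRankingLists <- function(rankings, k, path) {
  stopifnot(k >= 1, all(c("query", "candidate", "score") %in%
                          names(rankings)))
  if (any(!is.finite(rankings$score))) stop("scores must be finite")
  out <- do.call(rbind, lapply(split(rankings, rankings$query), function(d) {
    o <- order(-d$score, d$candidate)
    d <- d[o[seq_len(min(k, nrow(d)))], , drop = FALSE]
    d$rank <- seq_len(nrow(d))
    d
  }))
  rownames(out) <- NULL
  names(out)[1:3] <- c("query_id", "candidate_id", "score")
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(out)
}
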