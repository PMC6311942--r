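# Planted-block synthetic data generator: produces an interaction network,
# expression profiles, target-gene layers and sequences with the
# statistical structure the ranking model assumes, fully reproducible from
# a seed.

#' Configuration of the synthetic data generator
#'
#' miRNAs and lncRNAs are assigned to co-regulation blocks; an interaction
#' (i, j) is drawn with probability \code{pIn} when i and j share a block
#' and \code{pOut} otherwise. Expression profiles are block mean vectors
#' plus Gaussian noise (so same-block RNAs are positively correlated), a
#' fraction of profiles is blanked, target-gene sets are block-shared genes
#' plus random extras, and sequences carry a weak block motif embedded in
#' random background — sequence similarity is intentionally the noisiest
#' channel.
#'
#' @param nm,nl numbers of miRNAs and lncRNAs.
#' @param nBlocks number of planted blocks.
#' @param pIn,pOut within-/cross-block interaction probabilities
#'   (pIn > pOut).
#' @param exprDims named vector: attribute counts of the miRNA and lncRNA
#'   expression profiles (172 and 22 emulate tissue/cell-line panels).
#' @param exprNoise noise SD relative to the unit block-signal SD.
#' @param missingFrac named vector: fractions of miRNA/lncRNA profiles
#'   blanked.
#' @param nGenes,genesPerBlock size of the target-gene universe and of each
#'   block's shared gene pool.
#' @param seqLenRange list of length-2 ranges (nt) per class.
#' @param seed RNG seed.
#' @return a list of class \code{syntheticConfig}.
#' @export
syntheticConfig <- function(nm = 60L, nl = 100L, nBlocks = 4L,
                            pIn = 0.3, pOut = 0.02,
                            exprDims = c(mirna = 172L, lncrna = 22L),
                            exprNoise = 0.5,
                            missingFrac = c(mirna = 0.1, lncrna = 0.1),
                            nGenes = 150L, genesPerBlock = 20L,
                            seqLenRange = list(mirna = c(18L, 25L),
                                               lncrna = c(200L, 400L)),
                            seed = 7L) {
  stopifnot(nm >= 1, nl >= 1, nBlocks >= 1, pIn >= 0, pIn <= 1,
            pOut >= 0, pOut <= 1, pIn > pOut, exprNoise >= 0,
            all(missingFrac >= 0), all(missingFrac < 1),
            nGenes >= nBlocks * genesPerBlock)
  expDensity <- pIn / nBlocks + pOut * (1 - 1 / nBlocks)
  if (expDensity * nm * nl < 1)
    stop("degenerate configuration: expected number of edges below 1")
  structure(list(nm = as.integer(nm), nl = as.integer(nl),
                 nBlocks = as.integer(nBlocks), pIn = pIn, pOut = pOut,
                 exprDims = exprDims, exprNoise = exprNoise,
                 missingFrac = missingFrac, nGenes = as.integer(nGenes),
                 genesPerBlock = as.integer(genesPerBlock),
                 seqLenRange = seqLenRange, seed = as.integer(seed)),
            class = "syntheticConfig")
}

#' Generator configuration at the reference data scale
#'
#' Mirrors the shape of the curated real data the method was designed
#' around: 275 miRNAs x 780 lncRNAs at ~2.49% interaction density,
#' expression panels of 172 (miRNA) and 22 (lncRNA) attributes, and
#' missing-profile fractions of 16.4% (miRNA) and 42.3% (lncRNA). The
#' density is realized with four blocks via pOut = 0.01 and
#' pIn = 4 * (0.0249 - 0.0075) = 0.0696.
#'
#' @param seed RNG seed.
#' @return a \code{syntheticConfig} list.
#' @export
referenceScaleConfig <- function(seed = 7L) {
  nBlocks <- 4L
  pOut <- 0.01
  pIn <- nBlocks * (0.0249 - pOut * (1 - 1 / nBlocks))
  syntheticConfig(nm = 275L, nl = 780L, nBlocks = nBlocks, pIn = pIn,
                  pOut = pOut,
                  missingFrac = c(mirna = 0.164, lncrna = 0.423),
                  nGenes = 400L, genesPerBlock = 40L, seed = seed)
}

#' Generate a synthetic dataset
#'
#' @param config a [syntheticConfig()] list.
#' @return a list with elements \code{network}
#'   ([InteractionNetwork-class]), \code{mirnaExpression} /
#'   \code{lncrnaExpression} ([ExpressionProfileSet-class]),
#'   \code{mirnaTargets} / \code{lncrnaTargets}
#'   ([TargetGeneNetwork-class]), \code{mirnaSequences} /
#'   \code{lncrnaSequences} ([SequenceSet-class]) and \code{blocks}
#'   (ground-truth block labels per class). Byte-identical for identical
#'   configurations.
#' @export
generateSyntheticData <- function(config = syntheticConfig()) {
  stopifnot(inherits(config, "syntheticConfig"))
  set.seed(config$seed)
  nm <- config$nm; nl <- config$nl; nb <- config$nBlocks
  mIds <- sprintf("miR-%03d", seq_len(nm))
  lIds <- sprintf("lnc-%03d", seq_len(nl))
  mBlock <- rep_len(seq_len(nb), nm)
  lBlock <- rep_len(seq_len(nb), nl)

  same <- outer(mBlock, lBlock, "==")
  prob <- ifelse(same, config$pIn, config$pOut)
  adj <- matrix(stats::runif(nm * nl) < prob, nm, nl)
  if (!any(adj)) stop("degenerate configuration: no edges realized")
  pairs <- which(adj, arr.ind = TRUE)
  net <- InteractionNetwork(
    cbind(mirna = pairs[, 1L], lncrna = pairs[, 2L]),
    mirnaIds = mIds, lncrnaIds = lIds)

  makeExpression <- function(ids, block, N, missingFrac) {
    centers <- matrix(stats::rnorm(nb * N), nb, N)
    X <- centers[block, , drop = FALSE] +
      matrix(stats::rnorm(length(ids) * N, sd = config$exprNoise),
             length(ids), N)
    nMiss <- round(missingFrac * length(ids))
    if (nMiss > 0) X[sample.int(length(ids), nMiss), ] <- NA_real_
    colnames(X) <- sprintf("attr_%03d", seq_len(N))
    rownames(X) <- ids
    ExpressionProfileSet(X)
  }
  mExpr <- makeExpression(mIds, mBlock, config$exprDims[["mirna"]],
                          config$missingFrac[["mirna"]])
  lExpr <- makeExpression(lIds, lBlock, config$exprDims[["lncrna"]],
                          config$missingFrac[["lncrna"]])

  gIds <- sprintf("gene-%04d", seq_len(config$nGenes))
  blockGenes <- split(seq_len(nb * config$genesPerBlock),
                      rep(seq_len(nb), each = config$genesPerBlock))
  makeTargets <- function(ids, block) {
    edges <- lapply(seq_along(ids), function(r) {
      pool <- blockGenes[[block[r]]]
      own <- pool[stats::runif(length(pool)) < 0.7]
      extra <- which(stats::runif(config$nGenes) < 0.02)
      unique(c(own, extra))
    })
    df <- data.frame(
      rna = rep(ids, lengths(edges)),
      gene = gIds[unlist(edges)])
    TargetGeneNetwork(df, rnaIds = ids, geneIds = gIds)
  }
  mTargets <- makeTargets(mIds, mBlock)
  lTargets <- makeTargets(lIds, lBlock)

  motifs <- vapply(seq_len(nb), function(b)
    paste(sample(c("A", "C", "G", "T"), 8L, replace = TRUE), collapse = ""),
    character(1))
  makeSeqs <- function(ids, block, lenRange) {
    s <- vapply(seq_along(ids), function(r) {
      len <- sample(seq(lenRange[1L], lenRange[2L]), 1L)
      bg <- paste(sample(c("A", "C", "G", "T"), len, replace = TRUE),
                  collapse = "")
      if (len > 9L) {
        at <- sample.int(len - 8L, 1L)
        bg <- paste0(substr(bg, 1L, at - 1L), motifs[block[r]],
                     substr(bg, at + 8L, len))
      }
      bg
    }, character(1))
    names(s) <- ids
    SequenceSet(s)
  }
  mSeqs <- makeSeqs(mIds, mBlock, config$seqLenRange$mirna)
  lSeqs <- makeSeqs(lIds, lBlock, config$seqLenRange$lncrna)

  list(network = net, mirnaExpression = mExpr, lncrnaExpression = lExpr,
       mirnaTargets = mTargets, lncrnaTargets = lTargets,
       mirnaSequences = mSeqs, lncrnaSequences = lSeqs,
       blocks = list(mirna = mBlock, lncrna = lBlock), config = config)
}

#' Write a synthetic dataset as fixture files
#'
#' Writes the interaction edge list, expression matrices, target-gene edge
#' lists and FASTA sequence files in the package's interchange formats.
#'
#' @param data output of [generateSyntheticData()].
#' @param dir output directory (created if absent).
#' @return invisibly, a named vector of the written paths.
#' @export
writeSyntheticData <- function(data, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(
    interactions = file.path(dir, "interactions.tsv"),
    mirnaExpression = file.path(dir, "mirna_expression.tsv"),
    lncrnaExpression = file.path(dir, "lncrna_expression.tsv"),
    mirnaTargets = file.path(dir, "mirna_targets.tsv"),
    lncrnaTargets = file.path(dir, "lncrna_targets.tsv"),
    mirnaSequences = file.path(dir, "mirna_sequences.fasta"),
    lncrnaSequences = file.path(dir, "lncrna_sequences.fasta"))
  writeInteractions(data$network, paths[["interactions"]])
  writeExpressionProfiles(data$mirnaExpression, paths[["mirnaExpression"]])
  writeExpressionProfiles(data$lncrnaExpression, paths[["lncrnaExpression"]])
  tg <- function(x, path) {
    e <- x@edges
    utils::write.table(
      data.frame(rna = x@rnaIds[e[, 1L]], gene = x@geneIds[e[, 2L]]),
      path, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  }
  tg(data$mirnaTargets, paths[["mirnaTargets"]])
  tg(data$lncrnaTargets, paths[["lncrnaTargets"]])
  writeSequences(data$mirnaSequences, paths[["mirnaSequences"]])
  writeSequences(data$lncrnaSequences, paths[["lncrnaSequences"]])
  invisible(paths)
}
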