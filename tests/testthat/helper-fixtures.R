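# Small in-code fixtures shared across test files.

# deterministic toy network: 3 miRNAs x 4 lncRNAs
toyNetwork <- function() {
  InteractionNetwork(data.frame(
    mirna = c("m1", "m1", "m2", "m2", "m3"),
    lncrna = c("l1", "l2", "l1", "l3", "l4")))
}

# random bipartite network with every miRNA having >= 1 observed and
# >= 1 unobserved partner
randomNetwork <- function(nm, nl, npairs, seed) {
  set.seed(seed)
  repeat {
    p <- unique(cbind(sample.int(nm, npairs, replace = TRUE),
                      sample.int(nl, npairs, replace = TRUE)))
    deg <- tabulate(p[, 1L], nm)
    if (all(deg >= 1L & deg < nl)) break
  }
  InteractionNetwork(p, mirnaIds = sprintf("m%02d", seq_len(nm)),
                     lncrnaIds = sprintf("l%02d", seq_len(nl)))
}

# random small model for gradient / scoring tests
randomModel <- function(nm, nl, d, seed, sd = 0.5) {
  set.seed(seed)
  new("GroupBPRModel",
      U = matrix(rnorm(nm * d, sd = sd), nm, d),
      V = matrix(rnorm(nl * d, sd = sd), nl, d),
      b = rnorm(nl, sd = sd),
      params = unclass(bprParams()),
      epochLoss = numeric(0),
      mirnaIds = sprintf("m%02d", seq_len(nm)),
      lncrnaIds = sprintf("l%02d", seq_len(nl)))
}

# similarity matrix equal to the identity over given ids
identitySimilarity <- function(ids, kind = "expression") {
  SimilarityMatrix(diag(length(ids)), rnaIds = ids, kind = kind)
}
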