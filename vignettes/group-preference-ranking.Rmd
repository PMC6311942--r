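---
title: "Group-preference Bayesian ranking for miRNA-lncRNA link prediction"
author: "mirlnclink"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Group-preference Bayesian ranking for miRNA-lncRNA link prediction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mirlnclink)
```

## The problem and the model

Experimentally confirmed miRNA–lncRNA interactions form a sparse
bipartite network of *positives only*: a pair that has never been
observed is unlabelled, not negative. `mirlnclink` treats candidate
prioritisation as a semi-supervised ranking problem. Each miRNA $i$ and
lncRNA $j$ carries a latent factor ($U_i, V_j \in \mathbb{R}^d$) and each
lncRNA a popularity bias $b_j$; the individual preference is

$$\mathrm{Score}_{ij} = U_i \cdot V_j + b_j.$$

Training follows the Bayesian pairwise-ranking principle: for an anchor
miRNA $i$, an observed partner $j$ and an unobserved lncRNA $k$, the
model should satisfy $\mathrm{Score}_{ij} > \mathrm{Score}_{ik}$, with
the probability of that event approximated by the sigmoid of the margin.
The *group preference* extension exploits that the observed partners
$\mathcal{M}_j$ of a lncRNA behave like a functional cluster: a sampled
group $G \subseteq \mathcal{M}_j$ containing the anchor contributes the
mean of its members' scores, fused with the anchor's own score,

$$\mathrm{Score}_{Gij} = \rho \,\frac{1}{|G|}\sum_{t \in G}
\mathrm{Score}_{tj} + (1-\rho)\,\mathrm{Score}_{ij},$$

and one sampled triple incurs the regularised softplus loss

$$f(G,i,j,k) = \ln\!\big(1 + e^{-(\mathrm{Score}_{Gij} -
\mathrm{Score}_{ik})}\big)
+ \tfrac{\alpha_m}{2}\sum_{t\in G}\lVert U_t\rVert^2
+ \tfrac{\alpha_l}{2}\big(\lVert V_j\rVert^2 + \lVert V_k\rVert^2\big)
+ \tfrac{\beta_l}{2}\big(b_j^2 + b_k^2\big),$$

minimised by stochastic gradient descent,
$\Theta \leftarrow \Theta - \gamma\, \partial f/\partial\Theta$. The
product likelihood over all $(j, k)$ pairs is never evaluated literally;
it is optimised through uniformly sampled triples, with $k$ drawn
uniformly from the anchor's unobserved lncRNAs.

At prediction time the latent score of an unobserved pair is augmented
with similarity evidence pooled over the pair's observed neighbours
(tradeoffs $\delta_m$, $\delta_l$), and candidates are ranked *locally*,
within each miRNA's own unobserved set — the local scheme counteracts the
strong degree disproportion of the network, which would otherwise let
popular lncRNAs dominate a global ranking.

## Tunable parameters

| Parameter | Default | Meaning and rationale |
|---|---|---|
| `d` | 16 | latent dimension. The scoring function is bilinear; a rank-1 factorisation cannot express block structure, and the training cost $O(T\,n\,|G|\,d)$ is linear in `d`. 16 balances capacity against the small entity counts. |
| `rho` | 0.5 | group/individual tradeoff in $[0,1]$; 0.5 weighs both preferences equally. |
| `gamma` | 0.1 | SGD learning rate. |
| `iters` | 500 | epochs; one epoch samples as many triples as there are observed pairs, which makes the iteration count independent of network size. Longer training eventually overfits the ranking objective. |
| `alphaM`, `alphaL`, `betaL` | 0.01 | L2 weights for miRNA factors, lncRNA factors and biases. Sensible values span 0.001–0.1; 0.01 is the log-scale midpoint. |
| `deltaM`, `deltaL` | 1 | weights of the pooled miRNA-/lncRNA-similarity evidence in the final score. |
| `groupSize` | 3 | target $|G|$; groups are capped by $|\mathcal{M}_j|$ and always contain the anchor, so a partner-poor lncRNA degrades gracefully to plain pairwise ranking. |
| alignment scores | 2 / −1 / −0.5 / −0.1 | match, mismatch, gap-open, gap-extension. The mismatch value is not pinned by the scoring scheme the other three come from; −1 is the standard nucleotide choice and is exposed for sensitivity analysis. |

## Similarity measures and their conventions

**Expression.** Pearson correlation of the per-RNA attribute vectors,
computed from the explicit centred-cross-product formula (so an
off-the-shelf correlation routine stays available as an independent
check). RNAs with a missing or zero-variance profile get an all-zero row
flagged invalid rather than being dropped, keeping every matrix aligned
with the network's id universe.

**Sequence.** Global Needleman–Wunsch alignment with affine gaps via
Biostrings. The convention is that a gap of length $L$ costs
$|open| + L\,|extend|$; any base pair involving N scores 0. Raw scores
are normalised by $\max(0, raw) / (match \times \min(len_i, len_j))$ and
clipped to $[0,1]$ — this is the simplest normalisation under which
self-similarity is exactly 1 (a min–max rescaling over the matrix would
instead tie the scale to the sample of sequences at hand). Alignment
scores are stored in single precision by the backend, so agreement with
a double-precision dynamic program is expected only to about $10^{-6}$.

**Function.** Neighbour-overlap indices on the RNA–target-gene graph:
CN, Adamic–Adar, Jaccard and Salton. Adamic–Adar uses the natural log
and skips genes with RNA-degree ≤ 1: such genes carry no co-neighbour
evidence and would divide by $\log 1 = 0$. The Salton index is
implemented as the standard symmetric cosine
$|\Gamma_i \cap \Gamma_j| / \sqrt{|\Gamma_i||\Gamma_j|}$.

The default pairing — Adamic–Adar function similarity for miRNAs,
expression similarity for lncRNAs (Salton when a function-based lncRNA
similarity is requested) — is the combination that evaluates best under
cross-validation; `selectSimilarity()` exposes every alternative.

Negative expression correlations are kept in the matrices (they are
informative for the cluster analysis) but clamped to zero inside the
score aggregation, which is a nonnegative evidence-pooling step. The
aggregation divides by the full neighbour count even when some
neighbours have invalid similarity rows; invalid entries contribute 0 to
the numerator.

## Numerical and design choices

- **Initialisation.** The default draws all factor entries from
  $\mathcal{N}(0, 0.01^2)$ under the training seed. An optional mode
  initialises $U$ and $V$ from the top-$d$ eigenvectors of $S_m$ and
  $S_l$, rescaled to the same entry magnitude; the random default is
  kept because it makes reproducibility independent of the similarity
  inputs.
- **Stability.** The loss uses the $\log(1+e^{-s})$ form computed as
  `log1p(exp(-s))` for $s \ge 0$ and `-s + log1p(exp(s))` otherwise;
  scores are never clipped. Non-finite parameters abort training with
  the epoch named.
- **Update convention.** All gradients of one triple are evaluated at
  the pre-update parameters and applied together; this makes the
  trajectory well-defined and lets a singleton group reproduce a plain
  pairwise-ranking implementation bit for bit.
- **Tie-breaks.** Rankings sort by descending score, then candidate id
  (lexicographic), making outputs deterministic. AUC gives ties half
  credit (Mann–Whitney convention).
- **Degenerate inputs.** miRNAs with no unobserved lncRNA cannot anchor
  a triple and are skipped with a warning; empty groups, empty score
  lists and out-of-range indices are errors.
- **Indexing.** Internal indices are 1-based (R convention); files
  always carry ids, never indices. Id matching is case-sensitive exact
  string matching — alias resolution across source databases is a
  curation task outside the method.
- **Edge-list dialect.** Tab or comma delimiters are auto-detected; a
  header row is recognised when its tokens reappear nowhere in their
  columns. This heuristic can mis-read a file whose first edge uses two
  globally unique ids, which is why writers never emit headers.

## Cross-validation protocol

Observed pairs are partitioned uniformly at random into $k$ folds. Per
fold, the model is retrained on the remainder and each held-out pair is
ranked within its miRNA against the miRNA's never-observed lncRNAs;
other folds' held-out positives are excluded from the negative set
because they are known positives, not sampled negatives. Per-miRNA AUCs
are macro-averaged (the natural completion of a local ranking scheme;
a pooled global AUC can be obtained through a custom scorer), then
averaged over folds and repeats with an SD.

Exact leave-one-out retrains once per pair and is therefore only
accepted below a configurable pair cap (default 200); the
fold-approximate mode groups the singleton tests into a bounded number
of retrains (default 20) and labels itself as an approximation in the
result. On a small synthetic network the two agree to within a few
hundredths of AUC.

The observed-vs-unobserved cluster analysis compares, for each anchor
RNA with enough partners, the mean pairwise similarity within its
observed partner group against the unobserved group's mean (the
baseline); a difference beyond $0.3$ observed-group SDs is flagged
remarkable. Anchor degree thresholds default to 3 for miRNA clusters and
6 for lncRNA clusters (anchors interacting with more than five
lncRNAs); both are exposed because the appropriate cut depends on how
well-studied the anchors are.

## What the synthetic generator does and does not emulate

The generator plants co-regulation blocks: block membership drives the
interaction probability (`pIn` within, `pOut` across), the expression
profiles (block mean vector plus Gaussian noise, some profiles blanked),
the target-gene sets (a shared per-block gene pool plus random extras)
and a weak 8-nt sequence motif. Sequences are deliberately the noisiest
channel — sequence similarity is the weakest real-world signal of the
three. `referenceScaleConfig()` reproduces the shape of the curated
real data (275 × 780 entities, ~2.49% density, 172/22 expression
attributes, 16.4%/42.3% missing profiles); the default small
configuration (60 × 100, 4 blocks, `pIn` 0.3, `pOut` 0.02, noise SD 0.5,
10% missing) keeps test runtimes at desk scale.

Passing the planted-block benchmarks shows that the implementation
recovers the kind of low-rank, similarity-aligned structure the model
assumes, and that the whole pipeline is deterministic under a seed. It
does **not** show that real curated networks meet those assumptions:
real interaction maps have heavier-tailed degree distributions,
correlated ascertainment (well-studied RNAs accumulate both partners
and annotations) and overlapping rather than disjoint functional
modules. Published real-data AUCs depend on the exact database
snapshots and id mappings used to build the network and are not
reproducible from generated data; the workflow to attempt them on a
user-supplied snapshot is supported but nothing in the package asserts
their values.

## Problem sizes used by the tests

The test-suite and the acceptance script run entirely on generated
data: gradient checks on models up to $6 \times 8$ entities with
$d \le 4$ and groups up to 4; similarity oracles on graphs up to
20 RNAs × 30 genes and sequences up to 12 nt; AUC oracles on up to
20 + 20 scores; the structure-recovery benchmark on the default
60 × 100 network with $d = 16$ and $T = 100$ epochs, 5-fold. These
sizes make every oracle exhaustively checkable while exercising the
same code paths as a full-scale run.

## Known limitations

- Training is plain SGD in R; at the reference scale with $T = 500$ a
  full run takes minutes, not seconds. No minibatching or GPU path is
  provided.
- The sampling distribution over unobserved lncRNAs is uniform;
  popularity-aware negative sampling is out of scope.
- The group mechanism is applied on the miRNA side; the transposed
  (lncRNA-group) variant can be run by transposing the network, but no
  claim is made that it matches any published variant in detail.
- Only the softplus pairwise loss is implemented — no hinge/WARP
  variants, no implicit-feedback weighting beyond the group mechanism.
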