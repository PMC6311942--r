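# mirlnclink

Link prediction for bipartite miRNA–lncRNA interaction networks.

Long non-coding RNAs act as competing endogenous RNAs (ceRNAs): they
sponge miRNAs through shared response elements, so the miRNA–lncRNA
interaction map is a key layer of post-transcriptional regulation. The
experimentally confirmed part of that map is sparse (a few percent of all
possible pairs) and contains positives only — an unobserved pair is not a
negative. `mirlnclink` is for computational biologists who want to
prioritise candidate target lncRNAs of a miRNA (or vice versa) from such
a network, optionally fusing expression-profile, sequence and target-gene
evidence about RNA–RNA similarity.

## The model

Each miRNA *i* and lncRNA *j* carry latent factors
*U<sub>i</sub>*, *V<sub>j</sub>* ∈ ℝ<sup>d</sup> and each lncRNA a bias
*b<sub>j</sub>*; the individual preference is the bilinear score

&nbsp;&nbsp;&nbsp;&nbsp;Score<sub>ij</sub> = U<sub>i</sub> · V<sub>j</sub> + b<sub>j</sub>.

Because only positive pairs exist, training is pairwise Bayesian ranking:
an observed pair (i, j) should outscore an unobserved pair (i, k). The
group-preference twist replaces the lone anchor score by a convex fusion
with the mean score of a sampled miRNA group G ⊆ M<sub>j</sub> (the
observed partners of j, with i ∈ G):

&nbsp;&nbsp;&nbsp;&nbsp;Score<sub>Gij</sub> = ρ · |G|<sup>−1</sup> Σ<sub>t∈G</sub> Score<sub>tj</sub> + (1 − ρ) · Score<sub>ij</sub>,

and stochastic gradient descent minimises
ln(1 + e<sup>−(Score<sub>Gij</sub> − Score<sub>ik</sub>)</sup>) plus L2
regularisation over sampled triples. At prediction time the latent score
of an unobserved pair is augmented with similarity evidence pooled from
the pair's observed neighbours:

&nbsp;&nbsp;&nbsp;&nbsp;Score<sub>ij</sub> += δ<sub>m</sub>/|M<sub>j</sub>| Σ<sub>i′∈M<sub>j</sub></sub> max(0, S<sub>m</sub>(i, i′)) + δ<sub>l</sub>/|L<sub>i</sub>| Σ<sub>j′∈L<sub>i</sub></sub> max(0, S<sub>l</sub>(j, j′)).

Three similarity families are provided for S<sub>m</sub> and
S<sub>l</sub>: Pearson correlation of expression profiles,
Needleman–Wunsch global sequence alignment (normalised to [0, 1]), and
target-gene neighbourhood overlap (Common Neighbors, Adamic–Adar,
Jaccard, Salton). The defaults — function-based similarity with the
Adamic–Adar index for miRNAs, expression-based similarity for lncRNAs —
are the combination that evaluates best.

Evaluation is *local*: candidates are ranked within each miRNA's own
unobserved set, per-miRNA AUCs are macro-averaged, and leave-one-out or
k-fold protocols report mean ± SD across folds.

## Worked example

All inputs are generated by the built-in planted-block simulator, so the
example runs offline.

```r
library(mirlnclink)

data <- generateSyntheticData(syntheticConfig(seed = 7))
data$network
#> InteractionNetwork: 60 miRNAs x 100 lncRNAs, 571 observed pairs (density 9.52%)

sims <- selectSimilarity(data$network,
                         mirnaTargets     = data$mirnaTargets,
                         lncrnaExpression = data$lncrnaExpression)
sims$Sm
#> SimilarityMatrix (function): 60 RNAs, 0 invalid

fit <- trainGroupBPR(data$network, sims$Sm, sims$Sl,
                     params = bprParams(d = 16, iters = 100, seed = 7))
fit
#> GroupBPRModel: 60 miRNAs x 100 lncRNAs, d = 16, 100 training epoch(s)
#>   mean triple loss: 0.6761 (first) -> 0.1705 (last)

rankCandidates(fit, data$network, sims$Sm, sims$Sl,
               query = "miR-001", k = 5)
#>     query candidate    score rank
#> 1 miR-001   lnc-009 5.990251    1
#> 2 miR-001   lnc-065 5.898621    2
#> 3 miR-001   lnc-085 5.741015    3
#> 4 miR-001   lnc-033 5.729888    4
#> 5 miR-001   lnc-053 5.549746    5

kfoldCV(data$network, sims$Sm, sims$Sl,
        params = bprParams(d = 16, iters = 100, seed = 7),
        k = 5, seed = 7)
#> CVResult [5-fold]: mean local AUC 0.8228 +/- 0.0227 over 5 fold(s)

clusterPCCAnalysis(data$network, sims$Sl, side = "lncrna")
#> ClusterAnalysisResult (lncrna clusters, min degree 6): 55 anchors
#>   invalid share: 0.0%; higher than baseline: 98.2%
```

The ranked candidates are the unobserved lncRNAs of `miR-001` sorted by
aggregated score; the falling epoch loss shows the ranking objective
converging; the CV line is the macro-averaged local AUC (0.5 would be
random); and the cluster analysis shows that lncRNAs observed to share a
miRNA are far more co-expressed than the unobserved baseline — the
statistical signature the similarity fusion exploits.

A thin command-line wrapper over the same functions lives at
`inst/scripts/mirlnclink.R`:

```sh
Rscript inst/scripts/mirlnclink.R evaluate --out run/ --seed 5 --k 3
```

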