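# sisdta

Drug–target binding affinity (DTA) regression with **structure-inclusive
similarity (SIS)** graphs.

## The problem

Predicting how strongly a compound binds a protein (as a continuous affinity:
pKd, Ki, or a KIBA score) guides drug discovery and repurposing.
Similarity-based models rest on guilt-by-association — similar drugs bind
similar targets — and propagate information over a drug–drug similarity
graph. Conventional similarities (Tanimoto/Jaccard) are symmetric, so two
molecules always exchange information with equal weight, even when one
molecule's substructures *contain* the other's. sisdta implements an
asymmetric alternative for people building or studying graph-based DTA
models.

## The method

Each molecule is reduced to its set of circular substructure identifiers
(ECFP environments, radius 2 by default). For substructure sets r_i, r_j the
structure-inclusive similarity is the containment fraction

    SIS(i, j) = |r_i ∩ r_j| / |r_j|

— the weight with which molecule i (the *collector*) gathers information
from molecule j (the *source*). For benzene (3 substructures) and phenol
(11, a strict superset): phenol collects benzene with weight 1.0, benzene
collects phenol with weight 3/11 ≈ 0.27, while Jaccard gives 0.27 in both
directions. Thresholding the SIS matrix at δ (default 0.6; 0.7 suits
KIBA-scaled data) therefore yields a **directed** relationship graph; a
k-nearest-neighbour backfill (k = 5) guarantees every node at least k
information sources. Protein graphs are built the same way from normalized
Smith–Waterman sequence similarity and stay undirected.

Feature views (fingerprint bits and GO annotation indicators) are propagated
through two weighted graph-convolution layers

    X' = D̂^{-1/2} Â D̂^{-1/2} X Θ,      D̂_ii = Σ_j Â_ij,

fused with raw embedding views, concatenated per drug–protein pair,
compressed by an autoencoder, and regressed onto affinity under the joint
objective

    loss = (1/q) Σ_k (Y_k − Ŷ_k)² + (1/q) Σ_k (H_k^I − H_k^D)²,

where H^I / H^D are the original and decoded pair features. Evaluation uses
the standard DTA metrics: MSE, RMSE, concordance index (CI), rm² index and
Spearman correlation.

## Worked example

```r
library(sisdta)

benzene <- enumerate_substructures("c1ccccc1")
phenol  <- enumerate_substructures("Oc1ccccc1")
length(benzene$identifiers)                 # 3
length(phenol$identifiers)                  # 11
sis_weight(phenol, benzene)                 # 1.0   benzene -> phenol
round(sis_weight(benzene, phenol), 2)       # 0.27  phenol  -> benzene
round(jaccard_similarity(benzene, phenol), 2)  # 0.27 (symmetric)

d <- generate_dataset(synthetic_spec(seed = 1))   # 20 x 10 planted dataset
fit <- sisdta(d, epochs = 200, seed = 1)
fit
#> SIS-graph affinity regression model
#>   20 drugs, 10 proteins; 150 training pairs, 30 test pairs
#>   drug similarity: sis (directed graph, delta = 0.6, k = 5)
#>   final training loss 0.36845 after 200 epochs
evaluate_fit(fit, split = "test")
#>   MSE          0.186074
#>   RMSE         0.431363
#>   CI           0.937931
#>   rm2          0.896684
#>   Spearman     0.970189
#>   n_pairs            30
```

The affinities were planted as a rank-3 bilinear form plus noise (sd 0.1);
the held-out CI of 0.94 and Spearman of 0.97 say the model recovers the
planted ordering almost perfectly from the feature views and graphs. The
same pipeline is scriptable from a shell via `inst/cli/sisdta.R`
(`simulate | featurize | build-graph | train | evaluate | sweep`), e.g.

```sh
Rscript "$(Rscript -e 'cat(system.file("cli","sisdta.R",package="sisdta"))')" \
    build-graph --fixture --similarity sis --delta 0.6 --k 5 --out graph/
```

which exports the fixture molecules' directed graph — including the
weight-1.0 `benzene -> phenol` edge — as `edges.tsv`.

## Scope

The package implements the method and its desk-scale validation surface.
Benchmarking on the public Davis/KIBA datasets additionally requires
downloading those datasets and long stochastic training; the readers
(`read_dataset()` and friends) accept their standard layout (SMILES map,
sequence map, affinity matrix with missing markers, fold-index JSON), so
such runs are possible but are not part of the test surface.
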