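---
title: "Structure-inclusive similarity graphs for binding-affinity regression"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Structure-inclusive similarity graphs for binding-affinity regression}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sisdta)
```

## The model

sisdta predicts continuous drug–target binding affinities from a
drug–protein pair. Its core assumption is guilt-by-association — entities
with similar structure share interaction partners — but with an asymmetric
notion of "similar". A molecule is represented by its set of circular
substructure identifiers $r_i$; the structure-inclusive similarity

$$\mathrm{SIS}_{i,j} = \frac{|r_i \cap r_j|}{|r_j|}$$

is the fraction of the *source* molecule $j$'s substructures that the
*collector* molecule $i$ contains. When $r_j \subseteq r_i$, the collector
obtains everything the source can tell it (weight 1); in the reverse
direction the source's extra substructures are mostly noise for the
collector and the weight shrinks accordingly. For benzene (3 substructures)
and phenol (11, a strict superset) the two directions are $1.0$ and
$3/11 \approx 0.27$, where Jaccard would report $0.27$ symmetrically.

```{r}
benzene <- enumerate_substructures("c1ccccc1")
phenol <- enumerate_substructures("Oc1ccccc1")
c(benzene = length(benzene$identifiers), phenol = length(phenol$identifiers))
c(collect_benzene = sis_weight(phenol, benzene),
  collect_phenol = sis_weight(benzene, phenol))
```

Thresholding the SIS matrix at $\delta$ keeps edge $(i,j)$ — "$i$ may
collect from $j$" — only when $\mathrm{SIS}_{i,j} \ge \delta$, which makes
the drug graph *directed*: one direction of a pair can survive while the
other is discarded. Nodes orphaned by the threshold are backfilled with
their $k$ most similar sources (which keep their sub-threshold weights), the
diagonal is set to 1, and the adjacency is normalized as
$\hat D^{-1/2}\hat A\hat D^{-1/2}$ with $\hat D$ the diagonal of row sums.
Each graph-convolution layer then computes
$X' = \hat D^{-1/2}\hat A\hat D^{-1/2} X\Theta$.

Per entity type the package propagates the *structural* views through a
two-layer convolution stack (fingerprint bits over the drug graph, binary GO
annotations over the protein graph) and concatenates the *raw* embedding
views unchanged (e.g. precomputed Mol2Vec-style drug vectors of width 300
and ProtTrans-style protein vectors of width 1024, both pluggable tables).
The drug and protein embeddings of a pair are concatenated into $H^I$,
compressed by an autoencoder to a latent code that feeds a small regression
head, and trained under

$$\mathcal{L} = \frac1q\sum_k (Y_k - \hat Y_k)^2 +
  \frac1q\sum_k (H^I_k - H^D_k)^2,$$

the equally weighted sum of prediction and reconstruction error
($H^D$ is the decoded pair feature). The reconstruction residual of a vector
is reduced by the mean over components so the two terms share scale; a
`lambda` override exists but defaults to the printed 1:1 weighting.

## Substructure enumeration

Identifiers are produced by iterated neighbourhood hashing in the
Morgan/ECFP style: every atom starts from a hash of (element, heavy degree,
hydrogen count, formal charge, ring membership) and at radius $r$ rehashes
its own identifier with the sorted (bond class, neighbour identifier) pairs.
An environment is dropped when the bond set it covers was already covered by
an earlier environment (radius-0 environments, with empty bond sets, are
always kept). Two choices deserve note:

* **Radius.** The default `max_radius = 2` follows the ECFP4 convention
  (radius counts bonds; "ECFP4" names the diameter) and reproduces the
  canonical unique-environment counts — benzene 3, phenol 11, methane 1.
  Radius is a configuration knob (`radius` in `sisdta()`).
* **Aromaticity.** SMILES are parsed through openbabel, which emits
  kekulized molfiles. To keep identifier sets invariant to the arbitrary
  kekulization, all ring bonds share one bond class and atoms carry a ring
  flag rather than an aromatic flag. On aromatic systems this matches the
  usual toolkit counts exactly; on non-aromatic rings containing double
  bonds it merges slightly more environments than an aromaticity-aware
  toolkit would. SMILES rewriting invariance is locked by tests.

SIS operates on the **unfolded** identifier sets by default: folding to 1024
bits can collide identifiers and corrupt the containment semantics
(`sis_on = "bits"` enables the folded variant; on the fixture molecules the
two agree).

## Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `delta` | 0.6 | drug similarity threshold; 0.7 works better for KIBA-scaled data, so sweep over it with `threshold_sweep()` |
| `delta_protein` | `delta` | protein threshold (no separate default is established) |
| `k` | 5 | backfill floor: minimum information sources per node |
| `radius` | 2 | substructure radius (bonds) |
| `fp_length` | 1024 | folded fingerprint width (bits) |
| `gcn_dims` | 64, 32 | widths of the two convolution layers |
| `latent_dim` | 64 | autoencoder code width |
| `hidden_dim` | 32 | regression-head hidden width |
| `epochs`, `learning_rate` | 200, 1e-3 | full-batch Adam settings |
| `lambda` | 1 | reconstruction weight in the joint loss |

Network depth (two convolution layers with ReLU between them), the
optimizer (Adam, full batch) and the layer widths are this package's
defaults, chosen so the desk-scale synthetic problems train in seconds;
they are deliberately configurable because no canonical setting exists.

## Numerical and design choices

* **Orientation.** Adjacency entry $(i,j)$ is the weight $i$ collects from
  $j$; rows therefore list a node's information *sources*, the backfill
  counts in-neighbours (an orphan lacks sources, not audiences), and the
  normalization's row sums run over sources. A dedicated test asserts the
  superset drug's row carries weight 1 against its subset drug.
* **Ties.** Backfill candidates sort by descending similarity then
  ascending node index — deterministic without randomness.
* **Self-loops** are added after backfill with weight 1 (self-similarity is
  1 under every kernel here) and are excluded from the neighbour count;
  they keep $\hat D$ invertible.
* **Symmetric graphs** (proteins, or symmetric drug kernels) use the same
  machinery with backfilled edges mirrored, so the pipeline commutes with
  transposition.
* **Smith–Waterman** is normalized as
  $SW(a,b)/\sqrt{SW(a,a)\,SW(b,b)}$ with BLOSUM62, gap open 10 / extend 1;
  negative local-alignment optima are clamped to 0 (the empty alignment).
  Datasets that ship a precomputed protein similarity matrix bypass this
  entirely, and that input is preferred when present.
* **Euclidean similarity** (an ablation kernel) is $1/(1+d)$ — bounded,
  monotone in $d$, and 1 only at equality — with a Gaussian
  $\exp(-d^2/\sigma^2)$ alternative; no canonical transform exists for this
  strategy, so it is config-selectable.
* **Empty substructure sets** are a domain error in every SIS computation
  (the formula divides by $|r_j|$), never silently similarity 0.
* **CI and rm².** The concordance index is the pairwise form (ties in the
  truth excluded, prediction ties score 1/2); rm² is
  $r^2(1-\sqrt{|r^2-r_0^2|})$ with $r$ the with-intercept correlation and
  $r_0^2$ the through-origin coefficient of determination of observed on
  predicted. Both are locked by brute-force/formula oracles in the tests.
* **Affinity transforms** are the caller's responsibility: Davis-style Kd
  values are usually modelled as $pK_d = -\log_{10}(K_d/10^9)$, KIBA scores
  as shipped. The package consumes whatever scale the affinity matrix is on.
* **Training failures** abort with the epoch at which the loss became
  non-finite; histories are recorded per epoch and runs are reproducible
  from the seed.

## What the synthetic generator emulates

`generate_dataset()` produces every input the pipeline consumes: abstract
substructure sets with planted strict-containment pairs (so SIS asymmetry is
exercised: one direction exactly 1, the other below 1), random protein
sequences and GO sets, drug/protein embedding views, an affinity matrix with
missing cells, and fold assignments (1/6 held-out test, five training
folds). Affinities follow a bilinear latent model
$y_{ij} = u_i \cdot v_j + \varepsilon$ with
$u_i, v_j \in \mathbb{R}^{3}$ and $\varepsilon \sim N(0, 0.1^2)$ by
default, over 20 drugs × 10 proteins with 10% of cells masked; the embedding
views are noisy linear images of the latent factors. This induces exactly
the similar-entities-share-profiles structure the graph model assumes, and
makes the task learnable: the default configuration reaches held-out
Spearman well above 0.5 in 200 epochs.

What it does **not** emulate: real chemistry (the synthetic sets are
abstract integers; real SMILES live in the frozen `make_fixture()`
molecules), realistic affinity distributions and dynamic ranges, kinase
family structure, or dataset-scale entity counts. Passing tests on
synthetic data demonstrate that the machinery is correct and that the model
learns planted structure — not that it reproduces published benchmark
accuracy, which would require the external Davis/KIBA downloads and long
training runs.

## Problem sizes

The test and example workloads use 20 × 10 (or smaller) synthetic datasets
and 200 training epochs; a full fit takes on the order of half a minute on
one CPU in plain R. These sizes were chosen as the smallest at which the
learnability properties are stable across seeds.

## Known limitations

* The SMILES path supports the common organic subset handled by the
  openbabel round-trip and a fixed valence table; exotic valences fall back
  to zero implicit hydrogens.
* Training is dense full-batch: fine for hundreds of entities, not tuned
  for the 2000-drug scale (a sparse/minibatch engine would be the natural
  extension).
* The model is transductive — predictions exist only for entities present
  in the graphs at fit time.
* The autoencoder acts on the concatenated pair feature (one per pair); a
  per-entity variant is a plausible alternative reading of the
  architecture and is not implemented.
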