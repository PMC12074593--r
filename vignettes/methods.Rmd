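---
title: "Imbalance-aware graph networks for DNA-binding residue prediction: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Imbalance-aware graph networks for DNA-binding residue prediction: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bindgraph)
```

## The problem and the model

DNA-binding residues are rare: across the community benchmark datasets
(TR646, TR573, TE46, TE129, TE181) they make up 4–9% of residues
(`dataset_stats(benchmark_dataset_counts())`). A residue-level classifier
must therefore be built and judged with the imbalance in mind, or it
degenerates into an all-negative predictor with excellent accuracy and
zero recall.

`bindgraph` couples three ingredients:

**Residue contact graph.** One chain, one graph. Nodes are residues with
a Cα coordinate; an undirected edge joins residues whose Cα–Cα distance
is *strictly below* 8 Å (`graph_config(distance_threshold = 8)`). The
strict `<` follows the plain reading of a "less than" cutoff; at typical
backbone geometry the choice at exactly 8.0 Å affects almost no pairs,
but it is fixed and tested so results are reproducible. Sequence-adjacent
residues receive no special edge: consecutive Cα atoms sit ~3.8 Å apart
and are connected by the distance rule anyway. Residues without a Cα
cannot participate in a Cα-distance graph and are dropped (with a
warning), never imputed. Hetero residues and waters are excluded.
Alternate locations resolve to the highest-occupancy Cα.

**Per-residue features.** The model consumes an L × D feature matrix per
chain. The production surface is a protein-language-model embedding
(L × 2560, final-layer residue representations) supplied through an
adapter function; embeddings are cached on disk keyed by sequence hash
because a multi-billion-parameter forward pass is expensive. All tests
use the synthetic provider instead: rows are standard Gaussian, and rows
of binding residues are shifted by `class_shift` along a fixed unit
direction μ seeded independently of the noise. This design has a closed
form for the planted signal's difficulty — the Bayes-optimal AUC is
`pnorm(class_shift / sqrt(2))` (≈ 0.92 at the default effect size 2) —
so every downstream claim about learnability can be checked against a
known ceiling.

**SAGE + MLP node classifier with focal loss.** Each SAGE layer computes
for node *i* the neighbour aggregate `n_i` (sum of neighbour rows by
default, mean as an option; isolated nodes aggregate the zero vector),
concatenates `[h_i, n_i]`, and applies a learned affine map followed by
ReLU. The stacked layers feed a two-hidden-layer MLP (LeakyReLU, slope
0.01) with a softmax output over the two classes. Training minimises the
focal loss `-alpha * (1 - p_t)^gamma * log(p_t)` averaged over training
nodes, where `p_t` is the predicted probability of the node's true
class. At `gamma = 0, alpha = 1` this is exactly cross-entropy (a tested
identity). As printed, the weight `alpha` multiplies both classes — it
rescales the loss rather than reweighting one class; class balance is
the oversampler's job, and the focusing exponent `gamma` is what
modulates easy versus hard examples.

## Graph-aware SMOTE

`oversample()` balances the training graph by synthesising minority
nodes until the minority count reaches
`ceiling(target_ratio * majority_count)`:

1. identify the rarer class among training nodes (counted, not assumed);
2. for each source node (cycled round-robin over the minority), pick one
   of its `k_neighbors` nearest same-class training neighbours by
   Euclidean feature distance (ties break to the lower node id);
3. interpolate `x = x_src + lambda * (x_nn - x_src)`, `lambda ~ U[0, 1]`,
   so every synthetic vector lies on the segment between its endpoints
   (a tested invariant, and the reason synthetic feature distributions
   cannot wander outside the minority's convex hull);
4. wire the new node into the graph.

Edge cases are explicit: an exactly tied training set is a warned no-op;
a minority node with no same-class peer is duplicated with small
Gaussian jitter (σ = 0.01 × feature SD) because interpolation is
undefined with one sample. Every synthetic node records
`(source, neighbour, lambda)` provenance, exportable as a table, and
synthetic nodes exist only in the training mask — they can never touch
an evaluation metric.

### Wiring synthetic nodes: a design decision

How a synthetic node connects to the graph is genuinely open, and the
package separates two concerns:

*Graph structure.* Three discrete strategies are implemented:
`inherit-source` (default; connect to the source and all its
neighbours), `inherit-union` (both endpoints' neighbourhoods plus the
endpoints), and `knn-feature` (k nearest base nodes in feature space).
All guarantee at least one incident edge. No learned edge generator is
embedded: it would put a second trained model inside the oversampler.

*Message passing.* During training, the aggregation operator over an
augmented graph is direction-aware and interpolated. Base residues
aggregate only over base edges, so their layer inputs are bit-identical
with and without the synthetic nodes — whatever the network learns about
real residues transfers unchanged to evaluation graphs, where synthetic
nodes do not exist. Each synthetic node receives the convex combination
`(1 - lambda) * row(source) + lambda * row(neighbour)` of its endpoints'
aggregation rows, making it the *same* interpolation in aggregate space
as in feature space at every layer.

The reason for this construction is empirical and instructive: wiring
synthetic edges symmetrically distorts the neighbourhoods of exactly the
real minority nodes (their degree inflates with synthetic neighbours
that will be absent at prediction time), and the network exploits the
discrepancy — during development this train/test shift was strong enough
to *invert* the oversampler's benefit on held-out chains. The
interpolated operator removes the shift by construction; the discrete
edges remain the recorded graph structure and provenance.

## Training

The method statement ends at "minimise focal loss"; every optimisation
detail below is this package's own design, chosen from standard practice
for full-graph node classification and exposed in `train_config()`:

| parameter | default | role |
|---|---|---|
| `epochs` | 200 | full-graph passes |
| `learning_rate` | 0.01 | Adam step size |
| `sage_dims` | 256, 256 | SAGE layer widths |
| `mlp_dims` | 128, 64 | MLP hidden widths |
| `aggregation` | sum | neighbour aggregation (printed-formula default; `mean` available) |
| `loss` | α = 0.25, γ = 2 | focal-loss shape |
| `threshold` | 0.5 | decision rule `p ≥ threshold` |
| `dropout` | 0.2 | inverted dropout on hidden activations |
| `weight_decay` | 0 | decoupled L2 on weight matrices |
| `batch_fraction` | 0.25 | fraction of training nodes per update step |
| `val_fraction` | 0.15 | stratified validation split for checkpoint selection |

Training is full-graph: one forward/backward per step with a sparse
aggregation operator, which at these problem sizes is far cheaper than
neighbourhood-sampled minibatching. Stochasticity is reintroduced where
it matters — `batch_fraction` draws a fresh random subset of training
nodes for each step's loss, supplying the gradient noise that minibatch
training normally provides. Dropout applies to hidden activations only;
the raw input features are low-dimensional and dense, and deleting them
removes signal rather than co-adaptation. The validation split is carved
from the training nodes *before* oversampling (stratified by class), the
validation AUC is measured every `val_every` epochs with an
evaluation-mode forward pass, and the best checkpoint is returned —
plain early stopping by selection. All randomness (initialisation,
oversampling, dropout, subsampling, splits) derives from `seed`; two
runs with the same configuration are bit-identical, a tested contract.

## Evaluation conventions

* Prediction is positive when `p ≥ threshold`; the boundary counts as
  positive. A rule had to be fixed; `≥` is tested explicitly.
* Metrics with a zero denominator (e.g. precision of an all-negative
  predictor) are reported as 0 with the metric's name in an `undefined`
  flag, never as NaN — dataset-level tables stay finite and the
  degeneracy stays visible.
* AUC is the rank-based Mann–Whitney statistic with midrank ties,
  pooled over all residues of all evaluated chains (dataset-level, not
  per-chain averaged), matching how benchmark tables in this field
  report single values per dataset. The suite cross-checks it against
  both exhaustive pair counting and an independent ROC implementation.
* MCC uses double-precision arithmetic throughout; the four-way product
  of count sums overflows 32-bit integers at realistic dataset sizes.
* Node indices are 1-based internally, following R convention (residue
  numbers in files are 1-based anyway); exported edge lists are 0-based,
  the common interchange convention for graph tooling.

## What the synthetic generator emulates — and what it does not

`generate_toy_chain()` produces a self-avoiding 3-D random walk with
3.8 Å steps and a 3 Å excluded-volume rejection, giving contact-graph
degrees comparable to real backbones under the 8 Å rule. Binding labels
are placed as one or two spatially contiguous patches (real binding
interfaces are spatial neighbourhoods), at minority fractions in the
benchmark 4–9% band. Features carry the planted Gaussian signal
described above, with the signal direction shared across chains and the
noise independent per chain — geometry and feature noise use disjoint
seed streams, so the only label–feature association is the planted one.

This suffices to test every mechanism in the package: graph
construction, oversampling, learning, ranking, and the recall benefit of
rebalancing. It does not emulate real embedding geometry (anisotropic,
non-Gaussian, sequence-correlated), real binding-site chemistry, fold
topology, or dataset-level effects such as inter-protein redundancy.
Passing the mechanism study therefore demonstrates that the machinery
works and that graph-SMOTE recovers minority recall under controlled
imbalance — not that any particular benchmark AUC is attainable on real
data, which additionally requires the external datasets and the
language-model embeddings.

## The mechanism study

`run_mechanism_study()` is the package's desk-scale evaluation: 14
chains × 200 residues per replicate (2000 training, 800 held-out
residues), 5% positives, feature dimension 32, ten seeds. The network is
deliberately small for this scale — one 16-unit SAGE layer with mean
aggregation, a 16/8 MLP head, weight decay 10⁻³, 300 epochs — sized so a
full two-arm, ten-seed study with a null companion completes in a few
minutes on one CPU. Three claims are asserted: no-signal fixtures yield
chance-level held-out AUC; planted-signal fixtures yield AUC well above
0.8 (the Bayes ceiling is ≈ 0.92 on features alone, higher with
neighbour information); and oversampling raises median minority recall
over the no-oversampling baseline, paired seed-by-seed, while
specificity stays high. Mean aggregation is used here because the sum's
magnitude couples to node degree, which adds an irrelevant nuisance
dimension at this small scale; the package default remains sum, the
printed-formula form.

## Known limitations

* The focal `alpha` does not reweight classes (it follows the printed
  single-weight form); users wanting asymmetric class weights should
  combine `gamma` with oversampling, which is the package's design
  intent.
* Inference on an augmented graph is intentionally impossible in
  `evaluate()`; predict on clean graphs.
* Chains are processed independently; inter-chain contacts of
  multi-chain complexes are out of scope, as are heavy-atom or
  side-chain distance definitions.
* The language-model adapter is a contract, not a bundled model; without
  a backend it fails with instructions rather than attempting a
  download.
* Very long chains are limited by the dense L × L distance computation
  in graph construction (fine to a few thousand residues).
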