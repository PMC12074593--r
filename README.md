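# bindgraph

Predicting which residues of a DNA-binding protein actually contact DNA is
a severely imbalanced classification problem: in the community benchmark
datasets only 4–9% of residues are binding sites, so a classifier that
calls everything "non-binding" is 95% accurate and completely useless.
`bindgraph` implements a graph-neural-network pipeline for this problem
that attacks the imbalance directly, for structural bioinformaticians who
have per-residue features and predicted or experimental structures and
want residue-level binding probabilities plus honest, imbalance-aware
evaluation.

## The method

1. **Contact graph.** Each protein chain becomes a graph: residues are
   nodes, and an undirected edge joins residues *i*, *j* whenever their
   Cα–Cα distance satisfies ‖**r**ᵢ − **r**ⱼ‖ < 8 Å (strict inequality).
   Spatially close residues exchange information even when far apart in
   sequence.
2. **Node features.** Per-residue feature vectors come from a protein
   language model (an L × 2560 embedding surface, supplied through an
   adapter) or from a deterministic synthetic provider with a plantable,
   seeded class signal — the latter powers every test in this package.
3. **Graph-aware SMOTE.** Minority (binding) training nodes are
   oversampled by interpolation: a synthetic node takes features
   x = x_src + λ(x_nn − x_src), λ ~ U[0,1], between a minority node and
   one of its k nearest minority neighbours in feature space, and is
   wired into the graph rather than floating free. Oversampling repeats
   until the minority class reaches a target ratio (default 1:1).
4. **SAGE + MLP classifier.** Each layer aggregates neighbour features
   nᵢ = Σ_{j∈N(i)} hⱼ (sum by default; mean available), concatenates
   hᵢ′ = [hᵢ, nᵢ], applies a learned linear map with ReLU, then a
   two-hidden-layer LeakyReLU MLP with softmax output produces per-node
   class probabilities.
5. **Focal loss.** Training minimises L = −α(1−p_t)^γ log p_t, with p_t
   the predicted probability of the true class, down-weighting easy
   majority examples.
6. **Evaluation.** Specificity, precision, recall, F1, Matthews
   correlation coefficient from the confusion matrix at a stated
   threshold (default 0.5, `≥` rule), plus the threshold-free rank AUC
   (Mann–Whitney), pooled over all residues of all evaluated chains.

## Worked example

Everything below is synthetic and seeded — no downloads. Six toy chains
with spatially clustered binding patches (7% positives) and a planted
feature signal; four chains train the model, two are held out:

```r
library(bindgraph)

ds <- make_synthetic_dataset(n_chains = 6, chain_len = 120,
                             binding_fraction = 0.07, class_shift = 2,
                             feature_dim = 16, seed = 42)
fit <- train(ds$train,
             train_config(epochs = 150, sage_dims = 16, mlp_dims = c(16, 8),
                          aggregation = "mean", weight_decay = 1e-3,
                          seed = 1))
fit
#> <bindgraph_fit> 150 epochs, final loss 0.00049 (762 train nodes, 354 synthetic)

evaluate(fit, ds$test)
#> <metrics_report> TP=8 FP=15 TN=209 FN=8
#>   Spe=0.933 Pre=0.348 Rec=0.500 F1=0.410 MCC=0.367 AUC=0.873
```

Reading the output: of 480 training residues, 354 synthetic minority
nodes were interpolated to balance the classes. On the 240 held-out
residues the model ranks binding above non-binding residues with AUC
0.873 (the planted signal's Bayes optimum is `pnorm(2/sqrt(2))` ≈ 0.92),
recovers half of the 16 binding residues at threshold 0.5 while keeping
specificity at 0.93, and scores MCC 0.367 — far from the 0 an
all-negative predictor would earn. At a 5–9% base rate, MCC and AUC are
the numbers to watch; accuracy is not reported because it is
uninformative here.

File-level usage (PDB + label sidecar + feature TSV) goes through
`read_structure()`, `attach_labels()`, `build_contact_graph()`, or the
command line:

```sh
Rscript inst/cli/bindgraph.R make-fixtures --dir demo --n-chains 3
Rscript inst/cli/bindgraph.R stats --labels demo/chain01.labels
```

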