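# graphxgen

Synthetic node-classification graphs with known ground-truth explanations,
plus the metrics to score GNN explainers against them.

## Why

Post-hoc explainers for graph neural networks (GNNExplainer, saliency
maps, subgraph search, ...) are usually judged on datasets where nobody
actually knows the right answer. `graphxgen` takes the opposite route: it
*constructs* the label-generating process, so the correct explanation is
known by design. The package is aimed at people developing or auditing GNN
explanation methods — in cheminformatics, fraud/credit modelling, or any
domain where "why did the model predict this for this node?" has to be
answered defensibly.

## What it does

**Generator.** Graphs are built from `N_s` preferential-attachment
subgraphs, each seeded with a planted motif `S` (a five-node house or a
triangle). Subgraphs are sparsely wired so that every node `v` has between
1 and `K` motifs in its closed 1-hop neighborhood `N(v) ∪ {v}`, and the
label is

    y(v) = |{ motifs S_i : S_i ∩ (N(v) ∪ {v}) ≠ ∅ }| − 1   ∈ {0, …, K−1}.

Node features combine `n_i` informative columns (a hypercube latent
cluster model with class separation `s_f` and `c_f` clusters per class),
pure-noise columns, a binary protected attribute whose correlation with
the label is `1 − 2φ`, and a homophily pass controlled by `η` (positive =
homophilic, negative = heterophilic). For every node the package emits
binary ground-truth masks over its `L`-hop enclosing subgraph `Sub(v; L)`:
one node/edge mask per motif intersecting the subgraph (each motif is an
equally valid rationale) and a feature mask marking the informative
columns. Six presets (`SG-Base`, `SG-Heterophilic`, `SG-SmallEx`,
`SG-Unfair`, `SG-MoreInform`, `SG-LessInform`) reproduce the reference
study conditions, and a `ba_shapes()` generator covers the classic
Barabási–Albert + house benchmark.

**Metrics.** For a predicted soft mask `M^p`, binarized at top-k
(k = 25 % by default):

| metric | definition | reads |
|---|---|---|
| `gea` | max over ground truths of Jaccard `TP/(TP+FP+FN)` | accuracy, higher better |
| `gef` | `1 − exp(−KL(f(S) ‖ f(S_masked)))` | unfaithfulness, lower better |
| `ges` | max cosine distance to explanations of behavior-preserving perturbations | instability, lower better |
| `gecf` | cosine distance to the explanation of the protected-flipped counterfactual | counterfactual-fairness mismatch |
| `gegf` | `abs(SP(ŷ) − SP(ŷ_masked))`, SP = statistical parity | group-fairness mismatch |

**Harness.** A seeded, fully reproducible GIN-style message-passing
classifier (three layers, hidden 16, learnable per-layer ε, Adam 1e-2 /
weight decay 1e-5), a GCN-like variant, a uniform-random baseline
explainer and a vanilla-gradient (saliency) explainer — enough to exercise
every metric end to end with no external data or frameworks.

**IO / CLI.** Datasets serialize to a plain-text bundle (TSV edge list,
GraphML, CSV features/labels/split, JSON masks and config) that
round-trips exactly. A command-line entry point is installed at
`inst/cli/graphxgen.R`:

```sh
Rscript "$(Rscript -e 'cat(system.file("cli/graphxgen.R", package="graphxgen"))')" \
    generate --preset SG-Base --seed 0 --out sg-base/
# then: stats sg-base/ | train | explain | evaluate
```

## Worked example

```r
library(graphxgen)

cfg <- shapeggen_config(num_subgraphs = 100, seed = 7)   # small instance
ds  <- generate_dataset(cfg)
dataset_stats(ds)[c("nodes", "directed_edges", "average_degree")]
#> nodes: 1124, directed edges: 2748, average degree: 2.44

pred <- train_gnn(ds, predictor_config(epochs = 200, seed = 1))
pred
#> gnn_predictor: gin_like, 3 layers, hidden 16, 2 classes (val acc 0.946)

v  <- which(ds$split == "test" & ds$graph$labels == 1)[1]   # a class-1 node
sg <- enclosing_subgraph(ds$graph, v, cfg$gnn_layers)
sg
#> enclosing_subgraph: center 48, 3 hops, 26 nodes, 34 undirected edges

set.seed(42)
m_rand <- random_explainer(sg)
m_grad <- gradient_explainer(pred, sg)
gts    <- ds$ground_truth[[v]]

gea(gts, m_rand, "node", 0.25)   # 0.200  random mask barely hits the motif
gea(gts, m_grad, "node", 0.25)   # 0.500  saliency recovers half of it
gef(pred, sg, m_grad, "node")    # 1.000  ...yet masking to its top-25%
                                 #        completely changes the prediction
```

The three numbers tell the typical story: the gradient explainer is far
more accurate than random at locating the motif, but the masked input it
deems sufficient does not preserve this node's prediction — accuracy and
faithfulness are different questions, which is exactly why the metrics
are separate.

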