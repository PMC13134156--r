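---
title: "Local message passing, global attention, and when the difference matters"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Local message passing, global attention, and when the difference matters}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(molgps)
```

## The problem

Graph neural networks are the workhorse surrogate models for molecular and
atomistic property prediction. The mainstream architecture — the message
passing neural network (MPNN) — updates each atom's representation from its
immediate graph neighborhood, so a K-layer model is blind to anything beyond
K hops. Physically interesting properties, however, are often governed by
interactions that decay only as inverse powers of the interatomic distance
(electrostatics, induction, London dispersion with its leading $-C_6/R^6$
term) and therefore persist far beyond any bond graph or radius cutoff.
Transformer-style *global attention* gives every atom a direct view of every
other atom in one layer, at quadratic cost — but it is genuinely unclear when
that buys accuracy over a well-tuned MPNN, because published comparisons
differ in features, encodings and tuning effort.

`molgps` implements a controlled four-way comparison on a single code path.
Two switches — a global-attention engine and a feature-encoder suite — give
four model classes:

| Scheme | Attention | Encoders | Node input | Edge input |
|---|---|---|---|---|
| S1 | off | off | raw `X` | raw `E` |
| S2 | off | on | `[X‖L‖P‖C]·W` | `[E‖G]·W` |
| S3 | on | off | `[X‖L]·W` | `[E‖|L_i−L_j|]·W` |
| S4 | on | on | `[X‖L‖P‖C]·W` | `[E‖G]·W` |

All four share the same data pipeline, training loop, and hyperparameter
protocol, so differences in accuracy are attributable to architecture, the
encoders, or their combination — nothing else.

## Graphs and encoders

An atomistic graph carries atomic numbers, optional 3D coordinates (Å),
an undirected edge set, optional raw node/edge features, and targets. Edges
are built either from a supplied bond list or by a radius cutoff
$\mathcal{E} = \{(u,v) : u \neq v, \lVert r_u - r_v\rVert < r_c\}$ with a
*strict* inequality at the boundary; the default cutoff is 5.0 Å, the
conventional choice for crystal and framework data, while the synthetic
generator uses 2.0 Å to match its bond-like geometries. Internally each
undirected edge is stored as both ordered directions because messages are
direction-explicit; file writers emit each edge once. Node indices are
1-based throughout, matching R and igraph conventions.

The encoder suite precomputes, per graph:

* **CE** (chemical element descriptors, N×15): atomic weight, group, period,
  block (ordinal 0–3 for s/p/d/f — the encoding is a package choice since
  only the category matters), valence electrons, covalent and van der Waals
  radii, Pauling and Allen electronegativities, electron affinity, first
  ionization energy, melting and boiling points, density, atomic volume.
  The table is embedded as a plain CSV for Z = 1..86, compiled once from
  standard reference values; properties with no accepted value (noble-gas
  electron affinities, Allen electronegativities of heavy elements) are NA
  and propagate to the discard rule below.
* **Node TE** (N×9): degree, closeness, betweenness, eigenvector
  centrality, PageRank, local clustering coefficient, k-core number,
  harmonic centrality, eccentricity — classic measures on the unweighted
  undirected graph, computed with igraph. On disconnected graphs,
  closeness and eccentricity follow within-component conventions and
  harmonic centrality sums over reachable nodes; any remaining non-finite
  value triggers a discard.
* **Edge TE** (|E|×4): edge betweenness, Jaccard coefficient, Adamic–Adar
  score, preferential attachment.
* **LPE** (N×$d_\ell$): unit-norm eigenvectors of the combinatorial
  Laplacian $L = D - A$ for the $d_\ell$ smallest eigenvalues strictly above
  a zero tolerance of $10^{-8}$ relative to the largest eigenvalue, sorted
  ascending. Eigenvector sign is inherently arbitrary; we fix it by forcing
  the largest-magnitude entry positive (ties to the lowest index) so builds
  are deterministic, with an optional random sign-flip augmentation that
  defaults off. A graph with fewer than $d_\ell$ nontrivial eigenpairs is
  omitted, and every graph whose computed encodings contain a non-finite
  entry is discarded with a logged reason code.

All feature blocks — and regression targets — are standardized to zero mean
and unit variance. The statistics are fitted on the **training split only**
and applied unchanged to validation and test. Refitting per split would leak
target-distribution information and make splits non-comparable, so where
"per split" standardization is ambiguous we deliberately chose fit-on-train.

## Embeddings

Active channels are concatenated in the fixed order X, L, P, C and mapped by
a single bias-free linear projection to the hidden width $d_h$; edges are
likewise projected to $d_e'$. S1 performs no learned embedding at all. When
attention is on but encoders are off (S3), the edge channel is the absolute
LPE row difference $|L_{i:} - L_{j:}|$ — a cheap, sign-invariant spectral
displacement that is symmetric in the edge direction. When encoders are on,
the edge topological encodings take precedence over the LPE difference —
one relational channel per edge keeps the comparison across schemes clean. Setting
`edge_embed_dim = 0` bypasses the projection and passes raw edge features
(for geometric graphs, the interatomic distance) straight through — the
equivariance-preserving path. Single projections, not per-channel MLP
towers, keep the parameter count low and leave depth to the backbone.

## Layers

The generic MPNN layer computes per-edge messages $\phi(h_v)$ (a linear map,
optionally edge-conditioned by a learned map of the edge features),
aggregates them over each node's neighborhood by sum, mean, max, or a
softmax-normalized neighbor attention (GAT-style additive scoring), and
updates with either an MLP over `[h‖agg]` or a GRU-style gate. The
geometric layer instead embeds interatomic distances through a Gaussian
radial basis (16 centers uniform on $[0, r_c]$, width equal to the spacing)
and triplet angles through a cosine basis ($\cos n\theta$, $n = 0..7$),
sums the angular terms over each receiver's other neighbors, and feeds
$(h_u, h_v, \bar e_{uv})$ to an MLP message function. Because only
distances and angles enter, the geometric path is invariant under rigid
motions — verified in the test suite to $10^{-5}$ over random rotations and
translations.

Global attention is standard scaled dot-product multi-head attention,
restricted to each graph's own nodes by a block mask when graphs are
batched. The per-head width is $d_h / B$ with concatenation back to $d_h$:
the search space enforces `hidden_dim %% heads == 0`, which is exactly the
divided-width convention, so we adopt it (a full-width-per-head reading of
the projection shapes would make that constraint pointless) and scale
logits by $\sqrt{d_h/B}$ accordingly.

The GPS fusion layer runs the MPNN branch and the attention branch on the
same input and applies an MLP to their elementwise sum; edge state is
updated by the local branch only. The layer is implemented literally in
this additive form — no residual connections or normalization — so the
degenerate limits are exact and auditable. Zeroing the
attention value/output weights therefore reproduces the pure MPNN+MLP
composition bit-for-bit, which the tests assert.

## Multitask heads, losses, metrics

A shared trunk feeds one two-layer decoder head per task (hard parameter
sharing); graph-level heads read a permutation-invariant pooling (mean by
default; min/max/sum available), node-level heads read node states
directly. Losses are mean squared error for regression, softmax
cross-entropy for multi-class, and per-label binary cross-entropy with
missing-label masking for multi-label targets; the global objective is the
weighted sum of task losses with default weight 1 per task — the neutral
choice absent a reason to prefer any task.
Metrics are MSE/MAE/Pearson r, top-1 accuracy, and mean average precision
with missing labels excluded per label.

## Training and hyperparameter search

Training uses Adam on full passes over fixed-size graph batches (32 graphs
by default), with early stopping after `patience` epochs without
validation improvement and a checkpoint written every epoch; the best
epoch's checkpoint is flagged and reloadable bit-exactly. The search space
is conditional on three flags — coordinate availability, the attention
switch, and the encoder switch: 1–6 conv layers (1–3 with attention),
hidden widths 4–32 / 16–64 without attention and {8,16,...,48} /
{16,24,...,64} with it (all multiples of 8, so every width is compatible
with 2, 4 or 8 heads), edge embed widths {0, 4..12}, and learning rates
{1e-2, 3e-3, 1e-3, 3e-4} (a package default spanning the useful Adam range). The backbone menu is conditioned on coordinates:
geometric message passing plus the generic aggregators with 3D, the
non-geometric subset without. `molgps` uses uniform random search over the
space — dependency-free and unbiased — with the standard protocol: sample,
train for T epochs, select $h^* = \arg\min$ validation loss, then retrain
the winner with a larger budget $T' > T$. Ties go to the earliest trial,
and the final test metrics are computed once, on the held-out split only.

## The synthetic generator and what it does (and does not) show

The generator emulates small organic molecules: 10–30 atoms from
{H, C, N, O}, grown by sequential attachment at bond-like distances
(1.2–1.8 Å) under a global 1.0 Å minimum separation, with radius-cutoff
edges at 2.0 Å (so the attachment structure is connected) or an explicit
bond graph with degree capped at 4. Optional schemas attach OGB-style
9-channel integer atom features or PPA-style 7-channel binary edge
evidence vectors. Target families span the locality spectrum:

* `local`: $\sum_u \mathrm{covrad}(Z_u)\cdot \overline{r}_{u\mathcal{N}(u)}$
  — 1-hop computable by construction;
* `dispersion` / `dispersion_beyond`: $\sum_{u<v} -C_6(Z_u,Z_v)/r_{uv}^6$
  over all pairs, or only pairs at $r \ge r_c$ — the latter is *invisible*
  to one-hop models and is the long-range stressor. Pair coefficients are
  geometric means of free-atom values with realistic relative magnitudes;
  only the ratios matter for learning, and no quantum-chemical accuracy is
  claimed;
* `node_charge`: per-atom electronegativity imbalance (partial-charge-like,
  node-level);
* `motif_class` and `multilabel`: banded triangle counts and threshold
  indicators on graph statistics, for the classification paths.

Gaussian noise of configurable sd can be added to regression targets;
targets are standardized with the same train-fitted machinery as the
features.

What passing the desk-scale comparison shows: that with identical
pipelines, a one-layer globally-attending model recovers signal a one-layer
local model provably cannot see, and that on a strictly local target the
encoder-augmented MPNN is not handicapped. What it does not show: anything
about data at real benchmark scale, chemical diversity beyond four
elements, conformational realism, or the behavior of specific literature
backbones (PNA, PAINN, DimeNet, ...) that the generic aggregators here
stand in for.

## Numerical choices and degenerate inputs

* Weight initialization: uniform scaled by the inverse square root of the
  fan-in, fully seeded.
* Zero-eigenvalue tolerance for the Laplacian: $10^{-8}$ relative.
* Constant feature columns standardize to zero and are flagged.
* Isolated nodes receive a zero message aggregate and pass through the
  update function; empty graphs cannot be pooled (error).
* Coincident atoms on an edge (zero distance) invalidate a graph.
* Ties in the attention softmax and in pooling argmax resolve
  deterministically (first index), so runs are bit-reproducible per seed.
* The dataset container stores numbers at full precision; round-trips are
  bit-exact for finite values.

## Study problem sizes

The packaged comparison (also recomputed by `scripts/acceptance.R`) uses
250 generated graphs of 15–25 atoms (about 20 on average) with an
80/10/10 split — 200 training graphs — one-layer models at matched
parameter budgets (the S1 width is chosen so its count is within ±10% of
the attention models'), batch size 32. The long-range part trains three
seeds with a 120-epoch budget and patience 20 (its margins are large and
insensitive to the budget); the local-parity part trains two seeds with a
250-epoch budget and patience 40, because comparing near-floor MAEs is
only meaningful between converged models, and reports the ratio of
seed-mean family-best validation MAEs. These sizes keep the full
comparison in the ten-minute range on a laptop core while leaving the
qualitative contrast unambiguous; the overfit sanity check uses 32 graphs
and a 400-epoch budget.

## Known limitations

* Dense attention and dense eigendecomposition limit practical graph sizes
  to a few hundred atoms — adequate for the scope here, not for proteins.
* The AD engine supports exactly the operations the architectures need; it
  is not a general-purpose framework.
* Random search explores the space uniformly; no early-termination or
  model-based acceleration.
* Periodic boundary conditions, bond-order perception, and
  force/uncertainty prediction are out of scope.
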