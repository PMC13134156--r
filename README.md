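# molgps

**When does global attention help?** A controlled framework for molecular
property prediction that switches between four graph-learning model classes
on one code path:

* **S1** — a plain message passing neural network (MPNN) on raw atom/bond
  features;
* **S2** — MPNN + a precomputed encoder suite (chemical element descriptors,
  node/edge topological encodings, Laplacian positional encodings);
* **S3** — GPS-style hybrid layers that fuse local message passing with
  multi-head global self-attention, positions supplied by Laplacian
  eigenvectors;
* **S4** — the fully fused model: encoders *and* global attention.

An MPNN layer updates node states from their graph neighborhood,

```
H̄ = ⊕(φ(H), ℰ, E),   H' = Ψ(H̄, H),
```

so a K-layer stack cannot see past K hops. Physical long-range interactions
(the London dispersion term −C₆/R⁶ being the canonical example) violate
exactly that locality. The GPS layer adds a global branch,

```
X̂_M, E' = GNN(X, E, ℰ),   X̂_T = MHA(X),   X' = MLP(X̂_M + X̂_T),
```

giving every atom a one-layer view of the whole graph. `molgps` makes the
comparison fair: identical data pipeline, embeddings, multitask heads,
training loop, and a conditional random hyperparameter search whose grids
are shared by all schemes. A built-in synthetic molecule generator provides
targets with controlled locality — from strictly 1-hop-computable sums to a
beyond-cutoff dispersion sum that no one-layer local model can represent —
so the central question is testable offline on a laptop core.

The package is written for method researchers and tool builders in
cheminformatics who want to attribute accuracy gains to architecture,
feature encoders, or their combination, without confounds. All learnable
modules run on a compact tape-based reverse-mode autodiff engine included
in the package (gradients are verified against finite differences in the
test suite); graph measures use igraph; no deep-learning framework is
required.

## Worked example

Generate a long-range dataset, train a one-layer fused model, and compare
it with a parameter-matched plain MPNN:

```r
library(molgps)

spec   <- gen_spec(n_graphs = 250, atoms_range = c(15, 25),
                   target = "dispersion_beyond", seed = 11)
graphs <- gen_dataset(spec)
tasks  <- list(task_spec("dispersion_beyond"))
prep   <- prepare_dataset(graphs, tasks, d_l = 2, r_c = 2.0, seed = 1)

cfg_s4 <- model_config(scheme = "S4", mpnn_type = "edgecond-sum",
                       num_conv_layers = 1, hidden_dim = 8,
                       edge_embed_dim = 4, global_attn_heads = 2,
                       has_pos = TRUE, lpe_dim = 2, r_c = 2.0, lr = 3e-3)
set.seed(1)
model <- assemble(cfg_s4, prep$meta)
rec   <- train_model(model, prep, epochs = 150, patience = 25, seed = 1)
evaluate_model(model, rec$params, prep, "val")$dispersion_beyond
#>       mse       mae pearson_r
#> 0.2399555 0.4142382 0.9225293
```

Validation MAE is on the standardized target scale (the pipeline
standardizes regression targets with train-fitted statistics). Under the
same protocol a parameter-matched one-layer S1 model reaches an MAE of
about 0.96 — essentially the predict-the-mean floor — because the
beyond-cutoff pairs that define this target are invisible to a single hop
of message passing, while the attention branch recovers most of the
signal (Pearson r ≈ 0.92 here). On the strictly local target family the
ordering flattens: encoder-augmented message passing is competitive with
the fused models.

Hyperparameter search over the conditional space, then an extended retrain
of the winner:

```r
hpo  <- run_hpo(prep, has_pos = TRUE, global_attn_engine = TRUE,
                use_encodings = TRUE, n_trials = 5, epochs = 30, seed = 1)
best <- retrain(hpo$best$config, prep, epochs = 200, patience = 30, seed = 1)
best$test_metrics
```

A thin command-line wrapper ships in `inst/cli/molgps.R` with subcommands
`convert`, `generate`, `encode`, `train`, `hpo`, and `evaluate`; every run
writes a JSON manifest (config, seeds, data hash, split sizes, metrics)
sufficient to re-execute it.

## Scope

Small to medium atomistic graphs (tens to a few hundred nodes): dense
attention and dense eigendecomposition are deliberate simplicity choices.
Periodic crystals, bond perception from geometry, forces, and
uncertainty are out of scope.
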