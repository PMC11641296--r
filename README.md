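# hydrographer

Protein–ligand binding affinity regression that takes interfacial **water
networks** seriously. For computational chemists and method developers who
want a self-contained, inspectable implementation of a water-aware
graph-transformer scoring pipeline — from structure files to pK_d — that
runs and tests at desk scale without external data downloads.

## What it computes

A complex is represented as attributed graphs: **G_A** (pocket protein +
ligand heavy atoms), and **G_B** / **G_C** which add water oxygens from two
hydration-site sources (a knowledge-based grid + mean-shift pipeline, and a
solvent-density-grid peak extractor). Nodes carry a fixed 58-dimensional
feature vector (residue one-hot, 22-type ECIF-style protein atom types,
ligand element one-hot, geometry and chemistry slots); edges carry
distances typed by pair (LL, PL, PP, WL, WP, WW) under a 6 Å base cutoff
and a configurable water threshold `T`, with strict `<` comparisons.

The regressor is a graph transformer: multi-head attention whose logits are
biased by structure,

    A_h = softmax( Q K' / sqrt(d_h) + b_spd(i,j) + c_h(i,j) ),

with `b_spd` a learned scalar per shortest-path-hop bucket (spatial
encoding), `c_h` an edge-feature term averaged along one canonical shortest
path (edge encoding), and degree-embedding centrality added at the input.
Each graph is read out through a virtual node; the two branch embeddings
are concatenated and passed through a softmax-gated linear head to a single
pK_d. Forward, backprop and Adam are implemented in base R (no deep-learning
framework is required) and are verified against finite differences in the
test suite.

Evaluation uses the scoring-power metrics R_p (Pearson correlation) and
RMSE, plus ΔG = RT ln K_d conversion. An ablation harness trains matched
models in `full`, `no_water`, `hydramap_only` and `rism_only` modes. A
synthetic-complex generator plants a known affinity law (pK_d = β +
α·n_bridge_waters + noise) so the whole pipeline is testable end to end.

## Worked example

```r
library(hydrographer)

# a small synthetic dataset with a planted water-bridge signal
ds  <- make_dataset(100, seed = 7, noise_sd = 0.3, alpha = 1, beta = 5)
pks <- lapply(ds, extract_pocket, cutoff = 10)

cfg <- model_config(layers = 2, heads = 4, hidden_dim = 32,
                    epochs = 40, lr = 2e-3, seed = 1)
tab <- run_ablation(pks, modes = c("full", "no_water"), config = cfg)
print(tab, digits = 3)
```

```
      mode   r_p rmse n_train n_test
1     full 0.972 0.47      80     20
2 no_water 0.361 2.02      80     20
```

With water networks in the graphs the model recovers the planted
bridge-count signal (held-out R_p ≈ 0.97, RMSE ≈ 0.5 against a 0.3 noise
floor); with water-blind G_A graphs the same architecture cannot see the
bridge count and its held-out correlation collapses — the water nodes *are*
the signal, by construction. This run takes a couple of minutes on one CPU.

Hydration sites from a synthetic solvent-density grid:

```r
grid  <- make_density_grid(rbind(c(0,0,0), c(5,1,0)), spacing = 0.5)
sites_from_density(grid, threshold = 2)
```

```
  x y z score provenance
1 0 0 0     1       rism
2 5 1 0     1       rism
```

## Layout

* `R/structures_io.R` — PDB/Mol2/SDF parsing, residue templates, pocket
  extraction
* `R/hydration.R` — grid + mean-shift and density-peak site pipelines,
  OpenDX I/O, site matching
* `R/featurize.R` — ECIF-style typing, 58-slot node features, edge features
* `R/graph.R` — G_A/G_B/G_C assembly, stats, JSON-lines serialization
* `R/model.R` — graph transformer, manual backprop, Adam, checkpoints
* `R/train_eval.R` — metrics, splits, index I/O, ablation harness
* `R/fixtures.R` — synthetic complexes, datasets, density grids
* `inst/cli/hydrographer.R` — `hydrate` / `featurize` / `train` /
  `predict` / `evaluate` subcommands
* `vignettes/water-network-affinity.Rmd` — the methods vignette (model,
  assumptions, parameter choices, limitations)
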