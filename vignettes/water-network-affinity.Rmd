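---
title: "Water-network graphs and biased graph-transformer regression of binding affinity"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Water-network graphs and biased graph-transformer regression of binding affinity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The problem

Interfacial water molecules mediate protein–ligand recognition: a water that
simultaneously hydrogen-bonds to a protein residue and a ligand heteroatom
("water-mediated bridge") can stabilize a complex that direct contacts alone
would not, and displacement of ordered water contributes entropically to the
binding free energy ΔG = RT ln K_d. Scoring functions that see only protein
and ligand atoms are blind to this contribution. `hydrographer` represents a
complex *plus its predicted interfacial water network* as attributed graphs
and regresses pK_d = −log10 K_d with a graph transformer whose attention is
structurally biased.

## Graph representation

Three graph variants share one node scheme — every heavy atom of the binding
pocket (protein and ligand), plus water oxygens:

* **G_A** — protein + ligand only;
* **G_B** — G_A plus water sites from the knowledge-based grid pipeline;
* **G_C** — G_A plus water sites from a solvent-density grid.

Node features occupy a fixed 58-slot vector: a 20-way residue one-hot, a
22-way protein atom-type one-hot (ECIF-style strings
`Element,ExplicitValence,HeavyNeighbors,AttachedH,Aromatic,Ring`), a 9-way
ligand element one-hot (C, N, O, S, F, Cl, Br, I, P), one geometric slot,
implicit valence, two 2-way one-hots (aromatic, ring) and the attached
hydrogen count. Water oxygens use the element block's O channel with fixed
chemistry (valence 2, two hydrogens, acyclic).

Edges carry the Euclidean distance and a pair-type tag. Protein–ligand and
protein–protein distance edges attach at the Cα level, ligand edges at the
heavy-atom level, water edges at the oxygen; all comparisons are strict
(`<`). The base cutoff is 6 Å; the water threshold `T` is configurable
(4/6/8 Å, default 6, the published optimum). Ligand covalent bonds are kept
as edges regardless of length. Consecutive-residue Cα–Cα backbone edges and
residue-internal atom→own-Cα edges keep the protein subgraph connected.
Isolated waters are removed.

### Design choices the sources left open

* **The single "coordinates" feature slot.** The published 58-slot total
  admits only one geometric dimension although raw coordinates are three
  numbers. We store the distance from the atom to the pocket centroid:
  dimension-preserving and invariant under rigid motion, which raw
  coordinates are not. Raw coordinates stay on the atom records for all
  distance computations.
* **Node vs edge levels.** "Each atom is a node" and "protein edges live at
  the Cα level" are both honoured: all pocket atoms are nodes, but
  inter-molecular distance edges attach at the published representative
  levels. A `protein_level = "heavy"` mode connects all protein heavy atoms
  instead.
* **Water node features** are not specified by the sources; the minimal
  dimension-preserving encoding above was chosen, with pair-typed edges
  carrying the distinction.

## Hydration-site prediction

Two complementary routes mirror the two published water sources:

1. **Grid + mean shift** (knowledge-based): an axis-aligned box around the
   ligand expanded by margin D = 4 Å is voxelized (default spacing 1 Å — the
   sources do not state it); a water probe is scored at every voxel center;
   voxels within 2 Å of a solute heavy atom get a steric-clash sentinel;
   voxels with score ≥ 5 (the published cutoff) enter flat-kernel mean-shift
   clustering with bandwidth 2 Å (the published radius), convergence 1e-4 Å
   or 200 iterations; clusters with fewer than N = 1 member voxels are
   dropped. The published parameter table lists N with a length unit — we
   read it as a count. The *probe potential itself is pluggable*: the
   original statistical potential is proprietary to external software, so
   the default is a documented surrogate: a sum of Gaussian attractions
   centered on polar protein atoms (N/O/S), with amplitude 15 and width
   1.5 Å so that a single hydrogen-bond partner scores above the favourable
   cutoff of 5 throughout its first hydration shell (2.0–2.6 Å). The
   pipeline — box, grid, threshold, cluster — is the described computation;
   the surrogate cannot reproduce the external tool's site positions on
   real proteins and does not try to.
2. **Density peaks** (solvent-distribution): 26-neighbourhood local maxima
   of a 3D density grid (parsed from OpenDX text, or synthesized) at ≥ 2×
   the grid mean, with maxima closer than 2 Å merged keeping the higher
   peak. The integral-equation solver that produces such grids is not
   reimplemented.

Both site lists pass a contact filter (≥ 1 solute heavy atom within 4 Å, the
published contact distance). Provenances are kept separate because G_B and
G_C consume different sources. Predicted-vs-reference site agreement uses
greedy globally-nearest-first one-to-one matching under a 2 Å tolerance;
greedy matching can differ from the optimal assignment in adversarial
configurations, which the tests avoid by construction.

## The model

Per graph, node features are projected to d dimensions and a learned
per-degree embedding (degrees clamped at 32) is added — the centrality
encoding. A virtual readout node with a learned input embedding is
prepended. Each of L transformer layers applies pre-norm multi-head
attention and a 2× feed-forward block with residual connections. The
attention logits of head h between nodes i and j are

    (q_i · k_j) / sqrt(d_h)  +  b_spd(i,j)  +  c_h(i,j)

where `b_spd` is a learned scalar per shortest-path-hop bucket (hops clamped
at 20; reserved buckets for unreachable pairs and virtual-node pairs) — the
spatial encoding — and `c_h` is the edge-path term: the average over the
edges of one recorded shortest path of ⟨edge feature, learned per-position
weight⟩. Edge features are the distance plus a 6-way pair-type one-hot.

Numerical and structural choices:

* **Per-head scaling.** The published attention formula divides by sqrt(d);
  we use sqrt(d_head) per head, the convention of the cited graph
  transformer.
* **Edge-term normalization.** The published formula divides the path sum by
  the graph's total edge count N; the cited graph transformer averages over
  the path. The per-path average is the default; the literal 1/N variant is
  available via `edge_bias_literal_n = TRUE`.
* **Canonical paths.** Among equal-hop shortest paths, the one with the
  smallest total geometric length is recorded (weights 1 + 1e-3·distance),
  and per-position weights are symmetrized over the two path directions, so
  predictions are invariant under node reindexing. Exact geometric ties
  would fall back to index order; generic coordinates never tie.
* **"Softmax regression".** The sources state that concatenated graph
  embeddings are fed "into the Softmax function for regression", which is
  not a standard construction for a continuous output. We read it as
  softmax gating: with z the concatenated pair of virtual-node embeddings,
  the prediction is w · (softmax(z) ⊙ z) + b. This is the only reading we
  found that yields a continuous scalar while using a softmax at the head.
* **Branch weights.** Whether the two graph branches share weights is
  unstated; default shared (halving parameters), `shared_weights = FALSE`
  separates them.
* **Width.** The published head count is 12 and our width must be divisible
  by the head count, so the default hidden dimension is 60 (not 64).

Training minimizes MSE on pK_d with Adam (default lr 1e-4, batch 8),
gradient-norm clipping at 5, and a single seed controlling initialization
and shuffling; dropout defaults to 0, making runs bit-reproducible. No
autodiff framework is available in this environment, so forward and
backward passes are hand-derived; the test suite checks every parameter
block against central finite differences (relative error < 1e-4 on sampled
coordinates).

Published settings adopted as defaults: edge threshold 6 Å, 12 heads, 4
layers. The optimizer, learning rate, epochs and validation protocol are
not published; package defaults are ours and are not claimed as the
sources'. Desk-scale runs in the tests use a 2-layer, 4-head, width-32
model with lr 2e-3 for a 30-epoch budget.

## The synthetic world

The generator emits well-formed toy complexes, not physical ones:

* a helix-like chain (Cα trace with 2.3 Å radius, 1.5 Å rise, 100°/residue;
  template residues SER/ALA/THR/VAL/GLY/CYS with backbone, Cβ and polar
  tips at idealized local offsets);
* a branched C/N/O ligand (1.5 Å bonds) placed beside the helix;
* per-complex coordinate jitter (σ = 0.15 Å) so no two complexes share a
  geometry — without it all water-free graphs would be identical and a
  water-blind baseline would predict a constant;
* **bridge waters** at jittered midpoints of (protein polar atom, ligand
  atom) pairs 3–6.4 Å apart, hence < 3.5 Å from both partners — inside
  hydrogen-bond range and inside the 4 Å contact filter;
* **decoy waters** > 8 Å from the ligand and > 4 Å from the protein, which
  the contact filter removes and which never gain graph edges at T ≤ 8;
* a planted label law pK_d = β + α·n_bridges + N(0, σ_noise), defaults
  β = 5, α = 1 pK_d per bridge, σ_noise = 0.3 — so the *only* signal beyond
  noise is the water-bridge count, by construction.

Each bridge water is emitted as both a grid-pipeline site and a
density-grid site (0.15 Å apart — two predictors agreeing), decoys
alternate provenance; this emulates the complementary published sources and
keeps the planted signal visible in both water-bearing graphs.

What a green test therefore establishes: the pipeline can carry a
water-borne signal from files through graphs into an accurate regression,
and removing the water nodes removes the signal. What it does **not**
establish: performance on real complexes, where geometry, chemistry and the
affinity-structure relationship are vastly richer, and where the real
hydration predictors (not our surrogate) supply the sites.

## Known limitations

* Protein chemical context comes from residue templates at fixed
  protonation; no perception from geometry, no non-standard residues beyond
  an element-default fallback with a warning.
* Bond perception from distances is deliberately unsupported (ligand files
  must carry bond blocks).
* The surrogate probe potential is a stand-in; hydration-site positions on
  real proteins require external predictors, whose grids/sites this package
  reads.
* The hand-rolled training loop is CPU-bound R; it is sized for hundreds of
  pocket-scale graphs, not for full benchmark-scale training.
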