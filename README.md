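# molembed

Joint molecule–text representation learning at desk scale, for
cheminformaticians and method developers who want a fully inspectable,
CPU-sized implementation of a multimodal molecular embedding pipeline:
a graph Transformer molecule encoder whose attention is biased by combined
2D/3D structural encodings, a text Transformer encoder, contrastive
pretraining over RMSD-gated molecular augmentations, and downstream harnesses
for cross-modal retrieval, property prediction and text-prompted molecule
editing.

## The model

**Structural attention bias.** For a heavy-atom molecular graph with `a`
atoms, three pairwise encodings are combined into a bias matrix
φ ∈ ℝ^{a×a} added to every attention head's logits before the softmax:

- *edge encoding* φᵢⱼᴱᵈᵍᵉ = avg(e)·w — the element-wise average of the bond
  feature vectors e₁, e₂, … along the canonical shortest path between atoms
  i and j, dotted with a learnable weight vector w ∈ ℝ^{k_edge}
  (k_edge = 6: one-hot bond order, ring and conjugation flags);
- *shortest-path encoding* φᵢⱼˢᴾᴰ = spd(i, j)·w — the bond-count shortest
  path distance scaled by a learnable scalar (unreachable pairs carry the
  sentinel value `a`);
- *3D distance encoding* φᵢⱼ³ᴰ = ReLU(ψ(i, j)·W₁)·w₂ with
  ψₖ(i, j) = exp(−‖xᵢ − xⱼ‖/σₖ), a bank of K Gaussian-basis kernels of the
  Euclidean interatomic distance (decay form as the default; a standard
  Gaussian bump form is available), read out through a small learnable MLP.

Attention is then `softmax(QKᵀ/√d + φ)·V`. In `"2D"` mode the 3D term is
omitted. 3D coordinates come from seeded distance-geometry embedding plus
MMFF94 minimization (RDKit, behind a persistent worker process).

**Contrastive pretraining.** Each molecule contributes four augmented views
(never the original): node dropping (⌈0.1·a⌉ atoms), random-walk subgraph
sampling, functional-group transformation, and BRICS substructure removal.
A candidate view is accepted only if its maximum-common-substructure-mapped,
Kabsch-aligned RMSD to the original is below 3.0 Å. With zᵢᴳ¹…zᵢᴳ⁴ the view
embeddings and zᵢᵀ¹…zᵢᵀ³ the caption embeddings of molecule i in a batch of
N, the objective is L = L_cross + L_self, where L_cross is the
temperature-scaled InfoNCE between matched graph views and texts (softmax
over the batch's texts, averaged over all view × variant combinations), and
L_self contrasts the pair-kernel Σ exp(sim(zᵢᴳᵃ, zᵢᴳᵇ)/τ) over an item's own
view pairs against the same kernel evaluated across the batch. Both use
cosine similarity of L2-normalized embeddings and τ = 0.1.

**Downstream harnesses.** Retrieval ranks the opposite modality by cosine
similarity in seeded batches (top-1 accuracy and R@20); property prediction
attaches a ridge-logistic head to the 768-dim molecule embedding (held-out
AUROC); editing optimizes a latent of an invertible generator for 600
gradient steps against `(1 − cos(c, z_mol)) + λ(1 − cos(c, z_text))`,
decodes it, and judges hits by strict descriptor rules (TPSA, Lipinski HBA
and HBD, QED, Wildman–Crippen logP) with mean Tanimoto similarity reported
alongside.

## Worked example

```r
library(molembed)

g <- generate_conformer(parse_smiles("CC(=O)Oc1ccccc1C(=O)O"), seed = 1)
g
#> <mol_graph> 13 atoms, 13 bonds, 3D coords  CC(=O)Oc1ccccc1C(=O)O
property_panel(g)
#> TPSA 63.60 A^2 | HBA 4 | HBD 1 | QED 0.562 | WCLogP 1.31

build_augmentation_set(g, seed = 11)
#> <augmentation_set>
#>   G1 node_drop            rmsd 0.033 accepted
#>   G2 subgraph             rmsd 1.104 accepted
#>   G3 chem_transform       rmsd 0.031 accepted
#>   G4 substructure_removal rmsd 0.043 accepted

cfg <- encoder_config()           # 2 layers, 4 heads, width 64, embed 768
corpus <- make_toy_corpus(48, seed = 1)
fit <- pretrain(corpus$pairs[1:32], weights = init_weights(cfg, seed = 1),
                config = cfg, epochs = 30, batch_size = 8, seed = 1)
fit
#> <molembed_fit> 32 molecule-text pairs, 30 epochs (batch 8, lr 0.02, 3D bias)
#>   loss: 4.0361 (epoch 1) -> 3.1538 (epoch 30)

held <- corpus$pairs[33:48]
e <- predict(fit, graphs = lapply(held, `[[`, "graph"),
             texts = vapply(held, function(p) p$captions[1], ""))
retrieval_eval(e$molecules, e$texts, batch_size = 8, n_batches = 30, seed = 1)
#> retrieval M-T: top-1 0.0708, R@20 1.0000 (30 batches of 8)
```

Reading the numbers: the four augmentations of aspirin all passed the 3.0 Å
RMSD gate; 30 epochs of contrastive training cut the combined loss from 4.04
to 3.15. Held-out top-1 on a single 16-molecule split is noisy — chance is
1/8 = 0.125 and individual seeds range from below chance to ≈ 0.34; the
learning-signal check therefore aggregates five seeds (four of five beat
chance here). R@20 is trivially 1 at batch size 8. A command-line mirror of
these pipelines ships at `inst/cli/molembed`
(`featurize | augment | pretrain | retrieve | edit | fixtures`).

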