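---
title: "Methods: multimodal molecular embeddings at desk scale"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: multimodal molecular embeddings at desk scale}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of its model, the choices behind
it, and what its tests do and do not demonstrate. Everything stated here is
computed by the test suite or by `scripts/acceptance.R`; no empirical claim
beyond those is made.

## The model and its assumptions

The package learns a joint latent space for molecules and free text. Two
Transformer encoders produce 768-dimensional embeddings: a graph Transformer
over heavy-atom molecular graphs and a standard token Transformer over text
(truncated at 256 tokens). The molecule encoder's only access to molecular
geometry and topology is an additive attention bias: a symmetric `a x a`
matrix added to every head's logits before the softmax, combining

* a bond-feature term: the element-wise average of the bond feature vectors
  along the canonical shortest path between two atoms, dotted with a
  learnable vector (`k_edge = 6` slots: one-hot order single/double/triple/
  aromatic, in-ring, conjugation);
* a shortest-path-distance term: bond-count distance times a learnable
  scalar; and
* a 3D term: a bank of `K = 8` Gaussian-basis kernels of the Euclidean
  interatomic distance, passed through a one-hidden-layer ReLU readout.

Assumptions worth making explicit: hydrogens are implicit (no augmentation
or encoding ever manipulates explicit H); the graphs are connected in
practice but disconnection is handled by a sentinel distance equal to the
atom count, which is finite and order-preserving without a special code
path; and a single bias matrix is shared across heads (per-head scaling
would be a straightforward extension, but nothing here requires it).

### The distance kernel

The printed form of the kernel in the source material is ambiguous about
where the width enters. The default here is the literal exponential decay
`psi_k(d) = exp(-d / sigma_k)`, which is what the formula says if read
plainly; a conventional Gaussian bump form
`exp(-(d - mu_k)^2 / (2 sigma_k^2))` with centers on an even grid is
available via `kernel_form = "gaussian"` since the text calls the object a
Gaussian kernel. The widths default to a geometric grid from 0.5 to 10
Angstrom — the range from a covalent bond length to the diameter of a small
drug-like molecule — so the bank resolves both bonded and through-space
proximity. The diagonal of the 3D term is evaluated at `d = 0` (not zeroed):
the kernel is defined there and zeroing it would special-case self-attention
for no modelling reason. The edge and SPD terms are zero on the diagonal
because an empty path has no features and zero length.

### Tie-breaking and determinism

Shortest paths between a pair of atoms are generally not unique. For a
symmetric, reproducible bias the package normalizes each query to
`(min(i, j), max(i, j))` and takes the breadth-first path that expands
neighbors in ascending index order — a deterministic, lexicographically
canonical choice. All other determinism contracts (bitwise-identical
embeddings, augmentations, training traces and CLI reports for identical
inputs and seeds) follow from seeding every random draw with seeds derived
from a user seed via a string hash kept below 2^31.

## Coordinates

3D coordinates come from seeded distance-geometry embedding (ETKDG) followed
by MMFF94 minimization — RDKit's implementation, run behind a small
persistent worker process so a conformer costs milliseconds. This pipeline
was chosen over the in-process Open Babel builder because the builder's
coordinates are not reproducible across calls (its RNG cannot be seeded from
R), and reproducibility is a contract here: the same graph and seed must
give bitwise-identical coordinates. Single atoms are placed at the origin;
embedding failures retry with shifted seeds up to 10 attempts and then error
with the attempt count.

## Augmentations and the RMSD gate

Each molecule used in pretraining is represented by exactly four augmented
views (the original is deliberately excluded):

1. *node dropping* removes exactly `ceiling(0.1 a)` atoms, resampling up to
   20 times until the remainder is connected — 10% is a conservative rate
   that keeps the augmented molecule recognizably the same compound;
2. *subgraph sampling* takes the induced subgraph on the atoms visited by a
   seeded random walk (target 80% of atoms, capped at `10 a` steps);
3. *chemical transformation* adds or removes one functional group from a
   fixed five-entry catalog (methyl, hydroxyl, fluoro, chloro, amino) at a
   uniformly chosen legal site;
4. *substructure removal* cleaves one BRICS bond chosen uniformly among
   those leaving a connected retained fragment of at least 3 atoms and
   discards the smaller fragment.

Every candidate is rebuilt through the chemistry toolkit so implicit
hydrogens repair the open valences, re-embedded in 3D, and gated: a view is
accepted only if its dissimilarity to the original is below 3.0 Angstrom
RMSD, retrying up to 10 times and otherwise returning the
minimum-dissimilarity candidate flagged `accepted = FALSE`. Dissimilarity is
defined as maximum-common-substructure-mapped, Kabsch-aligned coordinate
RMSD: the smaller graph is embedded into the larger by an element- and
bond-order-colored VF2 search (greedily peeling low-degree atoms when no
full embedding exists; at least 3 mapped atoms required, otherwise the
dissimilarity is infinite), and the RMSD is minimized over candidate
correspondences. The catalog of five functional groups and the BRICS rule
table (atom-environment predicates for the published link types, evaluated
with SMARTS) are fixed design choices; the BRICS bond finder reproduces a
reference decomposition's bond sets on the test fixtures exactly.

Chemistry-dependent augmentations can be infeasible (caffeine has no BRICS
bond; heavy-atom methane has nothing to remove). The set builder then falls
back to node dropping under a distinct sub-seed so the contrastive losses
always see exactly four views per molecule.

## Losses

With `z_i^{G1..G4}` the view embeddings and `z_i^{T1..T3}` the caption
embeddings of molecule `i` in a batch of `N` (all L2-normalized immediately
before similarities, never inside the encoders; temperature `tau = 0.1`):

* the cross-modal loss is InfoNCE of the matched (view, text) pair against
  the same text variant of every batch item, averaged over all
  view x variant combinations and the batch. The printed objective
  normalizes over texts only (molecule-to-text); a symmetric variant is
  available behind `direction = "symmetric"`.
* the self-contrastive loss contrasts, per item, the pair kernel
  `sum exp(sim/tau)` over the item's own unordered view pairs against the
  same kernel evaluated between the item and every batch item. For the
  cross-item kernel the package sums all 16 ordered view pairs scaled by
  3/8: a labelled `a < b` subset would make the loss depend on the arbitrary
  ordering of an item's four views, while the full sum is invariant to
  relabelling and preserves both limits (`0` at `N = 1`, `ln N` under
  constant similarities).

Both losses ship with hand-derived analytic gradients with respect to the
raw embeddings (through the L2 normalization); the test suite checks them
against central finite differences to a relative error below `1e-4`.

## Pretraining at desk scale

The corpus is expanded once — four gated augmentations and up to three
captions per molecule — and encoded; training then performs seeded
mini-batch gradient descent with momentum (defaults: batch 8, lr 0.02,
momentum 0.9, 30 epochs) on the two joint-space projection matrices, with
the Transformer bodies frozen at their seeded random initialization. This
linear-probe scheme is the deliberate desk-scale reading of "train the
encoders": it keeps a full run under half a minute on one CPU while leaving
a genuine learning problem (a 64 -> 768 map per modality, fit contrastively),
and the optimizer defaults were chosen on validation seeds disjoint from any
test seed. Full-body backpropagation through the graph Transformer would
change no interface but is out of scope here. The learning-signal check
trains on 32 pairs and evaluates top-1 retrieval on 16 held-out molecules in
batches of 8: individual seeds fluctuate (a single split is only 16
molecules), so the criterion asks that at least 4 of 5 seeds beat the 1/8
chance rate.

## Editing

Molecule editing optimizes a latent vector of an invertible generator for
600 steps against `(1 - cos(c, z_mol)) + lambda (1 - cos(c, z_text))`, where
`c` is the latent translated into the joint space. Two readings of the
prompt-alignment loss exist in the source material; aligning the *original
molecule's* embedding with the prompt is a constant with zero gradient, so
the package aligns the *candidate* embedding, which is the only reading that
can drive the optimization. The step size halves whenever a step would
increase the loss, making every recorded trace non-increasing; `lambda`
defaults to 1. The shipped generator is a toy two-layer affine-coupling flow
over an 8-dimensional standardized descriptor vector (TPSA, HBA, HBD, QED,
WCLogP, MW, rotatable bonds, aromatic rings) with exact inverses, and
decoding realizes the descriptor vector as the nearest library molecule;
this exercises the full loop — noise-initialized latent, translated losses,
backpropagated gradients, inverse mapping, hit judgement — without
pretending to be a trained generative model. The translator is a fixed,
seeded 2-layer ReLU MLP (or the identity when dimensions match). Hits use
strict inequalities with zero margin: the source defines directions but no
thresholds, and a margin would add a free parameter with nothing to
calibrate it against.

## Descriptors

TPSA (Ertl), Wildman-Crippen logP and molecular weight come from the
chemistry toolkit; Lipinski-style HBA (N + O count) and HBD (N/O bearing H)
are computed from the graph. QED is implemented from the published
desirability functions (ADS parameters and mean weights) with this package's
own sub-descriptor routes: SMARTS-based acceptor counts, rotor flags, the
aromatic-ring count as the cycle rank of the aromatic subgraph, and the
standard structural-alert list evaluated by SMARTS (two
disconnected-component patterns are applied as count rules because the
SMARTS engine has no component-level logic). Absolute QED values can
therefore deviate slightly from other implementations (aspirin: 0.562 here
vs. 0.550 for a reference implementation); only the monotone direction of
QED enters any decision (the drug-likeness hit rules). Tanimoto similarity
uses hashed linear-path fingerprints (FP2, 1021 bits) — the installed
path-based implementation — rather than a hand-rolled 2048-bit clone.

## What the synthetic corpus does and does not show

`make_toy_corpus()` pairs ~40 small named drug-like molecules (extended by
seeded functional-group transforms when more are requested) with three
caption templates filled from each molecule's own computed descriptors, so
caption content genuinely correlates with structure — a linear probe on
bag-of-words captions predicts HBA parity above chance by construction. It
emulates the *shape* of a mined molecule-description corpus: several text
variants per molecule, descriptor-bearing sentences, drug-like chemistry.
It does not emulate the linguistic diversity, noise, or weak pairing of
literature-mined text, nor the scale (tens of molecules vs. 160K pairs);
passing tests on it demonstrate that the machinery learns and calibrates,
not that the embeddings transfer to real retrieval or property benchmarks.
Those headline results require GPU-scale pretraining and external benchmark
data, which are deliberately out of scope.

## Numerical choices and degenerate inputs

* Softmax rows are computed with max-subtraction; InfoNCE uses log-sum-exp.
* Zero embeddings raise errors at similarity time rather than propagating
  NaN; non-finite losses abort training with the offending batch named.
* Valence validation bounds the kekulized bond-order sum plus implicit
  hydrogens by charge-adjusted element maxima; every augmentation output is
  validated and re-embedded before it is returned.
* Graphs with a single atom short-circuit conformer generation (origin) and
  have vacuous distance structure; two-atom graphs are valid everywhere but
  are below the 3-atom minimum for augmentation and MCS mapping.
* Problem sizes in the checks — 200 random graphs for the shortest-path
  oracle, 50 rigid transforms, 10 molecules x 20 permutations, 100 gated
  augmentations per kind, 5 pretraining seeds, 500 null-retrieval batches —
  are the package's chosen study conditions: large enough for the property
  being tested to fail visibly if the code were wrong, small enough to run
  on one CPU in minutes.

## Known limitations

* The text encoder is weight-agnostic but ships only with seeded random
  initialization; loading converted pretrained weights is an interface, not
  a shipped artifact.
* Stereochemistry is not encoded (the bond feature schema reserves an
  extension slot); augmentations and MCS mapping ignore it.
* The editing generator is a toy; hit ratios from it characterize the
  harness, not editing quality.
* Pretraining updates projections only; representational changes inside the
  Transformer bodies are out of desk-scale scope.
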