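---
title: "A multimodal synergy regressor: model, design choices and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A multimodal synergy regressor: model, design choices and limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

`synergynet` predicts the Loewe-additivity-based synergy score of a drug
pair on a cancer cell line. This vignette is the package's account of the
science: the model and its assumptions, every tunable that matters, what the
synthetic-data generator does and does not emulate, and the places where the
design was genuinely open and a choice had to be made.

## The regression problem

The unit of data is a quadruple *(drug A, drug B, cell line, score)*. The
score derives from a dose–response matrix reduced under the Loewe
additivity reference model (computing that reduction from raw dose–response
data is out of scope here; the package consumes the scores). Scores in
large screens concentrate near zero with a long positive tail — most pairs
are additive, a minority strongly synergistic — which is why the synthetic
generator reproduces exactly that shape.

## Drug featurization

Everything starts from SMILES. OpenBabel (`obabel`) performs parsing and
perception (atoms, bonds, aromaticity, hybridization, formal charge); all
featurization on top of it is implemented in the package:

* **Morgan fingerprint** (`morgan_fingerprint()`): radius-2 circular
  neighborhoods hashed to 256 bits. Atom identifiers start from an
  order-invariant tuple (element, heavy degree, attached H, formal charge,
  ring membership, aromaticity) and are iteratively rehashed with the sorted
  (bond-order, neighbor-id) shells, so any SMILES spelling of a molecule
  yields the same bits. Bit collisions at 256 bits are accepted; there are
  no count fingerprints.
* **Atom sequence** (`atom_sequence()`): one 27-wide row per heavy atom —
  element one-hot over {C,N,O,S,F,Cl,Br,I,P,other} (10), heavy-degree
  one-hot 0–5 (6), formal charge (1), hybridization one-hot
  {sp, sp2, sp3, other} (4), aromatic flag (1), attached-H one-hot 0–4 (5).
  Hydrogens are implicit (heavy atoms only); rows follow the SMILES atom
  order.
* **Molecular graph** (`molecular_graph()`): vertices are heavy atoms, any
  bond order becomes an unweighted edge, and node features are *identical*
  to the atom-sequence rows. The branch additionally uses order-2 and
  order-3 **power graphs**. The package connects all pairs within
  shortest-path distance *k* (`power_mode = "cumulative"`); the alternative
  reading — distance exactly *k* — is available as `power_mode = "exact"`.
  Cumulative is the default because each order then works as a standalone
  message-passing support containing the chemical bonds. Supports are
  normalized as `D^{-1/2} A D^{-1/2}` with no added self-loops (the plain
  formula; `add_self_loops = TRUE` gives the common GCN variant), and
  zero-degree nodes have their degree clamped to 1 so their rows are zero
  rather than NaN.
* **Point cloud** (`point_cloud()`): a single 3D conformer, zero-padded to
  `cloud_len` rows. Conformers come from a deterministic distance-geometry
  embed implemented in the package: target distances from covalent radii
  scaled by bond order, with contraction factors 0.82/0.76/0.72 for
  topological paths of 2/3/≥4 bonds; classical MDS into three dimensions
  with eigenvector signs fixed for full determinism; then 60 deterministic
  harmonic-descent steps pulling bonds and 1–3 distances to their targets
  (`relax = FALSE` disables the refinement). This trades conformational
  realism for exact reproducibility: identical SMILES always give identical
  coordinates, with chemically sensible bond lengths (ethane C–C ≈ 1.52 Å,
  benzene ring ≈ 1.42 Å). Coordinates are deliberately *not* centered or
  rotationally normalized, and the downstream encoder is not
  rotation-invariant — a caveat inherited by design.

## Encoder branches

* **Sequence branch**: a BiLSTM (`d_l` units per direction, forget-gate bias
  1) runs over the exact-length sequence; padded positions are masked so the
  batched computation equals exact-length processing bit for bit. The full
  `2 d_l`-wide output feeds a stack of `gmlp_layers` gated-MLP blocks
  (`gmlp_input = "forward_half"` restricts to the forward states — the
  information-preserving full output is the default). Each block computes
  `Z = GELU(hU)`, splits channels in half, gates `Z_1 ⊙ (W Z_2 + b)` with an
  `L × L` token-mixing matrix (initialized near zero with bias 1, so the
  gate starts as the identity), and projects back. The two drugs are fused
  by position-wise addition followed by multi-head self-attention; the token
  matrix is reduced to a vector by a max over positions
  (`seq_pool = "mean"` available). Padded positions enter the attention as
  null tokens.
* **Graph branch**: the fixed three-part stack — three GCN layers on the
  order-1 support, two on the order-2, one on the order-3 — each layer
  exactly `ReLU(A_norm H W)` with no bias; per-node concatenation of the
  three parts, then global max pooling. Drug one, drug two and their
  block-diagonal pair graph (no cross-drug edges) share one weight set (a
  Siamese reading of the architecture); the branch output is the ordered
  concatenation drug-1 ‖ pair ‖ drug-2.
* **Point-cloud branch**: stages 3→32→64→128→160, each a convolution
  (kernel size `cloud_kernel`, default 1 — per-point maps in the point-net
  style, so atom order does not leak through the kernel), batch norm, ReLU,
  plus a same-width residual convolution; global max pool over positions.
  Convolutions carry no biases (batch normalization absorbs channel
  shifts). With max pooling, adding more zero padding cannot change the
  embedding — asserted in the tests.
* **Cell branch**: `F_cell = FNN(G' || M)` — z-scored expression factors
  concatenated with binary mutation indicators, one hidden layer
  (`cell_hidden`, ReLU) and a linear reduction to `cell_dim`. The package
  consumes a precomputed factor matrix; factor summarization itself
  (e.g. from raw microarray intensities) is upstream of the package.

The predictor receives `H_m || H_c || H || H_D || F_cell` and applies three
fully connected layers: the first two with ReLU followed by batch
normalization, the second at half the width of the first, the last a single
neuron. Training minimizes mean squared error.

## Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `d_l` | 64 | LSTM units per direction (sequence width `2 d_l`) |
| `gmlp_layers`, `gmlp_dim` | 3, 128 | gated-MLP depth; channel projection (split in two) |
| `heads`, `d_k`, `d_v` | 4, 32, 32 | attention heads and per-head widths |
| `gcn_width` | 64 | output width of every graph-convolution layer |
| `cloud_channels` | 3,32,64,128,160 | point-cloud channel schedule |
| `cell_hidden`, `cell_dim` | 256, 128 | cell-line FNN widths |
| `head_width` | 1024 | first predictor layer (second is half) |
| `max_atoms` | 64 | sequence capacity; token-mixing matrices are `max_atoms²` |
| `cloud_len` | 100 | padded point-cloud length (Å coordinates) |
| batch size | 256 | training minibatch |
| `lr0`, `gamma`, `step_size` | 0.001, 0.9, 20 | step-decay schedule `lr0·gamma^⌊e/20⌋` |
| epochs, patience | 100, 20 | maximum epochs; early stopping on validation MSE |
| AdamW weight decay | 0.01 | decoupled regularization |

Branch widths, depths and the optimizer protocol above are the package's
defaults; the batch size, optimizer and schedule constants are fixed
protocol, while the widths are conventional choices exposed in
`synergy_config()`. The epoch budget and early-stopping patience are package
choices (nothing in the protocol pins them); 10% of the training examples
are held out inside `train_synergy()` for the stopping criterion.

## Drug order

Nothing in the architecture symmetrizes the pair: the fingerprint
concatenation and the pair-graph block order both depend on which drug is
"first", though the measured synergy does not. With
`order_augment = TRUE` (default) training data contain both orderings and
prediction reports the mean of both, removing the arbitrary asymmetry while
leaving the architecture untouched.

## The synthetic generator

`make_dataset()` emulates the *shape* of a combination screen, not its
pharmacology:

* molecules assembled from a fixed valence-correct vocabulary of ring
  cores, substituents and amide/ester-type linkers (5–25 heavy atoms);
* dense correlated expression factors (AR(1) covariance, ρ = 0.5) and
  Bernoulli(0.02) mutation calls; five cycling tissue labels;
* scores from the documented generating function
  `raw = 3·tanimoto(fp_a, fp_b) + 1.5·(n_a/20)(n_b/20) + v·expr + 2·tanimoto·(v·expr)`
  (v a fixed unit vector), standardized over the dataset, skewed by
  `z + tail_weight·max(z, 0)`, restandardized and mapped to
  `score_center + score_spread·z` plus Gaussian noise. Defaults (center 5,
  spread 18, tail weight 1) put the marginal in roughly [−50, 75] with a
  positive tail. `noise_sd = NULL` calibrates the noise so that an oracle
  knowing the generating function would reach a Pearson correlation of
  `target_pcc` (default 0.95): `noise_sd = spread·√(1/pcc² − 1)`.

The generator's signal depends only on features the model can see — by
design. Passing the learning tests therefore demonstrates that the
featurization, encoders, gradients and optimizer are wired correctly and
can recover a planted signal at the calibrated noise level; it says nothing
about biology, target interactions, or how the model would rank real drug
combinations. Two further honest caveats: with 16 distinct drugs a 512-bit
fingerprint pair nearly identifies the pair, so every modality is in
principle redundant given enough capacity — ablation differences at this
scale reflect optimization and inductive bias, not information content; and
the test split shares drugs and cell lines with training (only the triples
are held out), mirroring the random-split protocol rather than
leave-drug-out generalization (stricter `--split-by` options exist in
`split_train_test()`).

## Study sizes and numerical choices

The test suite and the acceptance script run desk-scale studies chosen so a
single CPU completes them in minutes: the default 2,000-example screen (16
drugs, 17 cell lines, 40 factors, 200 mutation genes) with
`max_atoms = 32` and `cloud_len = 48` — paddings sized to the synthetic
vocabulary's largest molecules; the package defaults (64/100) cover typical
drug-like compounds. The overfit study uses 32 examples and 300 epochs; the
recovery study trains at most 100 epochs with early stopping.

Numerical specifics worth knowing:

* All gradients are computed by the package's reverse-mode tape and are
  verified against central finite differences (tolerance 1e−6) for every
  operation and for the full assembled network.
* Batch-norm uses population statistics within a batch, running moments
  (momentum 0.1, ε = 1e−5) in evaluation, so single-example prediction is
  well defined and two forward passes are identical.
* Max-pooling ties break to the first row; attention softmax subtracts the
  row maximum before exponentiation.
* `zscore()` uses the population standard deviation (denominator *n*);
  constant columns map to zeros rather than NaN.
* Weight init is Glorot-uniform; LSTM forget biases start at 1; token-mixing
  matrices start near zero (gate ≈ identity).
* Inside cross-validation, expression factors are re-standardized per fold
  using only cell lines that appear in that fold's training examples
  (`scale_mode = "train"`), a deliberate strengthening against leakage;
  `scale_mode = "global"` restores plain load-time scaling.
* Checkpoints embed the configuration, all weights, running moments and the
  data-driven dimensions; a round trip reproduces predictions bitwise.

## Interpretive corners

Three places in the architecture are specified only loosely anywhere, and
the package's readings are explicit:

* the predictor's four drug-feature slots are taken as (fingerprint pair,
  attention-fused sequence feature, graph fusion, point-cloud pair);
* the cross- and self-attention fusion variants (`MMFSyn-CA`, `MMFSyn-SA`)
  are minimal single-block implementations — per-modality tokens projected
  to a common width, one attention block (queries from the cell token for
  CA), flattened into the head;
* `Seq_B` (no attention fuser) pools the position-wise sum of the two
  sequence features directly; `Graph_B` drops the pair-graph segment.

## Limitations

Single conformer and no stereochemistry or tautomer handling; vertex-only
message passing (no bond-attribute features); no uncertainty estimates; no
pretraining; training is single-device and in-memory. The engine favors
transparency over speed — it is fast enough for the desk-scale studies
here, but real-screen scale (tens of thousands of examples, hours of
training) is outside its design envelope.
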