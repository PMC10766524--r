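---
title: "Ranking congeneric ligands with a physics-informed Siamese graph attention network"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Ranking congeneric ligands with a physics-informed Siamese graph attention network}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Lead optimization explores a congeneric series: ligands sharing a core
scaffold and differing in substituents, docked into one protein pocket.
The quantity that matters is not the absolute affinity of each ligand but
the *relative* affinity between pairs — ΔpIC50 = pIC50(i) − pIC50(j).
Predicting the difference directly cancels systematic errors that plague
absolute-affinity models and matches how chemists actually rank analogs.

PocketPairNet implements a Siamese network over pairs of pocket–ligand
complexes.  Both complexes pass through one shared graph encoder; the two
graph-level vectors $x^{(i)}, x^{(j)}$ are spliced into the pair
representation $\tilde x = x^{(i)} \oplus x^{(j)} \oplus (x^{(i)} -
x^{(j)})$, and two independent three-layer feed-forward heads predict the
difference $\hat y^{(i,j)}$ (regression) and the probability
$\hat p^{(i,j)}$ that ligand *i* is the more active one (an auxiliary
ranking task that penalizes small-error but wrongly-ordered pairs).

## The complex graph

Each complex is a directed graph over the heavy atoms of the ligand and
of the pocket (residues with any atom within 8.0 Å of the ligand, kept
whole):

* **covalent edges** — each bond contributes both directions;
* **virtual distance edges** — ligand↔pocket atom pairs at ≤ 5.0 Å,
  carrying the intermolecular geometry;
* **virtual aromatic nodes/edges** — one pseudo-node per aromatic ring
  centroid (ligand and pocket), connected to the ring members, letting
  π-system interactions pass messages through a single hub.

Feature vectors cover 15 atomic categories (mass, explicit/implicit
valence and van der Waals radius as scalars; element, degree, formal
charge, hybridization, aromaticity, ring membership and size, H-bond
donor/acceptor flags, chirality tag and hydrogen count as one-hots) and
5 bond categories (order, conjugation, ring membership, stereo tag, edge
kind).  Virtual nodes and virtual edges carry all-zero features — their
meaning comes entirely from their connectivity and geometry.  The exact
one-hot composition is a declared schema (`atomFeatureSchema()`); the
category counts are contractual, the composition is configurable.

## Message passing

A pocket-only GCN (symmetric-normalized adjacency with self-loops)
pre-encodes the pocket atoms before the complex graph is assembled.
After linear-ReLU initial encodings of nodes and edges (the intermediate
edge encoding lives in dimension m/2), L layers alternate two attention
blocks:

* **DAEE (edge-to-edge)** — edge $e_{\vec{uv}}$ attends over its incoming
  neighbor edges $e_{\vec{ku}}$.  The attention logit is a single-head
  GAT-style score of queries and keys, *plus an angle embedding*: the
  angle θ between the two edges is binned into six domains of π/6
  (`angleDivider`) and embedded through a learned matrix; *plus a
  statistical-potential bias* $p_{k,u}$ — 1 for covalent edges,
  $2\ln P(\mathrm{type}_k, \mathrm{type}_u, d)$ for virtual edges with
  covered types, 0.8 when a type is uncovered.  Messages are
  attention-weighted sums of key vectors, passed through a two-layer MLP
  and a double residual `Res(Res(h + branch))` with `Res` = LayerNorm.
* **DEN (edge-to-node)** — node v attends over its neighbors with the
  same bias term (no angle, since only one edge is involved), and
  aggregates the *same-layer* edge states of its incoming edges.  The
  attention of the last DEN layer is what `extractAttention()` exposes.

The pocket is then dropped and an attentive super-node readout (a
learnable graph vector that attends over the ligand atoms and updates
through a GRU cell for a configurable number of timesteps) produces the
graph vector.  Readout over ligand heavy atoms only: the pocket and the
virtual centroids inform the atom states during message passing but do
not enter the pooled representation.

### The statistical potential

The bias table is a distance-binned atom-pair potential (element
alphabet, 0.25 Å bins over (0, 5] Å).  `fitReferencePotential()` is an
inverse-Boltzmann estimator — observed contact counts over the counts
expected if a type pair's contacts were spread uniformly over the bins,
with an additive pseudocount of 1 and clipping to [1e−3, 1e3].  The
published field-theoretic potentials this stands in for are pluggable
through the same `PotentialTable` JSON interface; the package ships a
small default table fitted on its own synthetic fixtures so everything
runs offline.  The natural logarithm is used in the bias (the standard
convention for inverse-Boltzmann potentials).  The constants 1 and 0.8
are part of the contract and are not silently configurable.

## Inference, uncertainty, metrics

With references $\{(y^{(i)})\}$ from the same series, each pairwise
prediction anchors an absolute estimate $\hat y_i^{(u)} = y^{(i)} -
\hat y^{(i,u)}$; the reported prediction is their mean and the
uncertainty their **population** variance (1/N — deliberately, matching
the estimator's definition; with one reference the variance is exactly
0).  `evaluateSeries()` repeats reference selection (default 10×, seeded)
and reports Pearson R, Spearman ρ (average ranks on ties) and RMSE;
`rmsePw()` gives the pairwise RMSE in pIC50 or kcal/mol, the two scales
related by exactly RT·ln 10 with R = 1.987×10⁻³ kcal K⁻¹ mol⁻¹ and
T = 297 K, the same constants as `dgToPic50()`.

## Training

The hybrid loss is MSE on $\hat y$ plus α (default 1) times the binary
cross-entropy of the ranking head; exact ties (ΔpIC50 = 0) are excluded
from the entropy term.  Reference-scale defaults follow the full-scale
protocol (batch 96, lr 5×10⁻⁷, 5.75 epochs with validation every 0.25
epoch); fractional epochs are implemented as a step budget.  The
optimizer is Adam with gradient-norm clipping at 5 (a package choice —
the original protocol does not name one), early stopping on validation
pairwise RMSE with patience 8 units, and series-level cross-validation
folds (`seriesFolds()` never splits a series).  Fine-tuning
(`fineTunePairNet`) uses batch 30, 10 epochs, lr 10⁻⁵ by default, forms
all directed pairs among the reference ligands only, drops the auxiliary
task and freezes the classification head bitwise.

Training pairs are used in both directions (the reversed pair carries
the negated label), which doubles the data and teaches the antisymmetry
of the task; evaluation pairs are single-direction.  Training pairs are
filtered to Tanimoto similarity > 0.6 and label-balanced in 0.5-pIC50
bins with a 4:1 occupied-bin cap (undersampling dense bins, oversampling
sparse ones with replacement, seeded; labels never change, only
multiplicities).  The similarity fingerprint is Open Babel's FP2
path-based fingerprint via ChemmineOB — the R toolchain has no Morgan
fingerprint implementation, and any standard 2-D fingerprint serves the
purpose of excluding non-analog pairs from training.

## Active learning

`runCampaign()` simulates a lead-optimization campaign: the earliest
synthesized ligand seeds the reference set; each iteration scores the
remaining candidates and picks the top 3 by the acquisition score
$a = \hat y$ (iteration 1) or $a = \hat y + \beta\sigma^2$ (later
iterations), fine-tuning on all pairs among the current references from
iteration 2 on.  β > 0 explores (uncertain picks expand the model's
domain), β < 0 treats uncertainty as a penalty.  Selection-order
accounting counts the initial reference as 1 and increments picks in
batch order; acquisition ties break by ligand id.  The fine-tune set at
iteration k ≥ 2 is all unordered pairs among *all* current references —
the natural extension of the second-iteration rule.

## Interpretability

`extractAttention()` returns the per-edge attention of the last DEN
layer (recording never perturbs the prediction).  `smeAttribution()`
masks each substructure's node states at the readout (message passing is
not re-run), with substructures from a rule-based retrosynthetic
fragmenter — acyclic single bonds at ring attachment points and amide
C–N bonds are cut, a BRICS-style simplification authored here because no
installed R package provides BRICS; user-supplied fragments and manual
merge groups are supported.  Attribution is ŷ − ŷ(masked), normalized by
the total.  The normalized scores lie in [0, 1] and sum to 1 only when
all raw attributions share a sign; with mixed signs the package warns
and the raw scores are authoritative.

## The synthetic study system

`makeSeries()` generates the desk-scale study conditions: a pseudo-pocket
of 12 glycine-like residues on a jittered sphere (radius 6 Å) around a
cavity; ligands are para-substituted benzenes over a 6-substituent
alphabet (H, F, CH3, Cl, NH2, OH) with additive planted contributions of
0 to 1.0 pIC50 around a base of 6.0, activity noise SD 0.1 pIC50, and
rigid pose jitter SD 0.3 Å.  These emulate what the network actually
consumes — shared pocket, congeneric analogs, docked-like poses, additive
structure–activity signal — and deliberately omit conformational
flexibility, protonation states, water, and binding-mode changes; pose
generation is constructed, not docked, because the network consumes poses
agnostically.  Passing tests on this system demonstrate that the
architecture, pipeline and training machinery recover a planted signal;
they say nothing about accuracy on real protein–ligand data, which
requires large-scale training.

Two held-out experiments are built on this generator.  *Parameter
recovery*: a small network trained on four series must rank a fresh
series from the same generator (within-series Spearman ρ, averaged over
seeded reference draws and three training seeds).  *Few-shot
fine-tuning*: the trend with the number of fine-tuning references is
measured on an out-of-domain target — a series whose substituent
contributions follow a different pattern than the training series — so
zero-shot transfer is poor and reference information genuinely carries
the new structure–activity relationship.  All reference counts are
evaluated on one common held-out candidate subset of that series;
comparing counts on different candidate subsets would confound the trend
with subset composition, especially near the performance ceiling of the
in-domain task.

Desk-scale experiments in the test suite use a small network
(hidden width m = 8, L = 1 layer, pocket-GCN depth 1, one readout
timestep, no dropout), 4 training series of 8 ligands, a 16-ligand
held-out series, and an elevated learning rate (3×10⁻³, full training in
seconds) — problem sizes chosen so the whole suite runs comfortably on a
single CPU while still exercising every code path; the reference-scale
defaults remain available through the configuration objects.

## Numerical choices and degenerate inputs

* LayerNorm uses population variance with ε = 10⁻⁵; LeakyReLU slope 0.01.
* Attention is single-head (the score vectors are single vectors).
* Empty neighborhoods (an edge with no neighbor edges, an isolated node)
  contribute a zero message; the residual path still updates the state.
* An angle of exactly π clamps into the sixth domain; angles outside
  [0, π] beyond a 10⁻⁹ slack are errors.
* Unknown elements map to the "other" one-hot slot, never an exception;
  potential lookups for uncovered types fall back to the 0.8 bias.
* Gradients come from a small reverse-mode tape engine written for this
  package and are verified against central finite differences in the
  test suite; all randomness (init, batching, dropout, reference draws)
  is funneled through seeds, and `forwardPair` is bit-deterministic.
* Checkpoints embed configuration, parameters and the potential table.

## Known limitations

The pocket-identity check warns (not errors) on mismatched pockets, since
numerically identical pockets can arrive from different files.  The MCS
used by `selectPose()` is a maximum-clique search on the modular product
graph — exact but exponential in the worst case, intended for drug-sized
congeneric ligands.  Ring perception takes the shortest cycle through
each bond (size ≤ 8), an SSSR surrogate that is adequate for typical
scaffolds but can miss exotic cage rings.  Aromaticity is taken from
input flags or alternating Kekulé patterns, not a full electron count.
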