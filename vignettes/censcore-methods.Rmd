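---
title: "Context-explanation-network scoring: models, terms and design choices"
author: "censcore"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Context-explanation-network scoring: models, terms and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(censcore)
```

## The model

Most machine-learned scoring functions map a protein–ligand pose directly
to a binding-affinity estimate. A context explanation network (CEN)
instead predicts the *coefficients* of an interpretable linear model,
conditioned on the 3D structure: for a complex $e$ with precalculated,
scaled physicochemical terms $t_e \in \mathbb{R}^m$, a convolutional
network applied to a voxelized representation of the complex outputs a
weight vector $w_e \in \mathbb{R}^m$, and the predicted affinity (in pK
units, $-\log_{10}$ of a molar $K_d$, $K_i$ or IC$_{50}$) is the pure
linear combination

$$\hat{y}_e = w_e \cdot t_e = \sum_j w_{e,j}\, t_{e,j},$$

with no intercept. Each product $w_{e,j} t_{e,j}$ is that term's
contribution to the score, so the prediction decomposes exactly — the
package enforces `affinity == sum(contributions)` as an identity of the
same arithmetic, not an approximation. The weights themselves are the
scientific output: they indicate, per complex, which interactions the
model credits, and the interpretability machinery (per-atom attribution,
weight z-scores, weight-space embedding) operates on them.

## Physicochemical terms

The term registry is a data frame of descriptors, one per term, with
canonical smina-style names. All pairwise families act on receptor–ligand
*heavy-atom* pairs within a cutoff $c$ (8 Å throughout), through the
surface distance $d_s = d - d_0$, where $d_0$ is the sum of the two
atoms' XS van der Waals radii:

* `gauss(o,w,c)`: $\sum \exp(-((d_s - o)/w)^2)$ — attractive steric
  shape-complementarity terms; the canonical pair is $(o=0, w=0.5)$ and
  $(o=3, w=2)$.
* `repulsion(o,c)`: $\sum (d_s - o)^2$ for $d_s < o$, else 0 —
  penalizes sub-contact overlap.
* `hydrophobic(g,b,c)`: a linear ramp in $d_s$, 1 below $g = 0.5$, 0
  above $b = 1.5$, restricted to pairs in which both atoms are
  hydrophobic.
* `non_dir_h_bond(g,b,c)`: the same ramp with $g = -0.7$, $b = 0$,
  restricted to donor/acceptor-complementary pairs — a non-directional
  hydrogen-bond proxy, nonzero only for sub-contact geometry.
* `electrostatic(i,cap,c)`: $\sum q_1 q_2 / d^i$ for $i \in \{1, 2\}$,
  each pair's value capped at magnitude 100 (sign preserved; the cap is
  a guard against vanishing distances).
* `atom_type_gaussian(t1,t2)`: the $(o=0, w=1)$ Gaussian restricted to
  one unordered XS type pair — 325 candidates over the 25 steric types,
  the directly atom-attributable part of the registry.
* counts: `num_hydrophobic_atoms`, `num_heavy_atoms`, `ligand_length`
  (largest intra-ligand heavy-atom distance), and `num_tors_div`. The
  rotatable-bond term is defined only up to a monotone convention; we
  use the count divided by 5, the scale on which rotor penalties are
  conventionally expressed.

`candidateTermRegistry()` assembles the full 348-descriptor candidate
set (23 non-steric descriptors spanning several parameterizations per
family, plus the 325 typed Gaussians); `filterSparseTerms()` prunes
typed Gaussians that are nonzero in less than 1% of a corpus, counting
training and test examples jointly. `defaultTermRegistry()` is the
desk-scale default — one descriptor per distinct family plus typed
Gaussians over a compact six-type set (32 terms). Near-duplicate
parameterizations of one family are deliberately excluded from the
default: they make the term matrix ill-conditioned, which inflates the
variance of *any* weight estimate without probing anything new (see the
synthetic study below).

XS atom typing follows the Vina extended scheme from element and bonding
context: carbons bonded only to carbon/hydrogen are hydrophobic,
heteroatom-bonded carbons are not; nitrogen and oxygen with an attached
hydrogen are donor-capable; oxygen is always acceptor-capable, nitrogen
when a lone pair remains accessible; halogens count as hydrophobic and
metals as donors. The full rule table ships as `xsTypeTable()` so it is
auditable. Structures are assumed protonated and charged upstream (the
usual Open Babel preprocessing); when a file carries no charges the
reader zero-fills them and flags `metadata$chargesSource`, so
charge-dependent terms evaluate to zero rather than failing.

### Scaling

Terms have heterogeneous units and ranges. Per term, the scaling factor
is the maximum absolute raw value over all $T$ corpus examples (1 for
all-zero columns); dividing by it is the unique simple rule that maps
every term into $[-1, 1]$ *without changing any term's sign*, which can
be physically meaningful (e.g. a negative electrostatic total is
favorable). The factors are fitted once over train and test jointly,
persisted as JSON, bundled into checkpoints, and re-application is a
guarded no-op, so inference always sees the training-time scale.

## Voxelization

`voxelize()` deposits, for each heavy atom, a compactly supported
radially decreasing kernel — Gaussian $e^{-2x^2}$ of $x = d/r$ out to
one vdW radius, then the matching quadratic decay reaching zero at
$1.5r$ — into one of 28 channels: 14 receptor-side plus 14 ligand-side
XS type groups, on a cubic grid centered at the ligand centroid
(production geometry: 48³ voxels at 0.5 Å). The kernel constants are
configuration, not contract: tests assert only kernel-independent
properties (non-negativity, monotone decay, channel-bank disjointness,
rigid-motion invariance of total density up to discretization). Atoms
falling outside the grid are silently truncated and tracked by a
coverage statistic. Training-time augmentation samples a uniform random
rotation (random unit quaternion) and a per-axis uniform translation of
at most 2 Å — "at most" is read as an $L_\infty$ ball, the common
grid-augmentation semantics.

## The network

The backbone is configuration data — a list of convolution, average
pooling, global pooling and affine layers — so tiny desk backbones and
the production backbone share one forward/backward code path. The
production configuration is the default2018-style stack: 2× average
pooling and 3×3×3 convolutions of 32, 64 and 128 filters (the two lower
stages followed by 1×1×1 mixing convolutions, all ReLU), flattened into
two parallel 144-output affine heads whose sum is the weight vector.
This transcription is validated by an exact parameter count:

```{r}
countParameters(cenProductionConfig())
```

The engine is written in R against BLAS (convolution via unrolled voxel
patches); backpropagation is verified against central-difference
numerical gradients in the test suite. Initialization is He-scaled and
bitwise-reproducible under a seed. Evaluation mode is deterministic by
contract; all stochasticity (augmentation, shuffling) lives in training.

The desk-scale backbone, `cenTinyConfig()`, is global mean pooling with
a fixed gain (rescaling mean channel densities to order-one features),
a frozen per-feature standardization layer calibrated once on training
grids (`calibrateModel()`; the statistics travel with the checkpoint),
one 16-unit ReLU layer, and a linear head. Pooled channel densities
expose composition-style context (how much hydrophobic carbon lines the
pocket) while keeping a CPU training run in the minutes range.

## Training protocol

SGD with learning rate 0.01, weight decay $10^{-4}$, momentum 0.9;
step-decay learning rate ×0.1 every 80 epochs; smooth-L1 loss between
predicted and observed pK, averaged per batch of 25; 250 epochs at
production scale (desk runs cap the optimizer step budget instead); and
a fresh rigid augmentation per *presentation* of each example. The
smooth-L1 transition parameter is not fixed by the protocol; we default
to $\beta = 1$ pK, the conventional choice. Within-epoch order is
reshuffled from the run seed; the loss is averaged per batch element.
Gradients flow only through the weight head — the terms are fixed,
precalculated inputs, so the network cannot relabel chemistry, only
reweight it. Turning augmentation off makes runs bitwise repeatable,
which the tests exploit.

## Dataset curation and splits

Affinity records (`Kd`/`Ki`/`IC50`, converted uniformly to
pK $= -\log_{10}$ molar) are filtered by measurement qualifier: keep
"=" and "~", drop ">" (affinity only known to be weaker), keep "<" only
when the bound is at most 1 µM — such entries are treated downstream as
exact values, since no censoring model is specified; bounds exactly at
1 µM are retained (inclusive reading, flagged here). Entries whose
chains map to two or more sequence clusters are removed as ambiguous;
entries absent from the cluster table are removed as unclustered.

`clusteredKFold()` assigns whole clusters to folds — the defining
constraint is that no cluster ever straddles folds, preventing homology
leakage — balancing sizes greedily (largest cluster into the currently
smallest fold; ties broken by a seeded shuffle, so plans are
deterministic).

## Interpretability

*Per-atom attribution.* For each typed steric Gaussian term, each
in-cutoff pair's Gaussian value $g$ is divided by the term's scaling
factor (the same factor applied to the precalculated term), multiplied
by the term's predicted weight, and split half/half between the two
atoms; multi-pair atoms accumulate sums. Conservation — atom totals
equal the summed weighted scaled typed-Gaussian contributions — holds to
$10^{-9}$ relative and is tested on every run. `writeAttributionPDB()`
is presentation only: values are clamped to $[-0.15, +0.15]$ for
coloring and, with the display filter on, magnitudes at or below 0.025
are zeroed; the attribution math itself is never thresholded.

*Weight z-scores.* Per term, the mean target-set weight is compared with
the reference-corpus mean and *population* standard deviation (the
convention is recorded in the report header; the choice is ours, as
either convention is defensible), giving
$|z| = |\bar{w}_\text{target} - \bar{w}_\text{ref}| / \sigma_\text{ref}$.
Zero-spread terms are flagged rather than divided by zero.

*Weight-space embedding.* Exact t-SNE (perplexity calibrated per point
by bisection; early exaggeration; momentum gradient descent),
deterministic under a seed, with a k-means cluster-consistency score —
labels from k-means in the original weight space compared, under the
best label matching, with k-means labels on the embedded points — as the
sanity check that similar weight vectors land in adjacent regions. The
implementation is compact and exact ($O(n^2)$ per iteration), intended
for the hundreds-of-points scale of weight-vector sets.

*Screen metrics.* AUROC via the rank statistic with averaged ties
(equal to the probability a random active outranks a random inactive;
tested against exhaustive pair counting and an independent ROC
implementation), plus enrichment factors
$\mathrm{EF}_f = (\text{actives in top } f)/(f \cdot n_\text{actives})$
at configurable top fractions.

## The synthetic study

The generator exists so that every module — and above all the CEN's
defining capacity, context-dependent weighting — is testable without
external downloads. Each toy complex is a ligand (8–14 heavy atoms of
C/N/O with signed partial charges, packed into a 2.2 Å ball, plus a
detached surface carbon guaranteeing a hydrophobic patch) inside a
pocket built from two receptor populations:

* a charged inner ring of 12 atoms (balanced O⁻/N⁺, net-neutral by
  construction), one to three of which are placed at hydrogen-bond
  distance (2.7–3.0 Å) from polar ligand atoms — yielding sub-contact
  pairs that exercise the hydrogen-bond and repulsion ramps — and one or
  two near-contact carbons against the ligand's hydrophobic patch. This
  population is drawn *identically in every context*.
* a context-bearing outer shell (30–44 atoms at 6.5 ± 0.8 Å) whose
  hydrophobic-carbon fraction is drawn from a per-context band:
  0.15–0.25 (polar pocket) vs 0.75–0.85 (hydrophobic pocket). The shell
  carries no charge, so the electrostatic term distribution is
  context-independent; only the voxel channels reveal the context.

The true affinity is $y_e = w^*_{k(e)} \cdot t_e + \varepsilon$,
$\varepsilon \sim N(0, 0.3)$ pK, clipped to $[0, 14]$, where $k(e)$ is
the context implied by the structure and $t_e$ the scaled terms. The
contexts share all weights except an opposing-sign weight of $\pm 6$ on
`electrostatic(i=1)`. This construction makes the context-dependent
component roughly half the label variance while being invisible to any
single global weight vector: the electrostatic term is near zero-mean,
so the flipped contribution cannot be captured linearly in the terms,
only by reading the context from the structure.

Three generator details are validity constraints rather than tunables:
receptor atoms keep at least 2.6 Å from ligand atoms (sub-van-der-Waals
clashes would produce heavy-tailed electrostatic outliers that compress
the corpus-wide max-abs scale and with it the recoverable signal);
molecules are net-neutral (net-charge fluctuations have the same
outlier effect); and cluster ids are drawn as 20 jittered clusters per
context, fine-grained enough that greedy size balancing also keeps fold
composition roughly balanced. A small fraction of entries receive a
second chain in a different cluster to exercise ambiguity removal, and
qualifiers are sampled (85% "=", 7% "~", 4% ">", 4% "<") so the
affinity filter has real work.

What passing this study shows — and what it does not: the study
demonstrates end-to-end parameter recovery under a *known* context
signal that is strongly grid-visible and binary. Real binding-affinity
corpora have unknown, graded, many-dimensional context, docked-pose
noise, and term distributions far from this toy's; a CEN's held-out
correlation there is an empirical question this package's tests cannot
answer. The generator also makes no claim of physical realism: no force
field, no covalent geometry beyond separation floors, charges placed
for signal balance rather than chemistry.

Study sizes used by the automated checks: the parameter-recovery run
uses the generator defaults (600 complexes, 16³ grids at 1 Å, a
16-hidden-unit CEN trained for at most 300 steps on two folds of a
clustered 3-fold plan) — sizes chosen so the full study runs in a few
minutes on one CPU while leaving the achievable correlation (~0.97 with
the true weights) well above the 0.9 recovery bar. Across development
probes at seven seeds the trained CEN scored 0.92–0.96 held-out while
the best global OLS vector scored 0.40–0.74; the margins are
comfortable but the OLS side does drift toward its bound on corpora
where the electrostatic scale compresses.

## Numerical and degenerate-input choices

* Pair enumeration is defined by exact equality with an all-pairs
  double loop (tested at $10^{-9}$ relative); the implementation uses a
  vectorized distance matrix, adequate at pocket scale.
* Distances below $10^{-6}$ Å are floored in the electrostatic
  denominator; the per-pair cap bounds the result anyway.
* All-zero term columns scale by factor 1; re-scaling an
  already-scaled vector is a no-op (the `scaled` attribute is the
  contract, and `predictAffinity()` refuses unscaled input).
* Empty pair sets are valid (interaction terms 0); empty ligands are
  rejected at read time.
* Ties in greedy fold balancing go to the lowest fold index after a
  seeded shuffle of equal-size clusters.
* The learning-rate schedule is exact integer arithmetic
  (`lr * gamma^(epoch %/% step)`), so boundary epochs are unambiguous.
* NaN/Inf loss aborts training with the epoch and learning rate in the
  message rather than continuing silently.

## Known limitations

* The structure readers cover the common PDB/PDBQT/SDF/MOL2 cases
  (including charge round-trips) but are not full dialect parsers;
  exotic records pass through bio3d/ChemmineR behavior.
* Receptor bonding is inferred from covalent-radius distance when
  connectivity is absent; unusual coordination can mistype atoms, and
  without explicit hydrogens donor assignment falls back to heuristics
  (flagged in metadata).
* Aromaticity is taken from ligand bond blocks only; receptor carbons
  are treated as aliphatic, which merges the two carbon channels'
  aromatic subtypes.
* The R/BLAS network engine is CPU-bound and intended for desk-scale
  backbones; the production configuration builds and counts exactly but
  training it at corpus scale is out of scope here.
* Weight z-scores inherit the usual caveat that overlapping terms share
  credit: a hydrophobic signal may surface in counts rather than typed
  Gaussian terms, so single-term readings understate grouped effects.
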