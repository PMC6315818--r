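---
title: "Capped coarse-grained energies and neural-network decoy scoring"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Capped coarse-grained energies and neural-network decoy scoring}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(unresqa)
```

## The problem

Model quality assessment (MQA) asks: given a pool of candidate 3D models
("decoys") for one protein sequence, which are closest to the native
structure?  A physics-derived coarse-grained energy is a natural scorer,
but force fields tuned for free simulation assume relaxed structures;
fixed decoys contain steric clashes whose divergent repulsion swamps every
other term.  `unresqa` implements the whole chain of remedies: a capped
coarse-grained energy that scores clashed decoys gracefully, a
residue-type-resolved decomposition of that energy into 1296 features, an
ensemble of small feed-forward networks that re-learns the mapping from
those features to structural quality, and the ranking statistics used to
judge the result.

## The coarse-grained representation

Each residue is reduced to two interaction sites (`coarse_grain()`): the
united peptide group `p`, placed exactly halfway between consecutive Cα
atoms, and the united side chain `SC`, placed at the unweighted centroid
of the side-chain heavy atoms (the Cα itself for glycine).  Cα atoms
carry no interactions; they define the virtual-bond geometry
(`internal_geometry()`): bond lengths $d_i$, virtual bond angles
$\theta_i$, virtual dihedrals $\gamma_i$, side-chain orientation angles
$(\alpha_i, \beta_i)$ in a local backbone frame, and three
side-chain/backbone correlation dihedrals $\tau_i^{(m)}$.

Choices the literature leaves open, fixed here once:

* **Side-chain centroids are unweighted.** Mass weighting is an equally
  defensible convention; unweighted was chosen and is flagged to users.
* **Local frame** at residue $i$: $\hat x$ along
  $C\alpha_{i+1}-C\alpha_{i-1}$, $\hat z$ along
  $(C\alpha_{i-1}-C\alpha_i)\times(C\alpha_{i+1}-C\alpha_i)$, $\hat y$
  completing the right-handed set; $\alpha$ is the polar angle of the
  $C\alpha\to SC$ vector from $\hat z$, $\beta$ its azimuth.  Terminal
  residues and glycine have no defined orientation and are excluded from
  the rotamer term.
* **Correlation dihedrals**: $\tau^{(1)} = $ dih$(C\alpha_{i-1},
  C\alpha_i, SC_i, C\alpha_{i+1})$, $\tau^{(2)} = $ dih$(C\alpha_{i-2},
  C\alpha_{i-1}, C\alpha_i, SC_i)$, $\tau^{(3)} = $ dih$(SC_i, C\alpha_i,
  C\alpha_{i+1}, C\alpha_{i+2})$ — three distinct dihedrals coupling
  side-chain and backbone placement, undefined near the termini.
* Dihedral signs follow the IUPAC convention (`bio3d::torsion.xyz`
  agrees).
* MSE and SEC map to M and C; other nonstandard residues are rejected,
  because the 20-type pair decomposition requires standard types.

## The effective energy

`energy_evaluate()` computes a weighted sum of 15 term kinds: side-chain
pair interactions (6–12 well, pair-type-specific $\varepsilon,\sigma$,
asymmetric in sequence order), side-chain/peptide excluded volume
($r^{-12}$), peptide–peptide Lennard-Jones and point-dipole
electrostatics, torsional and double-torsional terms, virtual-bond-angle
bending, side-chain rotamer restraints, virtual-bond deformation around
3.8 Å, third- and fourth-order correlation terms, two turn terms (dipole
factors across windows of 3 and 4 peptide groups), a disulfide well for
close Cys–Cys pairs, and the $\tau$-based side-chain correlation term.
Terms that arise from order-$n$ cumulants of a restricted free energy
carry the temperature factor

$$f_n(T) = \frac{\ln(e + e^{-1})}{\ln\!\big(e^{x} + e^{-x}\big)},
  \qquad x = (T/T^\circ)^{n-1},$$

computed in log-sum-exp form so large $T$ cannot overflow; $f_n(T^\circ)
= 1$ and $f_n$ decreases strictly above the reference temperature
(default 300 K, where decoys are assumed folded).

Two design points matter most:

* **The repulsion cap.** Every pairwise nonbonded contribution is passed
  through $\min(u, c)$ with $c = 3$ kcal/mol *before* weighting.  This is
  what makes unminimized decoys scoreable: a clash saturates at the cap
  instead of dominating the total.  The cap is applied at the interaction
  level (each pair of interaction centers), to every term with a
  repulsive branch.
* **Functional forms are documented stand-ins.** The published
  coarse-grained force field defines its side-chain wells anisotropically
  (Gay–Berne) with parameter tables distributed outside the literature;
  this package deliberately uses spherical wells and compact closed
  forms, with a default parameter set generated deterministically from a
  fixed seed (well depths in 0.1–1.5 kcal/mol, contact distances 3–7 Å
  ordered by residue size).  Everything downstream — the decomposition,
  the reoptimization, the metrics — depends only on the term *structure*,
  which is preserved exactly.  `write_energy_params()` /
  `read_energy_params()` round-trip the set losslessly.

The rotamer azimuth deviation is wrapped at $\pm\pi$, so a branch flip of
`atan2` under coordinate rotation cannot change the energy; total energy
is rigid-motion invariant to $10^{-7}$ kcal/mol and exactly linear in the
weights.

## Features and scaling

`decompose_energy()` flattens a breakdown into 1296 entries in a frozen,
versioned order: the weighted total, 15 kind totals (stored unweighted
and without temperature factors — the network is meant to re-learn
effective weights), four type-resolved kinds at 20 entries each, and
three pair-resolved kinds at 400 entries each.  Pair cells are
*asymmetric*: `SCSC.AC` accumulates interactions where the alanine
precedes the cysteine in sequence, reflecting chain directionality.  An
MD5 of the name manifest is stored inside fitted models so a trained
ensemble rejects features in any other order.

`fit_scaler()` winsorizes each feature at its empirical 1st/99th
percentiles and z-scores the clamped values; constant features scale to
zero.  The scaler is fitted only on training rows (the training partition
of the first realization's split) and reused unchanged at prediction
time.

## TM-score and labels

`tm_score()` is a deterministic re-implementation of the standard
template-modeling score over Cα traces, with $d_0 = 1.24(L-15)^{1/3} -
1.8$ clamped at 0.5 Å and $L$ the reference length.  The maximization
uses the canonical heuristic: contiguous seed fragments of lengths $L$,
$L/2$, $L/4$ and 4 at stride $L/10$, each refined by Kabsch
superposition on the residues within $d_0$ until the included set is
stable; ties resolve to the first-found.  The heuristic is not exactly
symmetric in its arguments, so pairwise matrices average both
orientations.  Training labels are transformed as $TMS' = 1 - 2\,TMS$,
putting them on the bipolar output scale of the network with the energy
convention (lower is better, native $= -1$).

## The network ensemble

`unresqa()` fits `n_realizations` (default 6) feed-forward networks with
two hidden layers (defaults 6 and 7 nodes), bias nodes at every layer,
and the bipolar activation $g(z) = \tanh(a z)$ with $a = 0.2$ at every
node including the output.  Training is per-sample steepest-descent
backpropagation with momentum ($\mu = 0.003973$, $P = 0.4$), with the
training order reshuffled every epoch from the seeded stream.  Each
realization holds out 30% of *targets* (never splitting a target's
decoys) as an overfit-protection set; after every epoch the sum of
squared errors on that set is evaluated, the best-so-far weights are
kept (candidates start at the epoch-1 snapshot), and training stops
after 400 epochs without improvement or at 10000 epochs.  Prediction is
the arithmetic mean over realizations; the population standard deviation
across realizations is reported as a stability estimate.

Two questions the protocol leaves open were decided as follows:

* **Momentum** acts on the previous *total* update (the standard
  convention), not the previous raw gradient.
* **Update granularity** is per sample; per-epoch (batch) accumulation is
  available via `network_config(batch = TRUE)`.  In side-by-side runs on
  the synthetic sets, batch updates converged no better, so the
  shuffling-sensitive per-sample scheme remains the default.

## Ranking statistics

All metrics consume per-target tables of (model, real TMS, score), with
scores on the lower-is-better scale and the native row excluded from
score rankings (its predicted score would leak the label) but available
as the folding-path anchor:

* `top_k_mean_tms()` — mean real TMS of the $k$ best-scored models
  (ties by model id).
* `pearson_per_target()` — Pearson r between real and predicted TMS
  (back-transformed, so positive is good).
* `directional_accuracy()` (DA) — rank by real TMS, compare the mean
  score of ranks 1–5 against ranks 10–15 (six models, read inclusively);
  +1 if the top group is more favorable, −1 otherwise, exact ties +1.
  Because DA compares window *means*, it is invariant under affine but
  not arbitrary monotone score maps; DA2, PNA and top-k are rank- or
  pairwise-based and are fully monotone-invariant.
* `second_directional_accuracy()` (DA2) — rank by score, return the real
  TMS difference between ranks 1–5 and 10–15.
* `build_native_path()` — greedy chain from the native through all
  models, always stepping to the unused model of maximum TM-score
  ("nearest" means most similar; TMS is a similarity, not a distance);
  ties break by model id.  The path mean is the average consecutive-pair
  TMS, the span the TMS between native and the final model.
* `path_to_native_accuracy()` (PNA) — walk the path from its far end
  toward native, scoring +1 per step whose score does not increase
  toward native.

`aggregate_metric()` reports mean ± sample standard deviation over
targets (0 for a single target, by convention).

## The synthetic generator

`build_decoy_set()` emulates a CASP-style evaluation: per target one
native chain (seeded random sequence; idealized backbone of 3.8 Å
virtual bonds with helix/strand/coil segments at canonical virtual
angles; self-avoiding with nonadjacent Cα pairs ≥ 3.5 Å) plus a decoy
ladder.  Decoys are perturbed in *internal* coordinates — Gaussian noise
on dihedrals, 0.3× on angles, chain rebuilt — so they stay chain-like
the way server models are, rather than Cartesian noise clouds.  The
geometric sigma ladder (0.02–2.5 rad, frozen from
`scripts/calibrate_ladder.R`) spans labels from above 0.9 to below 0.3;
10% of decoys carry injected side-chain clashes (exercising the cap) and
one decoy is an exact duplicate (exercising tie handling).  All
coordinates are snapped to PDB precision before labels are computed, so
labels recomputed from the written files agree to machine precision, and
the whole tree is a deterministic function of the master seed.

What the generator does **not** emulate: real server-model error
correlations, native-like packing, sequence-dependent secondary
structure, or the difficulty distribution of real target sets.  Passing
tests on synthetic sets therefore demonstrates the correctness and
internal consistency of the machinery, not CASP-level accuracy.

## Problem sizes, and what desk-scale training shows

The test suite and examples run at deliberately small sizes: target sets
of 2–10 targets with 16–30 decoys of 30–60 residues, and ensembles of
2–6 networks.  The end-to-end recovery study uses 10 targets × 30 decoys
with labels constructed as a per-target monotone quantile map of the
capped total energy into [0.1, 0.9] — per-target because real TM-score
labels are also cohort-relative, and quantile because decoy energies are
strongly right-skewed (capped clashes, scrambled chains), so an even
label spacing keeps the DA/DA2 rank windows resolvable.

At this scale the binding constraint is per-network generalization: a
single realization has ~7800 first-layer weights against ~200 training
rows, so the overfit-protection set selects early epochs and each net
carries substantial target-level noise; the ensemble mean recovers
per-target correlations in the high 0.8s to low 0.9s and correct
directional calls on most targets, with seed-to-seed variability.  The
original protocol trained on hundreds of thousands of models, where this
constraint does not bind.  The architecture and training constants are
deliberately kept at their published values rather than re-tuned to the
small synthetic sets.

## Known limitations

* Spherical side-chain wells and generated default parameters: absolute
  energies are not comparable to any published force-field output.
* Single chains only; no mmCIF; hydrogens ignored.
* The TM-score heuristic can in principle return a slightly suboptimal
  superposition (bounded asymmetry ≤ 0.02 observed); exhaustive-seed
  references in the tests bound the gap at small sizes.
* No gradients/forces, minimization, or simulation capabilities: decoys
  are scored as fixed structures by design.
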