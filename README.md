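# unresqa

Coarse-grained energy decomposition and neural-network scoring for
protein model quality assessment (MQA).

Given a pool of candidate 3D models ("decoys") for one protein sequence,
which are closest to the native structure?  Physics-derived
coarse-grained energies are natural scorers, but force fields tuned for
free simulation assume relaxed structures — fixed decoys contain steric
clashes whose divergent repulsion swamps everything else.  `unresqa`
implements the full remedial chain, for structural bioinformaticians who
want a transparent, self-contained MQA pipeline:

1. **Two-site coarse-grained representation** — each residue reduced to a
   united peptide group `p` (midpoint of consecutive Cα) and a united
   side chain `SC` (centroid of side-chain heavy atoms), with virtual-bond
   geometry (d, θ, γ, α, β, τ⁽ᵐ⁾).
2. **Capped effective energy** — 15 term kinds
   (U<sub>SCSC</sub>, U<sub>SCp</sub>, U<sub>pp</sub><sup>VDW</sup>,
   U<sub>pp</sub><sup>el</sup>, U<sub>tor</sub>, U<sub>tord</sub>,
   U<sub>b</sub>, U<sub>rot</sub>, U<sub>bond</sub>, U<sub>corr(3)</sub>,
   U<sub>corr(4)</sub>, U<sub>turn(3)</sub>, U<sub>turn(4)</sub>,
   U<sub>ssbond</sub>, U<sub>SC-corr</sub>), order-n cumulant terms scaled
   by temperature factors
   f<sub>n</sub>(T) = ln(e+e⁻¹)/ln(e^x+e⁻^x), x = (T/T°)^(n−1),
   and — crucially — every pairwise repulsive contribution capped at
   3 kcal/mol so clashed decoys stay scoreable without minimization.
3. **1296-entry feature vector** — total energy + 15 kind totals +
   4×20 residue-type-resolved + 3×400 residue-pair-resolved components
   (asymmetric in chain order), winsorized at the 1st/99th percentiles
   and z-scored.
4. **TM-score machinery** — Kabsch superposition and the deterministic
   fragment-seeded TM-score heuristic (d₀ = 1.24(L−15)^⅓ − 1.8, ≥ 0.5 Å);
   labels transformed as TMS′ = 1 − 2·TMS so the native scores −1 and
   lower is better, matching the energy convention.
5. **Neural-network reoptimization** — `unresqa()` fits an ensemble of
   six feed-forward networks (hidden layers 6 and 7, bipolar activation
   tanh(0.2·z), per-sample steepest descent with momentum 0.4 and
   learning rate 0.003973), each with an independent 30 %-of-targets
   overfit-protection split and best-so-far weight selection; predictions
   are the ensemble mean ± spread.
6. **Ranking statistics** — top-5 mean TMS, per-target Pearson,
   directional accuracies DA and DA2 (rank windows 1–5 vs 10–15), and the
   greedy maximal-similarity folding path from the native with its
   path-to-native accuracy (PNA), mean and span.
7. **Synthetic CASP-style sets** — `build_decoy_set()` generates natives
   plus graded decoy ladders (internal-coordinate perturbations), clash
   decoys and duplicate decoys, with exactly reproducible TM-score labels,
   so the whole pipeline is testable without downloads.

## Worked example

```r
library(unresqa)

set <- build_decoy_set(n_targets = 3, decoys_per_target = 16, seed = 7)
#> Synthetic decoy set: 3 targets x 16 decoys (seed 7)
#> TM-score labels span 0.134 to 0.989

target <- character(0); model <- character(0); X <- NULL
for (tid in names(set$targets)) {
  F <- featurize_chains(set$targets[[tid]]$decoys)
  X <- rbind(X, F); target <- c(target, rep(tid, nrow(F)))
  model <- c(model, names(set$targets[[tid]]$decoys))
}

fit <- unresqa(X, set$labels$tms, target,
               config = network_config(n_realizations = 3, n_max = 2000),
               seed = 7)
#> Decoy-scoring ensemble: 3 networks (6+7 hidden nodes), 1296 input features
#> Fitted on 48 decoys over 3 targets (seed 7)

pr <- predict(fit, X)
head(data.frame(target, model, tms = round(set$labels$tms, 3),
                score = round(pr$score, 3), tms_pred = round(pr$tms, 3)), 3)
#>   target     model   tms  score tms_pred
#> 1   T001 model_001 0.945 -0.272    0.636
#> 2   T001 model_002 0.963 -0.268    0.634
#> 3   T001 model_003 0.901 -0.269    0.634

tabs <- lapply(unique(target), function(tid) {
  i <- target == tid
  target_table(tid, model[i], set$labels$tms[i], pr$score[i])
})
evaluate_scoring(tabs)
#> Model-quality-assessment report over 3 target(s)
#>     metric   mean    std
#>    top5tms 0.8580 0.0586
#>    pearson 0.9125 0.0126
#>         da 1.0000 0.0000
#>        da2 0.6047 0.0271
```

`top5tms` is the mean real TM-score of the five best-ranked decoys per
target; `pearson` the per-target correlation between real and predicted
TM-scores; `da`/`da2` the directional-accuracy statistics (+1 and
positive values mean the scorer orders the decoy windows correctly).
Here the ensemble ranks the graded decoy ladders essentially correctly
on all three targets.  `score` is on the transformed scale (lower =
better, native = −1); `tms_pred` is its back-transform.

A command-line mirror of the same pipeline ships as `exec/unresqa`:

```sh
unresqa simulate --out-dir sim --n-targets 3 --n-decoys 16 --seed 7
unresqa featurize --dir sim --out features.tsv
unresqa train --features features.tsv --labels sim/labels.tsv --out fit.model --seed 7
unresqa predict --model fit.model --features features.tsv --out pred.tsv
unresqa evaluate --predictions pred.tsv --labels sim/labels.tsv \
    --pdb-dir sim --out report.tsv --per-target per_target.tsv
```

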