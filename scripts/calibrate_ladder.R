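#!/usr/bin/env Rscript
# Calibration run behind the frozen perturbation-ladder bounds
# (LADDER_SIGMA in R/decoy_synth.R): mean TM-score of perturbed decoys as a
# function of the dihedral noise scale, for two representative chain
# lengths.  The bounds lo = 0.02 / hi = 2.5 were chosen from this curve so
# a geometric ladder spans labels from above 0.9 down to the scrambled
# regime below 0.3.

suppressPackageStartupMessages(library(unresqa))

sigmas <- c(0.02, 0.05, 0.1, 0.2, 0.4, 0.8, 1.5, 2.5)
for (len in c(40, 60)) {
  nat <- make_native(len, seed = 7)
  cat(sprintf("length %d\n", len))
  for (s in sigmas) {
    tms <- vapply(1:20, function(k)
      tm_score(perturb_chain(nat, s, seed = k), nat), 0)
    cat(sprintf("  sigma %5.2f  mean TMS %.3f\n", s, mean(tms)))
  }
}
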