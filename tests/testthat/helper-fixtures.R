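# in-code fixtures shared across tests

# minimal hand-written all-atom PDB: 3 residues (ALA, GLY with two altlocs,
# MSE), a second NMR model, and a HETATM water
write_fixture_pdb <- function(path) {
  writeLines(c(
    "MODEL        1",
    "ATOM      1  N   ALA A   1       0.000   0.000   0.000  1.00  0.00           N",
    "ATOM      2  CA  ALA A   1       1.000   0.000   0.000  1.00  0.00           C",
    "ATOM      3  C   ALA A   1       2.000   0.000   0.000  1.00  0.00           C",
    "ATOM      4  O   ALA A   1       2.500   1.000   0.000  1.00  0.00           O",
    "ATOM      5  CB  ALA A   1       1.000   1.500   0.000  1.00  0.00           C",
    "ATOM      6  CA AGLY A   2       4.000   0.000   0.000  0.40  0.00           C",
    "ATOM      7  CA BGLY A   2       4.100   0.000   0.000  0.60  0.00           C",
    "ATOM      8  CA  MSE A   3       7.000   1.000   0.000  1.00  0.00           C",
    "ATOM      9  SD  MSE A   3       7.500   2.000   1.000  1.00  0.00          SE",
    "ENDMDL",
    "MODEL        2",
    "ATOM     10  CA  ALA A   1       9.000   0.000   0.000  1.00  0.00           C",
    "ENDMDL",
    "TER",
    "HETATM   11  O   HOH A 101       9.000   9.000   9.000  1.00  0.00           O",
    "END"), path)
  path
}

# a seeded proper rotation matrix plus translation
random_rigid <- function(seed) {
  set.seed(seed)
  M <- matrix(rnorm(9), 3, 3)
  Q <- qr.Q(qr(M))
  if (det(Q) < 0) Q[, 1] <- -Q[, 1]
  list(R = Q, t = rnorm(3, sd = 10))
}

apply_rigid <- function(cg, rig) {
  cgchain(cg$sequence, cg$ca %*% rig$R + rep(rig$t, each = nrow(cg$ca)),
          cg$sc_sites %*% rig$R + rep(rig$t, each = nrow(cg$ca)),
          id = cg$id)
}

# poly-alanine chain on a fixed helix backbone
poly_ala_chain <- function(n = 20, seed = 3) {
  base <- make_native(n, seed = seed, ss = "helix")
  cgchain(rep("A", n), base$ca, base$sc_sites, id = "polyA")
}

# small params variant with uniform side-chain well parameters
uniform_sc_params <- function(eps = 1, sigma = 4) {
  p <- default_energy_params()
  p$eps[, ] <- eps
  p$sigma[, ] <- sigma
  p
}

# seeded random symmetric TM-score-like matrix with a native row
random_tm_matrix <- function(k, seed) {
  set.seed(seed)
  M <- matrix(runif(k * k, 0.05, 0.95), k, k)
  M[lower.tri(M)] <- t(M)[lower.tri(M)]
  diag(M) <- 1
  rownames(M) <- colnames(M) <- c("native", sprintf("m%02d", seq_len(k - 1)))
  M
}
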