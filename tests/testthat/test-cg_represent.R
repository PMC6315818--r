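test_that("parse_pdb reads the fixture: first model, waters out, altloc by occupancy", {
  pdb <- write_fixture_pdb(tempfile(fileext = ".pdb"))
  ch <- parse_pdb(pdb)
  expect_s3_class(ch, "aachain")
  expect_length(ch$sequence, 3L)              # model 1 only, water excluded
  expect_identical(ch$sequence, c("A", "G", "M"))  # MSE mapped to M
  # altloc resolved to the higher-occupancy copy (B, x = 4.1)
  gly_ca <- ch$atoms[ch$atoms$res == 2 & ch$atoms$name == "CA", ]
  expect_equal(gly_ca$x, 4.1)
})

test_that("parse_pdb rejects residues without CA and unknown residue types", {
  bad <- tempfile(fileext = ".pdb")
  writeLines(c(
    "ATOM      1  CA  ALA A   1       0.000   0.000   0.000  1.00  0.00           C",
    "ATOM      2  CB  ALA A   2       3.800   0.000   0.000  1.00  0.00           C",
    "ATOM      3  CA  ALA A   3       7.600   0.000   0.000  1.00  0.00           C",
    "END"), bad)
  expect_error(suppressWarnings(parse_pdb(bad)), "no CA")
  unk <- tempfile(fileext = ".pdb")
  writeLines(c(
    "ATOM      1  CA  XYZ A   1       0.000   0.000   0.000  1.00  0.00           C",
    "ATOM      2  CA  ALA A   2       3.800   0.000   0.000  1.00  0.00           C",
    "ATOM      3  CA  ALA A   3       7.600   0.000   0.000  1.00  0.00           C",
    "END"), unk)
  expect_error(suppressWarnings(parse_pdb(unk)), "nonstandard")
})

test_that("coarse_grain: p-site midpoints, single-atom and multi-atom centroids", {
  pdb <- write_fixture_pdb(tempfile(fileext = ".pdb"))
  cg <- coarse_grain(parse_pdb(pdb))
  # peptide site is the exact midpoint of consecutive Ca
  expect_equal(cg$p_sites[1, ], (cg$ca[1, ] + cg$ca[2, ]) / 2)
  # alanine with a single CB: centroid is that atom
  expect_equal(cg$sc_sites[1, ], c(1, 1.5, 0))
  # glycine: side-chain site equals Ca
  expect_equal(cg$sc_sites[2, ], cg$ca[2, ])
  # three-atom side chain: centroid is the arithmetic mean (oracle)
  val <- tempfile(fileext = ".pdb")
  writeLines(c(
    "ATOM      1  CA  VAL A   1       0.000   0.000   0.000  1.00  0.00           C",
    "ATOM      2  CB  VAL A   1       0.000   0.000   0.000  1.00  0.00           C",
    "ATOM      3  CG1 VAL A   1       3.000   0.000   0.000  1.00  0.00           C",
    "ATOM      4  CG2 VAL A   1       0.000   3.000   0.000  1.00  0.00           C",
    "ATOM      5  CA  ALA A   2       3.800   0.000   0.000  1.00  0.00           C",
    "ATOM      6  CB  ALA A   2       3.800   1.000   0.000  1.00  0.00           C",
    "ATOM      7  CA  ALA A   3       7.600   0.000   0.000  1.00  0.00           C",
    "ATOM      8  CB  ALA A   3       7.600   1.000   0.000  1.00  0.00           C",
    "END"), val)
  cgv <- coarse_grain(parse_pdb(val))
  expect_equal(cgv$sc_sites[1, ], colMeans(rbind(c(0, 0, 0), c(3, 0, 0), c(0, 3, 0))))
})

test_that("internal_geometry matches hand and bio3d dihedral oracles", {
  sq <- c("A", "A", "A", "A")
  ca_cis <- rbind(c(0, 0, 0), c(1, 0, 0), c(1, 1, 0), c(0, 1, 0))
  g <- internal_geometry(cgchain(sq, ca_cis))
  expect_equal(g$gamma[1], 0, tolerance = 1e-12)       # planar cis
  ca_90 <- rbind(c(0, 0, 0), c(1, 0, 0), c(1, 1, 0), c(1, 1, 1))
  g90 <- internal_geometry(cgchain(sq, ca_90))
  expect_equal(abs(g90$gamma[1]), pi / 2, tolerance = 1e-12)
  # collinear triple: straight angle
  ca_lin <- rbind(c(0, 0, 0), c(1, 0, 0), c(2, 0, 0), c(2, 1, 0))
  expect_equal(internal_geometry(cgchain(sq, ca_lin))$theta[1], pi,
               tolerance = 1e-12)
  # independent dihedral oracle on a random chain
  nat <- make_native(20, seed = 5)
  g2 <- internal_geometry(nat)
  tor <- bio3d::torsion.xyz(as.vector(t(nat$ca)), atm.inc = 1)
  expect_equal(g2$gamma, tor[is.finite(tor)] * pi / 180, tolerance = 1e-8)
  # degenerate coordinates are a hard error
  ca_dup <- rbind(c(0, 0, 0), c(0, 0, 0), c(1, 1, 0), c(2, 1, 0))
  expect_error(internal_geometry(cgchain(sq, ca_dup)), "identical")
})

test_that("internal geometry is rigid-motion invariant and mirror-covariant", {
  nat <- make_native(30, seed = 11)
  g <- internal_geometry(nat)
  for (s in 1:3) {
    g2 <- internal_geometry(apply_rigid(nat, random_rigid(s)))
    expect_equal(g2$d, g$d, tolerance = 1e-9)
    expect_equal(g2$theta, g$theta, tolerance = 1e-9)
    expect_equal(g2$gamma, g$gamma, tolerance = 1e-9)
    # wrap-aware comparison: a dihedral of exactly pi may come back as -pi
    expect_equal(sin(g2$tau), sin(g$tau), tolerance = 1e-9)
    expect_equal(cos(g2$tau), cos(g$tau), tolerance = 1e-9)
  }
  # mirroring flips the sign of every dihedral, preserves lengths and angles
  mir <- cgchain(nat$sequence, nat$ca %*% diag(c(1, 1, -1)),
                 nat$sc_sites %*% diag(c(1, 1, -1)))
  gm <- internal_geometry(mir)
  expect_equal(gm$d, g$d, tolerance = 1e-9)
  expect_equal(gm$theta, g$theta, tolerance = 1e-9)
  expect_equal(gm$gamma, -g$gamma, tolerance = 1e-9)
  expect_equal(sin(gm$tau), sin(-g$tau), tolerance = 1e-9)
  expect_equal(cos(gm$tau), cos(-g$tau), tolerance = 1e-9)
})

test_that("write_cg_pdb round-trips to PDB precision and honors the dialect", {
  nat <- make_native(25, seed = 2)
  f <- tempfile(fileext = ".pdb")
  write_cg_pdb(nat, f)
  back <- read_cg_pdb(f)
  expect_identical(back$sequence, nat$sequence)
  expect_lt(max(abs(back$ca - nat$ca)), 5e-4)
  expect_lt(max(abs(back$sc_sites - nat$sc_sites)), 5e-4)
  # p-site midpoint identity holds exactly on the re-parsed chain
  expect_equal(back$p_sites,
               (back$ca[-nrow(back$ca), ] + back$ca[-1, ]) / 2)
  # glycine-only chain emits no CM pseudo-atoms
  gly <- cgchain(rep("G", 5), make_native(5 + 11, seed = 1)$ca[1:5, ])
  f2 <- tempfile(fileext = ".pdb")
  write_cg_pdb(gly, f2)
  expect_false(any(grepl(" CM ", readLines(f2))))
  # chains below 3 residues are invalid by construction
  expect_error(cgchain("A", matrix(0, 1, 3)), "at least 3")
})
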