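# Structure input and the two-site-per-residue coarse-grained representation.
#
# Each residue is reduced to two interaction sites: a united peptide group (p)
# halfway between consecutive Ca atoms, and a united side chain (SC) at the
# unweighted centroid of the side-chain heavy atoms (the Ca itself for
# glycine).  Ca atoms carry the geometry only.

NONSTD_MAP <- c(MSE = "M", SEC = "C")

#' Parse a PDB file into an all-atom chain
#'
#' Reads ATOM records of one protein chain.  Only the first model of a
#' multi-model (e.g. NMR) file is used; alternate locations are resolved to
#' the highest-occupancy copy; waters and other HETATM records are excluded.
#' Selenomethionine (MSE) and selenocysteine (SEC) are mapped to M and C;
#' any other nonstandard residue type is an error.
#'
#' @param path path to a PDB-format file.
#' @param chain chain identifier to select; default the first chain present.
#' @return an object of class `aachain`: a list with `sequence` (one-letter
#'   codes), `atoms` (data.frame with `res`, `type`, `name`, `element`,
#'   `x`, `y`, `z`) and `chain_id`.
#' @export
parse_pdb <- function(path, chain = NULL) {
  stopifnot(file.exists(path))
  pdb <- suppressWarnings(bio3d::read.pdb(path, multi = FALSE, rm.alt = FALSE,
                                          verbose = FALSE))
  at <- pdb$atom
  at <- at[at$type == "ATOM", , drop = FALSE]
  if (nrow(at) == 0L) stop("no ATOM records in ", path)
  if (is.null(chain)) chain <- at$chain[1L]
  at <- at[at$chain %in% chain, , drop = FALSE]
  if (nrow(at) == 0L) stop("chain '", chain, "' not found in ", path)

  # resolve alternate locations: keep the highest-occupancy copy of each atom
  if (any(!is.na(at$alt))) {
    key <- paste(at$resno, at$insert, at$elety)
    keep <- unlist(lapply(split(seq_len(nrow(at)), key), function(i) {
      o <- at$o[i]
      o[is.na(o)] <- 1
      i[which.max(o)]
    }), use.names = FALSE)
    at <- at[sort(keep), , drop = FALSE]
  }

  res_key <- paste(at$resno, at$insert %||% "")
  res_split <- split(seq_len(nrow(at)), factor(res_key, levels = unique(res_key)))
  seq1 <- character(length(res_split))
  rows <- vector("list", length(res_split))
  for (k in seq_along(res_split)) {
    i <- res_split[[k]]
    resid3 <- at$resid[i[1L]]
    one <- if (resid3 %in% names(NONSTD_MAP)) NONSTD_MAP[[resid3]]
           else bio3d::aa321(resid3)
    if (!(one %in% AA20))
      stop("nonstandard residue '", resid3, "' at position ", k,
           " (resno ", at$resno[i[1L]], ")")
    if (!any(at$elety[i] == "CA"))
      stop("residue ", resid3, " ", at$resno[i[1L]], " has no CA atom")
    seq1[k] <- one
    rows[[k]] <- data.frame(
      res = k, type = one, name = at$elety[i],
      element = at$elesy[i] %||% NA_character_,
      x = at$x[i], y = at$y[i], z = at$z[i],
      stringsAsFactors = FALSE)
  }
  atoms <- do.call(rbind, rows)
  if (length(seq1) < 3L) stop("chain has fewer than 3 residues")
  structure(list(sequence = seq1, atoms = atoms, chain_id = chain),
            class = "aachain")
}

#' Construct a coarse-grained chain
#'
#' Builds a `cgchain` from a sequence, Ca coordinates and side-chain sites.
#' Peptide-group sites are always derived as exact midpoints of consecutive
#' Ca atoms, so the midpoint invariant holds by construction.
#'
#' @param sequence character vector of one-letter residue types (length N >= 3).
#' @param ca N x 3 matrix of Ca coordinates (Angstrom).
#' @param sc_sites N x 3 matrix of side-chain centroids; for glycine rows the
#'   site must equal the Ca position (enforced).
#' @param id optional chain/target identifier.
#' @return object of class `cgchain` with fields `sequence`, `ca`, `p_sites`
#'   ((N-1) x 3), `sc_sites`, `id`.
#' @export
cgchain <- function(sequence, ca, sc_sites = NULL, id = "chain") {
  sequence <- as.character(sequence)
  n <- length(sequence)
  if (n < 3L) stop("a coarse-grained chain needs at least 3 residues")
  if (!all(sequence %in% AA20)) stop("sequence contains nonstandard types")
  ca <- as.matrix(ca); storage.mode(ca) <- "double"
  stopifnot(nrow(ca) == n, ncol(ca) == 3L, all(is.finite(ca)))
  if (is.null(sc_sites)) sc_sites <- ca
  sc_sites <- as.matrix(sc_sites); storage.mode(sc_sites) <- "double"
  stopifnot(nrow(sc_sites) == n, ncol(sc_sites) == 3L, all(is.finite(sc_sites)))
  gly <- sequence == "G"
  sc_sites[gly, ] <- ca[gly, ]
  p <- (ca[-n, , drop = FALSE] + ca[-1L, , drop = FALSE]) / 2
  structure(list(sequence = sequence, ca = ca, p_sites = p,
                 sc_sites = sc_sites, id = id),
            class = "cgchain")
}

#' @export
print.cgchain <- function(x, ...) {
  cat("Coarse-grained chain '", x$id, "': ", length(x$sequence),
      " residues\n", sep = "")
  cat("  sequence: ", paste(x$sequence, collapse = ""), "\n", sep = "")
  invisible(x)
}

#' Coarse-grain an all-atom chain
#'
#' Reduces each residue to the Ca position plus a united side-chain site at
#' the unweighted centroid of its side-chain heavy atoms (every atom except
#' backbone N, CA, C, O; hydrogens are not expected in the input).  Glycine
#' gets its Ca position; a non-glycine residue with no side-chain heavy atoms
#' is treated glycine-like with a warning.
#'
#' @param chain an `aachain` from [parse_pdb()].
#' @return a [cgchain()].
#' @export
coarse_grain <- function(chain) {
  stopifnot(inherits(chain, "aachain"))
  at <- chain$atoms
  n <- length(chain$sequence)
  ca <- matrix(NA_real_, n, 3L)
  sc <- matrix(NA_real_, n, 3L)
  backbone <- c("N", "CA", "C", "O", "OXT")
  for (k in seq_len(n)) {
    rows <- at[at$res == k, , drop = FALSE]
    cai <- which(rows$name == "CA")[1L]
    ca[k, ] <- c(rows$x[cai], rows$y[cai], rows$z[cai])
    side <- rows[!(rows$name %in% backbone) &
                 !(rows$element %in% "H") &
                 !grepl("^H", rows$name), , drop = FALSE]
    if (chain$sequence[k] == "G" || nrow(side) == 0L) {
      if (chain$sequence[k] != "G")
        warning("residue ", chain$sequence[k], k,
                " has no side-chain heavy atoms; treated glycine-like")
      sc[k, ] <- ca[k, ]
    } else {
      sc[k, ] <- colMeans(side[, c("x", "y", "z")])
    }
  }
  cgchain(chain$sequence, ca, sc, id = chain$chain_id)
}

vcross <- function(a, b) {
  c(a[2L] * b[3L] - a[3L] * b[2L],
    a[3L] * b[1L] - a[1L] * b[3L],
    a[1L] * b[2L] - a[2L] * b[1L])
}

vangle <- function(a, b) {
  # numerically stable angle between two vectors
  atan2(sqrt(sum(vcross(a, b)^2)), sum(a * b))
}

dihedral4 <- function(p1, p2, p3, p4) {
  # signed torsion, IUPAC sign convention (agrees with bio3d::torsion.xyz)
  b1 <- p2 - p1; b2 <- p3 - p2; b3 <- p4 - p3
  n1 <- vcross(b1, b2); n2 <- vcross(b2, b3)
  m1 <- vcross(n1, b2 / sqrt(sum(b2^2)))
  -atan2(sum(m1 * n2), sum(n1 * n2))
}

#' Internal geometry of a coarse-grained chain
#'
#' Computes the virtual-bond geometry: Ca-Ca distances `d`, virtual bond
#' angles `theta`, virtual dihedrals `gamma`, the side-chain orientation
#' angles `alpha` (polar) and `beta` (azimuth) in a local backbone frame,
#' and for each residue the three side-chain/backbone correlation dihedrals
#' `tau` (columns m = 1..3).
#'
#' The local frame at residue i has x along `ca[i+1] - ca[i-1]`, z along
#' `(ca[i-1]-ca[i]) x (ca[i+1]-ca[i])` and y completing a right-handed set;
#' `alpha` is the polar angle of the Ca->SC vector from z and `beta` its
#' azimuth in the xy plane.  Terminal residues (no frame) and glycine (zero
#' Ca->SC vector) get `alpha = beta = 0` and are flagged in `rot_defined`.
#' The correlation dihedrals are
#' tau1 = dih(ca\[i-1\], ca\[i\], sc\[i\], ca\[i+1\]),
#' tau2 = dih(ca\[i-2\], ca\[i-1\], ca\[i\], sc\[i\]),
#' tau3 = dih(sc\[i\], ca\[i\], ca\[i+1\], ca\[i+2\]); entries undefined near the
#' termini (or for glycine) are `NA`.
#'
#' @param cg a [cgchain()]; N >= 3 (N >= 4 for dihedrals).
#' @return object of class `cggeom`: list with `d` (N-1), `theta` (N-2,
#'   residues 2..N-1), `gamma` (N-3, dihedral i spans ca i-1..i+2 for
#'   i = 2..N-2), `alpha`, `beta` (length N), `rot_defined` (logical N),
#'   `tau` (N x 3).
#' @export
internal_geometry <- function(cg) {
  stopifnot(inherits(cg, "cgchain"))
  ca <- cg$ca; sc <- cg$sc_sites
  n <- nrow(ca)
  dvec <- ca[-1L, , drop = FALSE] - ca[-n, , drop = FALSE]
  d <- sqrt(rowSums(dvec^2))
  if (any(d < 1e-9)) stop("consecutive identical Ca coordinates: angle undefined")

  theta <- vapply(2:(n - 1L), function(i)
    vangle(ca[i - 1L, ] - ca[i, ], ca[i + 1L, ] - ca[i, ]), 0)

  gamma <- if (n >= 4L)
    vapply(2:(n - 2L), function(i)
      dihedral4(ca[i - 1L, ], ca[i, ], ca[i + 1L, ], ca[i + 2L, ]), 0)
  else numeric(0)

  alpha <- numeric(n); beta <- numeric(n)
  rot_defined <- rep(FALSE, n)
  for (i in 2:(n - 1L)) {
    v <- sc[i, ] - ca[i, ]
    if (sqrt(sum(v^2)) < 1e-9) next   # glycine or degenerate
    xhat <- ca[i + 1L, ] - ca[i - 1L, ]
    zhat <- vcross(ca[i - 1L, ] - ca[i, ], ca[i + 1L, ] - ca[i, ])
    nx <- sqrt(sum(xhat^2)); nz <- sqrt(sum(zhat^2))
    if (nx < 1e-9 || nz < 1e-9) next  # collinear backbone, frame undefined
    xhat <- xhat / nx; zhat <- zhat / nz
    yhat <- vcross(zhat, xhat)
    alpha[i] <- vangle(v, zhat)
    beta[i] <- atan2(sum(v * yhat), sum(v * xhat))
    rot_defined[i] <- TRUE
  }

  tau <- matrix(NA_real_, n, 3L)
  for (i in seq_len(n)) {
    if (sqrt(sum((sc[i, ] - ca[i, ])^2)) < 1e-9) next  # glycine: undefined
    if (i >= 2L && i <= n - 1L)
      tau[i, 1L] <- dihedral4(ca[i - 1L, ], ca[i, ], sc[i, ], ca[i + 1L, ])
    if (i >= 3L)
      tau[i, 2L] <- dihedral4(ca[i - 2L, ], ca[i - 1L, ], ca[i, ], sc[i, ])
    if (i <= n - 2L)
      tau[i, 3L] <- dihedral4(sc[i, ], ca[i, ], ca[i + 1L, ], ca[i + 2L, ])
  }

  structure(list(d = d, theta = theta, gamma = gamma, alpha = alpha,
                 beta = beta, rot_defined = rot_defined, tau = tau),
            class = "cggeom")
}

#' Write a coarse-grained chain as a PDB file
#'
#' Emits one CA record per residue plus one pseudo-atom record named `CM`
#' carrying the side-chain centroid for every non-glycine residue.  The
#' occupancy column stores the residue index (sanity check for round trips).
#' `coarse_grain(parse_pdb(path))` of the output reproduces the chain to PDB
#' fixed-point precision (3 decimals).
#'
#' @param cg a [cgchain()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_cg_pdb <- function(cg, path) {
  stopifnot(inherits(cg, "cgchain"))
  n <- length(cg$sequence)
  con <- file(path, "w")
  on.exit(close(con))
  eleno <- 0L
  fmt <- "ATOM  %5d %-4s%1s%3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s"
  for (i in seq_len(n)) {
    res3 <- bio3d::aa123(cg$sequence[i])
    occ <- min(i %% 100, 99)  # occupancy column reused as index check
    eleno <- eleno + 1L
    writeLines(sprintf(fmt, eleno, " CA ", "", res3, "A", i, "",
                       cg$ca[i, 1L], cg$ca[i, 2L], cg$ca[i, 3L], occ, 0, "C"),
               con)
    if (cg$sequence[i] != "G") {
      eleno <- eleno + 1L
      writeLines(sprintf(fmt, eleno, " CM ", "", res3, "A", i, "",
                         cg$sc_sites[i, 1L], cg$sc_sites[i, 2L],
                         cg$sc_sites[i, 3L], occ, 0, "C"),
                 con)
    }
  }
  writeLines(c("TER", "END"), con)
  invisible(path)
}

#' Read a coarse-grained PDB file
#'
#' Convenience composition `coarse_grain(parse_pdb(path))`; works both on
#' files written by [write_cg_pdb()] and on ordinary all-atom PDB files.
#'
#' @inheritParams parse_pdb
#' @return a [cgchain()].
#' @export
read_cg_pdb <- function(path, chain = NULL) coarse_grain(parse_pdb(path, chain))
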