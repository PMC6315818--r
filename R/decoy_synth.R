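# Synthetic CASP-like target sets: one native per target plus a graded decoy
# ladder with known TM-scores, including clash decoys (to exercise the
# repulsion cap) and a duplicate decoy (to exercise tie handling).
#
# Decoys are perturbed in internal coordinates (dihedral/angle noise, chain
# rebuilt), not in Cartesian space, so they remain chain-like the way server
# models are -- rather than noise clouds.

# canonical Ca-trace internal coordinates (rad)
SS_THETA <- c(helix = 1.59, strand = 2.13)
SS_GAMMA <- c(helix = 0.87, strand = -2.98)
CA_BOND <- 3.8

# perturbation ladder bounds (rad), calibrated once with
# scripts/calibrate_ladder.R and frozen: sigma near the low end leaves
# TM-scores above 0.9, the high end scrambles chains below 0.3
LADDER_SIGMA <- c(lo = 0.02, hi = 2.5)

# rebuild Cartesian Ca coordinates from internal coordinates (NeRF chain)
build_backbone <- function(d, theta, gamma) {
  n <- length(d) + 1L
  ca <- matrix(0, n, 3L)
  ca[2L, ] <- c(d[1L], 0, 0)
  ca[3L, ] <- ca[2L, ] + d[2L] * c(-cos(theta[1L]), sin(theta[1L]), 0)
  if (n >= 4L) for (i in 4:n) {
    A <- ca[i - 3L, ]; B <- ca[i - 2L, ]; C <- ca[i - 1L, ]
    th <- theta[i - 2L]      # angle at residue i-1
    ph <- gamma[i - 3L]      # dihedral spanning residues i-3 .. i
    bc <- C - B; bc <- bc / sqrt(sum(bc^2))
    nv <- vcross(B - A, bc)
    nv <- nv / sqrt(sum(nv^2))
    mv <- vcross(nv, bc)
    d2 <- d[i - 1L] * c(-cos(th), sin(th) * cos(ph), sin(th) * sin(ph))
    ca[i, ] <- C + d2[1L] * bc + d2[2L] * mv + d2[3L] * nv
  }
  ca
}

# residue-type-specific Ca->SC distance (A), from side-chain size
sc_distance <- function(type) 1.0 + 0.25 * SC_SIZE[type]

# deterministic side-chain placement from the backbone alone
place_sc <- function(sequence, ca) {
  n <- nrow(ca)
  sc <- ca
  dist <- sc_distance(sequence)
  for (i in seq_len(n)) {
    if (sequence[i] == "G") next
    if (i == 1L || i == n) {
      b <- if (i == 1L) ca[2L, ] - ca[1L, ] else ca[n - 1L, ] - ca[n, ]
      b <- b / sqrt(sum(b^2))
      u <- vcross(b, c(0, 0, 1))
      if (sqrt(sum(u^2)) < 1e-6) u <- vcross(b, c(0, 1, 0))
      u <- u / sqrt(sum(u^2))
    } else {
      xhat <- ca[i + 1L, ] - ca[i - 1L, ]
      zhat <- vcross(ca[i - 1L, ] - ca[i, ], ca[i + 1L, ] - ca[i, ])
      nx <- sqrt(sum(xhat^2)); nz <- sqrt(sum(zhat^2))
      if (nz < 1e-6) { sc[i, ] <- ca[i, ]; next }   # collinear: leave at Ca
      u <- -0.4 * (xhat / nx) + 0.9 * (zhat / nz)
      u <- u / sqrt(sum(u^2))
    }
    sc[i, ] <- ca[i, ] + dist[i] * u
  }
  sc
}

min_nonadjacent_ca <- function(ca) {
  D <- pair_dist(ca, ca)
  n <- nrow(ca)
  mask <- abs(row(D) - col(D)) > 1L
  min(D[mask])
}

#' Generate a synthetic native chain
#'
#' Seeded random sequence over the 20 standard types and a backbone built
#' from idealized internal coordinates: Ca-Ca bonds of exactly 3.8 A and
#' secondary-structure segments with canonical virtual angles/dihedrals
#' (helix, strand, or random coil) plus small jitter.  Side-chain centroids
#' sit at residue-type-specific distances along the local backbone frame.
#' The chain is rebuilt (up to `max_tries` draws) until self-avoiding: no
#' nonadjacent Ca pair closer than 3.5 A.
#'
#' @param length number of residues (16-ish to a few hundred; >= 16 so
#'   TM-scores against it are defined).
#' @param seed integer seed.
#' @param ss `"mixed"` (random helix/strand/coil segments, default),
#'   `"helix"` or `"strand"`.
#' @param id target identifier.
#' @param max_tries rebuild attempts before giving up.
#' @return a [cgchain()].
#' @export
make_native <- function(length, seed = 1L, ss = c("mixed", "helix", "strand"),
                        id = "native", max_tries = 100L) {
  ss <- match.arg(ss)
  if (length < 16L) stop("native chains need length >= 16")
  n <- as.integer(length)
  for (attempt in seq_len(max_tries)) {
    chain <- with_private_seed(derive_seed(seed, paste0("native", attempt)), {
      sequence <- sample(AA20, n, replace = TRUE)
      theta <- numeric(n - 2L); gamma <- numeric(max(n - 3L, 0L))
      i <- 1L
      while (i <= n - 2L) {
        seg_ss <- if (ss == "mixed")
          sample(c("helix", "strand", "coil"), 1L, prob = c(0.4, 0.3, 0.3))
        else ss
        seg_len <- min(sample(5:15, 1L), n - 2L - i + 1L)
        idx <- i:(i + seg_len - 1L)
        if (seg_ss == "coil") {
          theta[idx] <- runif(seg_len, 1.4, 2.4)
          gidx <- idx[idx <= n - 3L]
          gamma[gidx] <- runif(length(gidx), -pi, pi)
        } else {
          theta[idx] <- SS_THETA[seg_ss] + runif(seg_len, -0.05, 0.05)
          gidx <- idx[idx <= n - 3L]
          gamma[gidx] <- SS_GAMMA[seg_ss] + runif(length(gidx), -0.05, 0.05)
        }
        i <- i + seg_len
      }
      ca <- build_backbone(rep(CA_BOND, n - 1L), theta, gamma)
      cgchain(sequence, ca, place_sc(sequence, ca), id = id)
    })
    if (min_nonadjacent_ca(chain$ca) >= 3.5) return(chain)
  }
  stop("could not build a self-avoiding chain of length ", length,
       " in ", max_tries, " tries; try a shorter length")
}

#' Perturb a chain in internal coordinates
#'
#' Adds Gaussian noise of scale `sigma` to every virtual dihedral (and
#' `0.3 sigma` to every virtual bond angle, clamped to a valid range),
#' rebuilds the backbone from the perturbed internal coordinates with bond
#' lengths preserved, and replaces the side chains by the deterministic
#' placement rule.  `sigma = 0` returns the input unchanged.
#'
#' @param native a [cgchain()].
#' @param sigma dihedral noise scale in radians (>= 0).
#' @param seed integer seed.
#' @param id decoy identifier.
#' @return a perturbed [cgchain()] with the same sequence and length.
#' @export
perturb_chain <- function(native, sigma, seed = 1L, id = "decoy") {
  stopifnot(inherits(native, "cgchain"), sigma >= 0)
  if (sigma == 0) {
    out <- native; out$id <- id
    return(out)
  }
  geom <- internal_geometry(native)
  with_private_seed(seed, {
    theta <- pmin(pmax(geom$theta + rnorm(length(geom$theta), 0, 0.3 * sigma),
                       0.3), pi - 0.05)
    gamma <- geom$gamma + rnorm(length(geom$gamma), 0, sigma)
    ca <- build_backbone(geom$d, theta, gamma)
    cgchain(native$sequence, ca, place_sc(native$sequence, ca), id = id)
  })
}

#' Inject steric clashes into a decoy
#'
#' Moves `n_clashes` randomly chosen non-glycine side-chain sites to within
#' 0.5 A of another side-chain site, guaranteeing at least one pair whose
#' uncapped excluded-volume repulsion exceeds the cap by orders of
#' magnitude.
#'
#' @param chain a [cgchain()].
#' @param n_clashes number of side chains to relocate (>= 1).
#' @param seed integer seed.
#' @param id decoy identifier.
#' @return a clashed [cgchain()].
#' @export
make_clashed <- function(chain, n_clashes = 1L, seed = 1L, id = "clash") {
  stopifnot(inherits(chain, "cgchain"))
  if (n_clashes < 1L) stop("n_clashes must be >= 1")
  with_private_seed(seed, {
    sc <- chain$sc_sites
    nong <- which(chain$sequence != "G")
    if (length(nong) < 2L) stop("need at least two non-glycine residues")
    movers <- sample(nong, min(n_clashes, length(nong) - 1L))
    for (i in movers) {
      j <- sample(setdiff(nong, i), 1L)
      u <- rnorm(3); u <- u / sqrt(sum(u^2))
      sc[i, ] <- sc[j, ] + 0.2 * u   # well inside the 0.5 A clash radius
    }
    cgchain(chain$sequence, chain$ca, sc, id = id)
  })
}

round_coords <- function(cg) {
  # snap to PDB fixed-point precision so in-memory and written chains agree
  cgchain(cg$sequence, round(cg$ca, 3), round(cg$sc_sites, 3), id = cg$id)
}

#' Build a synthetic CASP-like target set
#'
#' For each target: a native chain plus `decoys_per_target` decoys -- a
#' geometric perturbation ladder spanning TM-scores from near 1 down to the
#' scrambled regime, 10% clash decoys and one exact duplicate decoy.
#' Coordinates are snapped to PDB precision (3 decimals) before labels are
#' computed, so labels recomputed from written files agree to machine
#' precision.  When `dir` is given, the set is written as
#' `targets/<id>/native.pdb` + `model_###.pdb` plus a `labels.tsv`.
#'
#' @param n_targets number of targets (>= 1).
#' @param decoys_per_target decoys per target (>= 16, metric preconditions).
#' @param seed master integer seed; the whole set is a deterministic
#'   function of it.
#' @param dir optional output directory for the PDB tree and label TSV.
#' @param length_range inclusive range of chain lengths to draw from.
#' @return object of class `synth_target_set`: list with `targets` (named
#'   list of `list(native, decoys, labels)`), `labels` (data.frame of
#'   target, model, tms), `seed`, and `dir` if written.
#' @export
build_decoy_set <- function(n_targets = 10L, decoys_per_target = 30L,
                            seed = 1L, dir = NULL,
                            length_range = c(30L, 60L)) {
  stopifnot(n_targets >= 1L, decoys_per_target >= 16L)
  n_clash <- max(1L, floor(0.1 * decoys_per_target))
  n_ladder <- decoys_per_target - n_clash - 1L   # one duplicate reserved
  sigmas <- exp(seq(log(LADDER_SIGMA["lo"]), log(LADDER_SIGMA["hi"]),
                    length.out = n_ladder))
  targets <- list()
  label_rows <- list()
  for (t in seq_len(n_targets)) {
    tid <- sprintf("T%03d", t)
    tseed <- derive_seed(seed, tid)
    len <- with_private_seed(derive_seed(tseed, "len"),
                             sample(length_range[1L]:length_range[2L], 1L))
    native <- round_coords(make_native(len, seed = tseed, id = tid))
    decoys <- vector("list", decoys_per_target)
    k <- 0L
    for (s in sigmas) {
      k <- k + 1L
      decoys[[k]] <- round_coords(
        perturb_chain(native, s, seed = derive_seed(tseed, paste0("d", k)),
                      id = sprintf("model_%03d", k)))
    }
    # clash decoys: mid-ladder geometry with relocated side chains
    for (c in seq_len(n_clash)) {
      k <- k + 1L
      base <- decoys[[max(1L, n_ladder %/% 2L)]]
      decoys[[k]] <- round_coords(
        make_clashed(base, n_clashes = 2L,
                     seed = derive_seed(tseed, paste0("clash", c)),
                     id = sprintf("model_%03d", k)))
    }
    # exact duplicate of the best ladder decoy (tie handling downstream)
    k <- k + 1L
    dup <- decoys[[1L]]
    dup$id <- sprintf("model_%03d", k)
    decoys[[k]] <- dup
    labels <- vapply(decoys, function(d) tm_score(d, native), 0)
    names(decoys) <- vapply(decoys, `[[`, "", "id")
    targets[[tid]] <- list(native = native, decoys = decoys, labels = labels)
    label_rows[[tid]] <- data.frame(target = tid, model = names(decoys),
                                    tms = labels, row.names = NULL)
  }
  labels_df <- do.call(rbind, c(label_rows, list(make.row.names = FALSE)))
  out <- structure(list(targets = targets, labels = labels_df, seed = seed),
                   class = "synth_target_set")
  if (!is.null(dir)) {
    for (tid in names(targets)) {
      td <- file.path(dir, "targets", tid)
      dir.create(td, recursive = TRUE, showWarnings = FALSE)
      write_cg_pdb(targets[[tid]]$native, file.path(td, "native.pdb"))
      for (d in targets[[tid]]$decoys)
        write_cg_pdb(d, file.path(td, paste0(d$id, ".pdb")))
    }
    write.table(data.frame(labels_df[1:2], tms = sprintf("%.6f", labels_df$tms)),
                file.path(dir, "labels.tsv"), sep = "\t", quote = FALSE,
                row.names = FALSE)
    out$dir <- dir
  }
  out
}

#' @export
print.synth_target_set <- function(x, ...) {
  cat("Synthetic decoy set:", length(x$targets), "targets x",
      length(x$targets[[1L]]$decoys), "decoys (seed", x$seed, ")\n")
  rng <- range(x$labels$tms)
  cat("TM-score labels span", round(rng[1L], 3), "to", round(rng[2L], 3), "\n")
  invisible(x)
}

#' Energy-linked synthetic TM-score labels
#'
#' Maps a cohort of total energies to TM-scores through the monotone
#' decreasing quantile transform: the lowest energy maps to `hi`, the
#' highest to `lo`, intermediate energies to evenly spaced intermediate
#' values (ties, e.g. duplicate decoys, share a label).  Used to build
#' study sets in which the transformed label is a monotone function of the
#' total energy by construction, so an ensemble that recovers the
#' energy-label link can be recognized by a high held-out correlation.
#' The quantile transform is chosen over value-proportional maps because
#' decoy energies are strongly right-skewed (capped clashes, scrambled
#' chains): an even label spacing keeps every rank window of the ranking
#' statistics resolvable instead of collapsing the near-native end.
#'
#' @param energies numeric vector of total energies (one target's decoys).
#' @param lo,hi bounds of the produced TM-scores.
#' @return TM-scores in `[lo, hi]`, monotone decreasing in energy.
#' @export
energy_linked_tms <- function(energies, lo = 0.1, hi = 0.9) {
  n <- length(energies)
  if (n == 1L) return((lo + hi) / 2)
  r <- rank(energies, ties.method = "average")
  lo + (hi - lo) * (n - r) / (n - 1)
}
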