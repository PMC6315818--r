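# Capped coarse-grained effective energy, resolved per interaction so it can
# be decomposed into residue-type-specific features.
#
# The effective energy is a weighted sum of 15 term kinds over the two-site
# representation.  Because the energy originates from a restricted free
# energy in which fast degrees of freedom were averaged out, cumulant terms
# of order n carry a temperature factor f_n(T) equal to 1 at the reference
# temperature.  Every pairwise nonbonded contribution is capped from above
# (default 3 kcal/mol) before weighting, so decoys with steric clashes can
# be scored without prior minimization.

#' Temperature factor of order-n cumulant terms
#'
#' `f_n(T) = ln(e + 1/e) / ln(exp(x) + exp(-x))` with `x = (T/T0)^(n-1)`,
#' evaluated in log-sum-exp form so large `T` does not overflow.  Equals 1
#' at `T = T0` and decreases strictly for `T > T0`.
#'
#' @param T temperature in kelvin (> 0).
#' @param T0 reference temperature in kelvin (default 300).
#' @param n cumulant order, integer >= 2.
#' @return dimensionless factor in (0, 1].
#' @export
temperature_factor <- function(T, T0 = 300, n) {
  stopifnot(T > 0, T0 > 0)
  if (n < 2) stop("temperature factors apply to cumulant orders n >= 2")
  x <- (T / T0)^(n - 1)
  # ln(exp(x) + exp(-x)) = x + log1p(exp(-2x)), safe for large x
  lcosh2 <- function(x) x + log1p(exp(-2 * x))
  lcosh2(1) / lcosh2(x)
}

#' Cap a repulsive pairwise contribution
#'
#' `min(u, cap)`, applied to each unweighted pairwise nonbonded contribution
#' before the term weights multiply it.  Attractive values pass unchanged.
#'
#' @param u pairwise energy (kcal/mol); vectorized.
#' @param cap positive ceiling (kcal/mol, default 3).
#' @return capped energy.
#' @export
cap_repulsion <- function(u, cap = 3) {
  stopifnot(cap > 0)
  pmin(u, cap)
}

# map of term kind -> temperature-factor order (NA = no factor)
KIND_FN <- c(SCSC = NA, SCp = NA, ppVDW = NA, ppel = 2, tor = 2, tord = 3,
             b = NA, rot = NA, bond = NA, corr3 = 3, corr4 = 4, turn3 = 3,
             turn4 = 4, ssbond = NA, SCcorr = 2)

kind_factors <- function(temperature, T0) {
  f <- rep(1, length(KIND_FN))
  names(f) <- names(KIND_FN)
  for (n in c(2, 3, 4))
    f[!is.na(KIND_FN) & KIND_FN == n] <- temperature_factor(temperature, T0, n)
  f
}

pair_dist <- function(A, B) {
  # full distance matrix between rows of A and rows of B
  an <- rowSums(A^2); bn <- rowSums(B^2)
  d2 <- outer(an, bn, "+") - 2 * tcrossprod(A, B)
  sqrt(pmax(d2, 0))
}

dipole_factor <- function(u_i, u_j, rvec, r) {
  # point-dipole orientation factor [ui.uj - 3 (ui.rhat)(uj.rhat)] / r^3
  rhat <- rvec / r
  (sum(u_i * u_j) - 3 * sum(u_i * rhat) * sum(u_j * rhat)) / r^3
}

#' Evaluate the capped coarse-grained energy of a chain
#'
#' Computes the 15 term kinds with their index ranges (side-chain pairs over
#' i < j; side-chain/peptide over i != j; peptide pairs over i < j-1; local
#' terms over their defined ranges), caps every pairwise nonbonded
#' contribution, and accumulates the residue-type-resolved breakdown: a
#' 20 x 20 matrix in chain order (earlier type, later type) for the
#' side-chain pair, torsional and side-chain-correlation kinds, and a
#' 20-vector for the excluded-volume, double-torsional, bending and rotamer
#' kinds.  Kind totals are stored unweighted and without temperature
#' factors; the stored `total` is the weighted sum with the factors applied
#' (order 2: peptide electrostatics, torsions, side-chain correlation;
#' order 3: double torsions, 3rd-order correlation and 3-turn; order 4:
#' 4th-order correlation and 4-turn).
#'
#' @param cg a [cgchain()].
#' @param geom optional [internal_geometry()] of `cg` (computed if missing).
#' @param params an `energy_params` set (default [default_energy_params()]).
#' @param weights a [term_weights()] vector.
#' @param temperature temperature in kelvin (default 300).
#' @param cap repulsion cap in kcal/mol; `Inf` disables capping.  Default
#'   taken from `params$cap`.
#' @return object of class `energy_breakdown`: list with `kinds` (named
#'   15-vector, unweighted), `pair` (list of three 20 x 20 matrices:
#'   `SCSC`, `tor`, `SCcorr`), `type` (list of four 20-vectors: `SCp`,
#'   `tord`, `b`, `rot`), `total` (weighted, kcal/mol), `temperature`,
#'   `max_pair` (largest capped pairwise contribution per nonbonded kind)
#'   and `n_res`.
#' @export
energy_evaluate <- function(cg, geom = NULL, params = default_energy_params(),
                            weights = term_weights(), temperature = 300,
                            cap = NULL) {
  stopifnot(inherits(cg, "cgchain"), inherits(params, "energy_params"))
  if (is.null(geom)) geom <- internal_geometry(cg)
  cap <- cap %||% params$cap
  n <- length(cg$sequence)
  ti <- match(cg$sequence, AA20)
  sc <- cg$sc_sites; p <- cg$p_sites; ca <- cg$ca

  zmat <- function() matrix(0, 20, 20, dimnames = list(AA20, AA20))
  zvec <- function() setNames(numeric(20), AA20)
  pairm <- list(SCSC = zmat(), tor = zmat(), SCcorr = zmat())
  typev <- list(SCp = zvec(), tord = zvec(), b = zvec(), rot = zvec())
  kinds <- setNames(numeric(15), KIND15)
  max_pair <- setNames(rep(-Inf, 6),
                       c("SCSC", "SCp", "ppVDW", "ppel", "turn3", "turn4"))

  ## side-chain -- side-chain (i < j), 6-12 well, capped, pair-resolved
  D <- pair_dist(sc, sc)
  iu <- which(upper.tri(D), arr.ind = TRUE)   # i < j, i earlier in sequence
  if (nrow(iu)) {
    r <- pmax(D[iu], 1e-6)
    e <- params$eps[cbind(ti[iu[, 1L]], ti[iu[, 2L]])]
    s <- params$sigma[cbind(ti[iu[, 1L]], ti[iu[, 2L]])]
    sr6 <- (s / r)^6
    u <- cap_repulsion(4 * e * (sr6^2 - sr6), cap)
    max_pair["SCSC"] <- max(u)
    kinds["SCSC"] <- sum(u)
    for (k in seq_along(u)) {
      a <- ti[iu[k, 1L]]; b <- ti[iu[k, 2L]]
      pairm$SCSC[a, b] <- pairm$SCSC[a, b] + u[k]
    }
    ## disulfide wells share the SC distances
    cys <- which(cg$sequence == "C")
    if (length(cys) >= 2L) {
      ss <- 0
      for (a in seq_along(cys)) for (b in seq_along(cys)) {
        if (a >= b) next
        r_ss <- D[cys[a], cys[b]]
        if (r_ss < params$ss_cutoff)
          ss <- ss + (-params$ss_eps + params$ss_k * (r_ss - params$ss_r0)^2)
      }
      kinds["ssbond"] <- ss
    }
  }

  ## side-chain -- peptide excluded volume (i != j), capped, type-resolved
  Dsp <- pair_dist(sc, p)
  for (i in seq_len(n)) {
    js <- setdiff(seq_len(n - 1L), i)
    if (!length(js)) next
    r <- pmax(Dsp[i, js], 1e-6)
    u <- cap_repulsion(params$scp_eps * (params$scp_radius[ti[i]] / r)^12, cap)
    max_pair["SCp"] <- max(max_pair["SCp"], u)
    typev$SCp[ti[i]] <- typev$SCp[ti[i]] + sum(u)
  }
  kinds["SCp"] <- sum(typev$SCp)

  ## peptide -- peptide LJ and dipole (i < j - 1), capped
  np <- n - 1L
  uhat <- (ca[-1L, , drop = FALSE] - ca[-n, , drop = FALSE])
  uhat <- uhat / sqrt(rowSums(uhat^2))
  Dpp <- pair_dist(p, p)
  for (i in seq_len(np)) for (j in seq_len(np)) {
    if (j <= i + 1L) next
    r <- max(Dpp[i, j], 1e-6)
    sr6 <- (params$pp_sigma / r)^6
    uv <- cap_repulsion(4 * params$pp_eps * (sr6^2 - sr6), cap)
    kinds["ppVDW"] <- kinds["ppVDW"] + uv
    max_pair["ppVDW"] <- max(max_pair["ppVDW"], uv)
    ue <- cap_repulsion(
      params$pp_dipole * dipole_factor(uhat[i, ], uhat[j, ],
                                       p[j, ] - p[i, ], r), cap)
    kinds["ppel"] <- kinds["ppel"] + ue
    max_pair["ppel"] <- max(max_pair["ppel"], ue)
  }

  ## torsional terms: gamma_i spans ca[i-1..i+2], flanking pair (i, i+1)
  gam <- geom$gamma
  if (length(gam)) {
    for (k in seq_along(gam)) {
      i <- k + 1L                       # dihedral index in residue numbering
      a <- ti[i]; b <- ti[i + 1L]
      u <- 0
      for (h in 1:3)
        u <- u + params$tor_a[a, b, h] * cos(h * gam[k]) +
                 params$tor_b[a, b, h] * sin(h * gam[k])
      pairm$tor[a, b] <- pairm$tor[a, b] + u
    }
    kinds["tor"] <- sum(pairm$tor)
  }

  ## double-torsional: consecutive dihedral pairs, central residue type
  if (length(gam) >= 2L) {
    for (k in seq_len(length(gam) - 1L)) {
      tcent <- ti[k + 2L]               # residue between the two dihedrals
      u <- params$tord_c[tcent] * cos(gam[k] - gam[k + 1L])
      typev$tord[tcent] <- typev$tord[tcent] + u
    }
    kinds["tord"] <- sum(typev$tord)
  }

  ## bending: theta_i at residues 2..n-1
  for (k in seq_along(geom$theta)) {
    t2 <- ti[k + 1L]
    u <- params$b_k[t2] * (geom$theta[k] - params$b_theta0[t2])^2
    typev$b[t2] <- typev$b[t2] + u
  }
  kinds["b"] <- sum(typev$b)

  ## rotamer restraint: residues with a defined local frame, non-glycine;
  ## the azimuth deviation is wrapped so the branch cut at +-pi is smooth
  angdiff <- function(x, y) atan2(sin(x - y), cos(x - y))
  for (i in which(geom$rot_defined)) {
    t2 <- ti[i]
    u <- params$rot_k[t2] * ((geom$alpha[i] - params$rot_alpha0[t2])^2 +
                             angdiff(geom$beta[i], params$rot_beta0[t2])^2)
    typev$rot[t2] <- typev$rot[t2] + u
  }
  kinds["rot"] <- sum(typev$rot)

  ## virtual-bond deformation
  kinds["bond"] <- sum(params$bond_k * (geom$d - params$bond_d0)^2)

  ## correlation terms over consecutive dihedrals
  if (length(gam) >= 2L)
    kinds["corr3"] <- params$corr3_c *
      sum(cos(gam[-length(gam)]) * cos(gam[-1L]))
  if (length(gam) >= 3L)
    kinds["corr4"] <- params$corr4_c *
      sum(cos(gam[seq_len(length(gam) - 2L)]) * cos(gam[-(1:2)]))

  ## turn terms: dipole factor across windows of 3 / 4 peptide groups
  if (np >= 3L) for (i in seq_len(np - 2L)) {
    r <- max(Dpp[i, i + 2L], 1e-6)
    u <- cap_repulsion(params$turn3_A *
           dipole_factor(uhat[i, ], uhat[i + 2L, ], p[i + 2L, ] - p[i, ], r),
           cap)
    kinds["turn3"] <- kinds["turn3"] + u
    max_pair["turn3"] <- max(max_pair["turn3"], u)
  }
  if (np >= 4L) for (i in seq_len(np - 3L)) {
    r <- max(Dpp[i, i + 3L], 1e-6)
    u <- cap_repulsion(params$turn4_A *
           dipole_factor(uhat[i, ], uhat[i + 3L, ], p[i + 3L, ] - p[i, ], r),
           cap)
    kinds["turn4"] <- kinds["turn4"] + u
    max_pair["turn4"] <- max(max_pair["turn4"], u)
  }

  ## side-chain/backbone correlation dihedrals, pair-resolved by (i, i+1)
  for (i in seq_len(n - 1L)) {
    a <- ti[i]; b <- ti[i + 1L]
    for (m in 1:3) {
      tv <- geom$tau[i, m]
      if (is.na(tv)) next
      u <- 0
      for (k in 1:2) u <- u + params$sccorr_c[a, b, m, k] * cos(k * tv)
      pairm$SCcorr[a, b] <- pairm$SCcorr[a, b] + u
    }
  }
  kinds["SCcorr"] <- sum(pairm$SCcorr)

  f <- kind_factors(temperature, params$T0)
  total <- sum(unclass(weights)[KIND15] * f[KIND15] * kinds[KIND15])

  structure(list(kinds = kinds, pair = pairm, type = typev, total = total,
                 temperature = temperature, weights = unclass(weights),
                 max_pair = max_pair, n_res = n, cap = cap),
            class = "energy_breakdown")
}

#' Weighted total energy of a breakdown
#'
#' Recomputes the weighted sum of the 15 stored kind totals with the
#' temperature factors of the breakdown's temperature; with the weights the
#' breakdown was evaluated under, this equals its stored `total`.
#'
#' @param bd an `energy_breakdown`.
#' @param weights a [term_weights()] vector.
#' @param T0 reference temperature (kelvin).
#' @return total energy in kcal/mol.
#' @export
total_energy <- function(bd, weights = term_weights(), T0 = 300) {
  stopifnot(inherits(bd, "energy_breakdown"))
  f <- kind_factors(bd$temperature, T0)
  sum(unclass(weights)[KIND15] * f[KIND15] * bd$kinds[KIND15])
}

#' @export
print.energy_breakdown <- function(x, ...) {
  cat("Coarse-grained energy breakdown (", x$n_res, " residues, T = ",
      x$temperature, " K)\n", sep = "")
  print(round(x$kinds, 4))
  cat("weighted total:", format(x$total, digits = 8), "kcal/mol\n")
  invisible(x)
}

#' Write an energy report as TSV
#'
#' One row per term kind (unweighted totals) plus a `total` row carrying the
#' weighted, temperature-scaled sum.
#'
#' @param bd an `energy_breakdown`.
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_energy_report <- function(bd, path) {
  df <- data.frame(term = c(KIND15, "total"),
                   energy = c(unname(bd$kinds[KIND15]), bd$total))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
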