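# Term weights and the numeric parameter set behind the energy terms.
#
# The published coarse-grained force field ships its parameter tables in
# separate machine-readable files that are not part of this package; the
# default set here is generated deterministically from a fixed seed with
# physically sensible magnitudes (epsilon in [0.1, 1.5] kcal/mol, contact
# sigmas in [3, 7] A ordered by residue size).  The term *structure* -- which
# kinds exist, which indices they run over, how they are resolved by residue
# type -- is what the feature decomposition and the network reoptimization
# rely on, and that structure is exact.

#' Energy-term weights
#'
#' One dimensionless weight per energy-term kind.  The defaults are the
#' published optimized weights of the EL force-field variant.
#'
#' @param ... named weight overrides, e.g. `tor = 2`.  Valid names are the 15
#'   kinds: `r paste(unresqa:::KIND15, collapse = ", ")`.
#' @return named numeric vector of class `term_weights`, length 15.
#' @export
term_weights <- function(...) {
  w <- c(SCSC = 1.00000, SCp = 1.23315, ppVDW = 0.23173, ppel = 0.84476,
         tor = 1.34316, tord = 1.26571, b = 0.62954, rot = 0.10554,
         bond = 1.00000, corr3 = 0.37357, corr4 = 0.19212, turn3 = 1.40323,
         turn4 = 0.64673, ssbond = 1.00000, SCcorr = 0.25000)
  over <- list(...)
  if (length(over)) {
    if (is.null(names(over)) || !all(names(over) %in% KIND15))
      stop("unknown weight name(s): ",
           paste(setdiff(names(over), KIND15), collapse = ", "))
    w[names(over)] <- as.numeric(unlist(over))
  }
  stopifnot(all(is.finite(w)))
  structure(w, class = "term_weights")
}

# side-chain heavy-atom counts, used to order contact radii by residue size
SC_SIZE <- c(A = 1, C = 2, D = 4, E = 5, F = 7, G = 1, H = 6, I = 4, K = 5,
             L = 4, M = 4, N = 4, P = 3, Q = 5, R = 7, S = 2, T = 3, V = 3,
             W = 10, Y = 8)

#' Default energy parameter set
#'
#' Deterministically generated numeric parameters for every energy term.
#' Pairwise side-chain well depths and the Fourier coefficients of the local
#' terms are drawn from a private seeded stream (the set is identical on
#' every call and every platform); contact distances derive from a fixed
#' residue-size table so that larger side chains get larger radii.
#'
#' @param seed integer seed of the private generator stream (change only to
#'   produce an alternative parameter realization).
#' @return object of class `energy_params`; see the fields in the source or
#'   the file written by [write_energy_params()].
#' @export
default_energy_params <- function(seed = 981203L) {
  radii <- 1.5 + 2 * (SC_SIZE[AA20] - min(SC_SIZE)) / diff(range(SC_SIZE))
  names(radii) <- AA20
  with_private_seed(seed, {
    p <- list(
      version = "v1",
      # side-chain--side-chain 6-12 well: asymmetric in (earlier, later) type
      eps = matrix(runif(400, 0.1, 1.5), 20, 20, dimnames = list(AA20, AA20)),
      sigma = outer(radii, radii, "+"),
      # side-chain--peptide excluded volume
      scp_eps = 0.3,
      scp_radius = radii + 0.7,
      # peptide-group LJ and dipole constants
      pp_eps = 0.3, pp_sigma = 4.0, pp_dipole = 2.0,
      # torsional Fourier coefficients, per flanking-type pair, k = 1..3
      tor_a = array(runif(400 * 3, -0.3, 0.3), c(20, 20, 3),
                    dimnames = list(AA20, AA20, NULL)),
      tor_b = array(runif(400 * 3, -0.3, 0.3), c(20, 20, 3),
                    dimnames = list(AA20, AA20, NULL)),
      # double-torsional amplitude per central type
      tord_c = setNames(runif(20, -0.2, 0.2), AA20),
      # virtual-bond-angle bending
      b_theta0 = setNames(runif(20, 1.6, 2.2), AA20),
      b_k = setNames(runif(20, 1.0, 3.0), AA20),
      # side-chain rotamer restraint
      rot_alpha0 = setNames(runif(20, 1.0, 2.0), AA20),
      rot_beta0 = setNames(runif(20, -1.0, 1.0), AA20),
      rot_k = setNames(runif(20, 0.2, 1.0), AA20),
      # virtual-bond deformation
      bond_d0 = 3.8, bond_k = 20.0,
      # disulfide well (Cys-Cys side chains within the cutoff)
      ss_r0 = 4.0, ss_eps = 3.0, ss_k = 2.0, ss_cutoff = 7.0,
      # correlation and turn constants
      corr3_c = 0.5, corr4_c = 0.3, turn3_A = 1.0, turn4_A = 0.5,
      # side-chain/backbone correlation Fourier coefficients, m = 1..3, k = 1..2
      sccorr_c = array(runif(400 * 6, -0.2, 0.2), c(20, 20, 3, 2),
                       dimnames = list(AA20, AA20, NULL, NULL)),
      cap = 3.0, T0 = 300.0)
    class(p) <- "energy_params"
    p
  })
}

#' Write an energy parameter set to a structured text file
#'
#' Key/value lines for scalars and whitespace-separated blocks for vectors,
#' matrices and arrays, at full double precision; [read_energy_params()]
#' round-trips losslessly.
#'
#' @param params an `energy_params` object.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_energy_params <- function(params, path) {
  stopifnot(inherits(params, "energy_params"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# unresqa energy parameter file", con)
  for (nm in names(params)) {
    v <- params[[nm]]
    if (is.character(v)) {
      writeLines(sprintf("@scalar %s %s", nm, v), con)
    } else if (length(v) == 1L && is.null(dim(v))) {
      writeLines(sprintf("@scalar %s %.17g", nm, v), con)
    } else {
      dims <- dim(v) %||% length(v)
      writeLines(sprintf("@block %s %s", nm, paste(dims, collapse = " ")), con)
      writeLines(paste(sprintf("%.17g", as.vector(v)), collapse = " "), con)
    }
  }
  invisible(path)
}

#' Read an energy parameter set written by [write_energy_params()]
#'
#' @param path parameter file path.
#' @return an `energy_params` object.
#' @export
read_energy_params <- function(path) {
  lines <- readLines(path)
  lines <- lines[!grepl("^#", lines) & nzchar(lines)]
  p <- list()
  i <- 1L
  while (i <= length(lines)) {
    parts <- strsplit(lines[i], "[[:space:]]+")[[1L]]
    if (parts[1L] == "@scalar") {
      val <- suppressWarnings(as.numeric(parts[3L]))
      p[[parts[2L]]] <- if (is.na(val)) parts[3L] else val
      i <- i + 1L
    } else if (parts[1L] == "@block") {
      dims <- as.integer(parts[-(1:2)])
      vals <- as.numeric(strsplit(lines[i + 1L], "[[:space:]]+")[[1L]])
      nm <- parts[2L]
      if (length(dims) == 1L) {
        v <- vals
        if (length(v) == 20L) names(v) <- AA20
      } else {
        v <- array(vals, dims)
        if (all(dims[1:2] == 20L))
          dimnames(v) <- c(list(AA20, AA20), rep(list(NULL), length(dims) - 2L))
      }
      p[[nm]] <- v
      i <- i + 2L
    } else stop("malformed parameter line: ", lines[i])
  }
  class(p) <- "energy_params"
  p
}
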