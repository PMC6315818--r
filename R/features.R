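# Decomposition of an energy breakdown into the fixed 1296-entry feature
# vector, plus the winsorizing z-score scaler used before network training.
#
# Layout (frozen; the manifest hash is stored inside saved models so a
# trained ensemble refuses features in a different order):
#   1     weighted total energy
#   15    kind totals, unweighted and without temperature factors
#   4x20  type-resolved kinds: SCp, tord, b, rot
#   3x400 pair-resolved kinds: SCSC, tor, SCcorr, cell order (earlier type
#         outer, later type inner), types in the order ACDEFGHIKLMNPQRSTVWY.
# Pair cells are asymmetric: "SCSC.AC" accumulates interactions where the
# alanine precedes the cysteine in sequence.

manifest_cache <- new.env(parent = emptyenv())

#' Feature-name manifest
#'
#' The frozen, ordered names of all 1296 features.
#'
#' @return character vector of length 1296.
#' @export
feature_manifest <- function() {
  if (!is.null(manifest_cache$names)) return(manifest_cache$names)
  pair_names <- function(kind)
    as.vector(t(outer(AA20, AA20, function(a, b) paste0(kind, ".", a, b))))
  nm <- c("U.total",
          paste0("kind.", KIND15),
          paste0("SCp.", AA20), paste0("tord.", AA20),
          paste0("b.", AA20), paste0("rot.", AA20),
          pair_names("SCSC"), pair_names("tor"), pair_names("SCcorr"))
  stopifnot(length(nm) == 1296L)
  manifest_cache$names <- nm
  nm
}

#' Hash of the feature manifest
#'
#' MD5 of the ordered feature names; stored in fitted ensembles and model
#' files to guard against feature-order drift.
#'
#' @return character MD5 string.
#' @export
feature_manifest_hash <- function() {
  if (!is.null(manifest_cache$hash)) return(manifest_cache$hash)
  tf <- tempfile()
  writeLines(feature_manifest(), tf)
  h <- unname(tools::md5sum(tf))
  unlink(tf)
  manifest_cache$hash <- h
  h
}

#' Decompose an energy breakdown into the 1296-entry feature vector
#'
#' Assembles the fixed-order descriptor: the weighted total, the 15
#' unweighted kind totals, the four type-resolved 20-vectors and the three
#' pair-resolved 400-vectors.  For resolved kinds the kind-total entry
#' equals the sum of its resolved entries.
#'
#' @param bd an `energy_breakdown` from [energy_evaluate()].
#' @return named numeric vector of length 1296 (manifest order).
#' @export
decompose_energy <- function(bd) {
  stopifnot(inherits(bd, "energy_breakdown"))
  flat <- function(M) as.vector(t(M))  # earlier type outer, later inner
  fv <- c(bd$total,
          unname(bd$kinds[KIND15]),
          unname(bd$type$SCp), unname(bd$type$tord),
          unname(bd$type$b), unname(bd$type$rot),
          flat(bd$pair$SCSC), flat(bd$pair$tor), flat(bd$pair$SCcorr))
  names(fv) <- feature_manifest()
  fv
}

#' Compute the feature matrix of a set of chains
#'
#' Convenience loop: energy evaluation plus decomposition for each chain,
#' with optional extra descriptive columns appended after the 1296 energy
#' features (e.g. residue count and pseudo-atom count, the "+length"
#' mechanism).
#'
#' @param chains list of [cgchain()] objects.
#' @param params,weights,temperature passed to [energy_evaluate()].
#' @param extra one of `"none"` (default) or `"length"` (append `n_res` and
#'   `n_sites` columns).
#' @return numeric matrix, one row per chain, 1296 (+ extras) columns.
#' @export
featurize_chains <- function(chains, params = default_energy_params(),
                             weights = term_weights(), temperature = 300,
                             extra = c("none", "length")) {
  extra <- match.arg(extra)
  rows <- lapply(chains, function(cg) {
    fv <- decompose_energy(energy_evaluate(cg, params = params,
                                           weights = weights,
                                           temperature = temperature))
    if (extra == "length") {
      n <- length(cg$sequence)
      fv <- c(fv, n_res = n, n_sites = n + (n - 1L) + n)
    }
    fv
  })
  do.call(rbind, rows)
}

#' Fit the winsorizing z-score scaler
#'
#' Per feature: clamp at the empirical 1st and 99th percentiles of the
#' training data (to limit the effect of outliers), then store the mean and
#' standard deviation of the clamped values.  Constant features get a unit
#' standard deviation so they z-score to zero.
#'
#' @param features numeric matrix (>= 2 rows), one row per decoy.
#' @return object of class `unresqa_scaler` with fields `lower`, `upper`,
#'   `mean`, `sd` (one entry per column).
#' @export
fit_scaler <- function(features) {
  features <- as.matrix(features)
  if (nrow(features) < 2L) stop("scaler needs at least 2 rows")
  lo <- apply(features, 2L, quantile, probs = 0.01, names = FALSE)
  hi <- apply(features, 2L, quantile, probs = 0.99, names = FALSE)
  clamped <- pmin(pmax(features, rep(lo, each = nrow(features))),
                  rep(hi, each = nrow(features)))
  m <- colMeans(clamped)
  s <- apply(clamped, 2L, sd)
  s[!is.finite(s) | s < 1e-12] <- 1
  structure(list(lower = lo, upper = hi, mean = m, sd = s,
                 n_features = ncol(features)),
            class = "unresqa_scaler")
}

#' Apply a fitted scaler
#'
#' Clamp to the stored percentile bounds, then standardize elementwise.
#' Clamping is idempotent: values at or beyond a bound map to the bound.
#'
#' @param scaler an `unresqa_scaler` from [fit_scaler()].
#' @param features numeric vector (one decoy) or matrix (rows = decoys).
#' @return scaled object of the same shape.
#' @export
apply_scaler <- function(scaler, features) {
  stopifnot(inherits(scaler, "unresqa_scaler"))
  vec <- is.null(dim(features))
  X <- if (vec) matrix(features, nrow = 1L) else as.matrix(features)
  if (ncol(X) != scaler$n_features)
    stop("feature length ", ncol(X), " does not match scaler (",
         scaler$n_features, ")")
  X <- pmin(pmax(X, rep(scaler$lower, each = nrow(X))),
            rep(scaler$upper, each = nrow(X)))
  X <- sweep(sweep(X, 2L, scaler$mean, "-"), 2L, scaler$sd, "/")
  if (vec) drop(X) else X
}

#' Write a feature matrix as TSV
#'
#' Header = target and model id columns followed by the manifest names.
#'
#' @param features numeric matrix from [featurize_chains()].
#' @param target,model character vectors identifying each row.
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_feature_tsv <- function(features, target, model, path) {
  df <- data.frame(target = target, model = model, features,
                   check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a feature TSV written by [write_feature_tsv()]
#'
#' @param path TSV path.
#' @return list with `target`, `model` (character) and `features` (matrix).
#' @export
read_feature_tsv <- function(path) {
  df <- read.table(path, sep = "\t", header = TRUE, check.names = FALSE)
  list(target = as.character(df$target), model = as.character(df$model),
       features = as.matrix(df[, -(1:2), drop = FALSE]))
}
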