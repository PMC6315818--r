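# TM-score between equal-length structures and the label transformation.

#' Optimal rigid superposition (Kabsch)
#'
#' Least-squares proper rotation and translation mapping `P` onto `Q`
#' (reflections excluded), via singular value decomposition of the
#' covariance of the centered coordinates.
#'
#' @param P,Q n x 3 coordinate matrices (n >= 3), rows are matched points.
#' @return object of class `superposition`: `rotation` (3 x 3, det +1),
#'   `translation` (length 3) with `P %*% rotation + translation ~ Q`, and
#'   `rmsd` (Angstrom).
#' @export
kabsch <- function(P, Q) {
  P <- as.matrix(P); Q <- as.matrix(Q)
  if (nrow(P) < 3L) stop("kabsch needs at least 3 points")
  if (!all(dim(P) == dim(Q)) || ncol(P) != 3L)
    stop("P and Q must be equal n x 3 matrices")
  res <- kabsch_cpp(P, Q)
  res$translation <- drop(res$translation)
  class(res) <- "superposition"
  res
}

#' @export
print.superposition <- function(x, ...) {
  cat("Rigid superposition: rmsd =", format(x$rmsd, digits = 6), "A\n")
  invisible(x)
}

tm_d0 <- function(L) max(1.24 * (L - 15)^(1 / 3) - 1.8, 0.5)

#' TM-score of a model against a reference
#'
#' Length-normalized structural similarity in (0, 1] over the Ca trace:
#' `TMS = max (1/L) sum_i 1/(1 + (d_i/d0)^2)` with
#' `d0 = 1.24 (L-15)^(1/3) - 1.8` (at least 0.5 A) and L the reference
#' length.  The maximum over superpositions is searched deterministically:
#' contiguous seed fragments of lengths L, L/2, L/4 and 4 at stride L/10,
#' each refined by iterative re-superposition on the residues within d0 of
#' the reference until the included set is stable; the best score seen is
#' returned.  The heuristic is not exactly symmetric in its arguments;
#' [pairwise_tm_matrix()] symmetrizes by averaging both orientations.
#'
#' @param model,reference [cgchain()] objects (same sequence) or n x 3 Ca
#'   coordinate matrices; length >= 16 so d0 is positive.
#' @return TM-score in (0, 1].
#' @export
tm_score <- function(model, reference) {
  P <- if (inherits(model, "cgchain")) model$ca else as.matrix(model)
  Q <- if (inherits(reference, "cgchain")) reference$ca else as.matrix(reference)
  if (nrow(P) != nrow(Q)) stop("model and reference lengths differ")
  if (inherits(model, "cgchain") && inherits(reference, "cgchain") &&
      !identical(model$sequence, reference$sequence))
    stop("model and reference sequences differ")
  L <- nrow(Q)
  if (L < 16L) stop("TM-score needs length >= 16 (d0 validity)")
  tm_score_cpp(P, Q, tm_d0(L), stride = max(1L, L %/% 10L), max_iter = 30L)
}

#' Transform a TM-score to the training label scale
#'
#' `TMS' = 1 - 2 TMS`, chosen so labels live in \[-1, 1\] (matching the
#' bipolar network output) and share the energy convention that lower is
#' better: a native structure scores exactly -1.
#'
#' @param t TM-score(s) in \[0, 1\].
#' @return transformed score(s) in \[-1, 1\].
#' @seealso [inverse_transform_tms()]
#' @export
transform_tms <- function(t) {
  if (any(t < 0 | t > 1)) stop("TM-score must lie in [0, 1]")
  1 - 2 * t
}

#' Back-transform a label to the TM-score scale
#'
#' Inverse of [transform_tms()]: `TMS = (1 - TMS') / 2`.
#'
#' @param s transformed score(s) in \[-1, 1\].
#' @return TM-score(s) in \[0, 1\].
#' @export
inverse_transform_tms <- function(s) {
  if (any(s < -1 | s > 1)) stop("transformed score must lie in [-1, 1]")
  (1 - s) / 2
}

#' Symmetrized pairwise TM-score matrix
#'
#' TM-scores between all pairs of a list of equal-length chains, symmetrized
#' as the mean of both orientations (the search heuristic is not exactly
#' symmetric); diagonal 1.
#'
#' @param chains list of [cgchain()] objects (typically native + decoys).
#' @return symmetric numeric matrix with unit diagonal, dimnames from
#'   `names(chains)`.
#' @export
pairwise_tm_matrix <- function(chains) {
  k <- length(chains)
  M <- diag(1, k)
  if (k >= 2L) for (i in seq_len(k - 1L)) for (j in (i + 1L):k) {
    v <- (tm_score(chains[[i]], chains[[j]]) +
          tm_score(chains[[j]], chains[[i]])) / 2
    M[i, j] <- M[j, i] <- v
  }
  dimnames(M) <- list(names(chains), names(chains))
  M
}
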