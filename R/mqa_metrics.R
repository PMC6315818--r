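# Decoy ranking statistics over per-target (model, real TMS, score) tables.
#
# Convention throughout: a score is on the transformed scale (or a raw
# energy), so LOWER is more favorable.  Predictions on the TM-score scale
# must go through transform_tms() before these functions.  The native row,
# when present, is flagged and excluded from score rankings by default (its
# predicted score would leak the label) but anchors the folding path.

#' Build a per-target scoring table
#'
#' @param target single target id.
#' @param model character vector of model ids.
#' @param tms TM-scores of each model to the native structure, in \[0, 1\].
#' @param score predicted transformed score or raw energy (lower = better).
#' @param native logical vector flagging the native row(s), default none.
#' @return data.frame of class `target_table`.
#' @export
target_table <- function(target, model, tms, score,
                         native = rep(FALSE, length(model))) {
  stopifnot(length(model) == length(tms), length(tms) == length(score))
  if (any(tms < 0 | tms > 1)) stop("tms must lie in [0, 1]")
  df <- data.frame(target = target, model = as.character(model),
                   tms = tms, score = score, native = native,
                   stringsAsFactors = FALSE)
  class(df) <- c("target_table", "data.frame")
  df
}

score_rows <- function(t, include_native = FALSE) {
  stopifnot(inherits(t, "target_table"))
  if (include_native) t else t[!t$native, , drop = FALSE]
}

#' Mean TM-score of the k best-scored models
#'
#' Ranks by score ascending (lower transformed score / energy = better,
#' ties broken by model id) and averages the real TM-scores of the k
#' best-ranked models.  The native row is excluded from the ranking.
#'
#' @param t a [target_table()].
#' @param k number of top models (default 5).
#' @param include_native include the native row in the ranking (default no).
#' @return mean TM-score of the top k.
#' @export
top_k_mean_tms <- function(t, k = 5L, include_native = FALSE) {
  tt <- score_rows(t, include_native)
  if (k > nrow(tt)) stop("k = ", k, " exceeds ", nrow(tt), " scoreable rows")
  ord <- order(tt$score, tt$model)
  mean(tt$tms[ord[seq_len(k)]])
}

#' Per-target Pearson correlation
#'
#' Pearson r between the real TM-score to native and the predicted
#' TM-score.  Scores are stored on the lower-is-better scale, so they are
#' back-transformed before correlating and a good scorer has r near +1,
#' matching the reported sign convention.
#'
#' @param t a [target_table()] with >= 3 scoreable rows.
#' @param include_native include the native row (default no).
#' @return Pearson correlation, or `NA` (with a warning) when either column
#'   has zero variance.
#' @export
pearson_per_target <- function(t, include_native = FALSE) {
  tt <- score_rows(t, include_native)
  if (nrow(tt) < 3L) stop("need at least 3 rows for a correlation")
  if (sd(tt$tms) < 1e-12 || sd(tt$score) < 1e-12) {
    warning("zero variance in target ", tt$target[1L], "; correlation undefined")
    return(NA_real_)
  }
  cor(tt$tms, inverse_transform_tms(pmin(pmax(tt$score, -1), 1)))
}

rank_window_means <- function(v, ord, top = 1:5, low = 10:15) {
  c(mean(v[ord[top]]), mean(v[ord[low]]))
}

#' Directional accuracy (DA)
#'
#' Ranks models by real TM-score descending, takes the mean score of ranks
#' 1-5 and of ranks 10-15, and returns +1 when the change points the right
#' way -- the top group more favorable (lower score) -- and -1 otherwise.
#' An exact tie counts as +1.
#'
#' @param t a [target_table()] with >= 15 scoreable rows.
#' @param include_native include the native row (default no).
#' @param low_window ranks of the lower comparison group (default 10:15).
#' @return +1 or -1.
#' @export
directional_accuracy <- function(t, include_native = FALSE,
                                 low_window = 10:15) {
  tt <- score_rows(t, include_native)
  if (nrow(tt) < max(low_window)) stop("need at least ", max(low_window), " rows")
  ord <- order(-tt$tms, tt$model)
  w <- rank_window_means(tt$score, ord, low = low_window)
  if (w[1L] <= w[2L]) 1 else -1
}

#' Second directional accuracy (DA2)
#'
#' Ranks models by score ascending (best first) and returns the real
#' TM-score difference between ranks 1-5 and ranks 10-15; positive when the
#' scorer puts genuinely better models in front.
#'
#' @inheritParams directional_accuracy
#' @return TM-score difference (top 1-5 minus ranks 10-15).
#' @export
second_directional_accuracy <- function(t, include_native = FALSE,
                                        low_window = 10:15) {
  tt <- score_rows(t, include_native)
  if (nrow(tt) < max(low_window)) stop("need at least ", max(low_window), " rows")
  ord <- order(tt$score, tt$model)
  w <- rank_window_means(tt$tms, ord, low = low_window)
  w[1L] - w[2L]
}

#' Greedy folding path from the native structure
#'
#' Starting at the native structure, repeatedly appends the unused model
#' most similar (maximum TM-score) to the current end of the chain until
#' all models are used; ties break by model id.  The path `mean` is the
#' average TM-score between consecutive path members; the `span` is the
#' TM-score between the native structure and the final member.
#'
#' @param pairwise_tms symmetric matrix of pairwise TM-scores over native +
#'   models, unit diagonal, with dimnames; row/column `native` names the
#'   native structure.
#' @param native name of the native row (default `"native"`).
#' @return object of class `native_path`: list with `order` (model ids,
#'   native first), `step_tms` (consecutive-pair TM-scores), `mean`, `span`.
#' @export
build_native_path <- function(pairwise_tms, native = "native") {
  M <- as.matrix(pairwise_tms)
  if (nrow(M) != ncol(M)) stop("pairwise TM-score matrix must be square")
  if (max(abs(M - t(M))) > 1e-6) stop("pairwise TM-score matrix must be symmetric")
  if (any(M < 0 | M > 1)) stop("TM-scores must lie in [0, 1]")
  ids <- rownames(M) %||% as.character(seq_len(nrow(M)))
  dimnames(M) <- list(ids, ids)
  if (!native %in% ids) stop("native row '", native, "' not found")
  current <- native
  unused <- setdiff(ids, native)
  path <- native
  steps <- numeric(0)
  while (length(unused)) {
    sims <- M[current, unused]
    nxt <- unused[order(-sims, unused)][1L]   # max similarity, ties by id
    steps <- c(steps, M[current, nxt])
    path <- c(path, nxt)
    unused <- setdiff(unused, nxt)
    current <- nxt
  }
  structure(list(order = path, step_tms = steps, mean = mean(steps),
                 span = M[native, path[length(path)]]),
            class = "native_path")
}

#' @export
print.native_path <- function(x, ...) {
  cat("Folding path over", length(x$order) - 1L, "models: mean =",
      round(x$mean, 4), "span =", round(x$span, 4), "\n")
  invisible(x)
}

#' Path-to-native accuracy (PNA)
#'
#' Walks the folding path from its far end toward the native structure and
#' assigns +1 to each consecutive pair whose score does not increase toward
#' native (consistent with approaching the native state) and -1 otherwise;
#' returns the mean assignment.  Pairs involving a structure without a
#' score (e.g. an unscored native anchor) are skipped.
#'
#' @param path a `native_path` from [build_native_path()].
#' @param scores named numeric vector of scores (lower = better) covering
#'   the path members; members missing from `scores` may only be the path
#'   anchor.
#' @return mean of the +1/-1 assignments.
#' @export
path_to_native_accuracy <- function(path, scores) {
  stopifnot(inherits(path, "native_path"))
  ids <- path$order
  have <- ids %in% names(scores)
  if (any(!have & seq_along(ids) > 1L))
    stop("missing score for path member(s): ",
         paste(ids[!have & seq_along(ids) > 1L], collapse = ", "))
  assigns <- numeric(0)
  for (k in length(ids):2L) {           # far end toward native
    farther <- ids[k]; closer <- ids[k - 1L]
    if (!(farther %in% names(scores)) || !(closer %in% names(scores))) next
    assigns <- c(assigns,
                 if (scores[[closer]] <= scores[[farther]]) 1 else -1)
  }
  if (!length(assigns)) stop("no scoreable path steps")
  mean(assigns)
}

#' Aggregate per-target metrics
#'
#' Arithmetic mean and sample standard deviation over targets (0 for a
#' single target, by convention).
#'
#' @param values numeric vector of per-target metric values.
#' @return named vector `c(mean, std)`.
#' @export
aggregate_metric <- function(values) {
  values <- values[is.finite(values)]
  if (!length(values)) stop("no finite per-target values")
  c(mean = mean(values), std = if (length(values) > 1L) sd(values) else 0)
}

#' Full evaluation report over targets
#'
#' Computes, per target: top-5 mean TM-score, Pearson correlation,
#' directional accuracies DA and DA2, and -- when pairwise TM-score
#' matrices are supplied -- the path-to-native accuracy with the path mean
#' and span.  Aggregates each metric over targets as mean +- sample STD.
#'
#' @param tables list of [target_table()]s, one per target.
#' @param pairwise optional named list of symmetric pairwise TM-score
#'   matrices (names matching each table's target id) for path metrics;
#'   native row named `"native"`.
#' @param native_scores optional named list of native-structure scores, one
#'   per target, used only on path steps touching the native anchor.
#' @return object of class `mqa_report`: list with `per_target` (data.frame)
#'   and `aggregate` (data.frame of mean and std per metric).
#' @export
evaluate_scoring <- function(tables, pairwise = NULL, native_scores = NULL) {
  per <- lapply(tables, function(t) {
    tid <- t$target[1L]
    row <- data.frame(
      target = tid,
      top5tms = top_k_mean_tms(t),
      pearson = pearson_per_target(t),
      da = directional_accuracy(t),
      da2 = second_directional_accuracy(t),
      pna = NA_real_, path_mean = NA_real_, path_span = NA_real_)
    if (!is.null(pairwise) && tid %in% names(pairwise)) {
      path <- build_native_path(pairwise[[tid]])
      sc <- setNames(t$score[!t$native], t$model[!t$native])
      if (!is.null(native_scores) && tid %in% names(native_scores))
        sc <- c(sc, native = unname(native_scores[[tid]]))
      row$pna <- path_to_native_accuracy(path, sc)
      row$path_mean <- path$mean
      row$path_span <- path$span
    }
    row
  })
  per <- do.call(rbind, per)
  metrics <- c("top5tms", "pearson", "da", "da2", "pna", "path_mean",
               "path_span")
  agg <- t(vapply(metrics, function(m) {
    v <- per[[m]]
    if (all(is.na(v))) c(mean = NA_real_, std = NA_real_)
    else aggregate_metric(v)
  }, c(mean = 0, std = 0)))
  structure(list(per_target = per,
                 aggregate = data.frame(metric = metrics, agg)),
            class = "mqa_report")
}

#' @export
print.mqa_report <- function(x, digits = 4, ...) {
  cat("Model-quality-assessment report over", nrow(x$per_target),
      "target(s)\n")
  agg <- x$aggregate
  agg$mean <- round(agg$mean, digits)
  agg$std <- round(agg$std, digits)
  print(agg, row.names = FALSE)
  invisible(x)
}

#' Write an evaluation report as TSV files
#'
#' @param report an `mqa_report` from [evaluate_scoring()].
#' @param per_target_path,aggregate_path output TSV paths (either may be
#'   `NULL` to skip).
#' @return invisibly, the paths written.
#' @export
write_mqa_report <- function(report, per_target_path = NULL,
                             aggregate_path = NULL) {
  fmt <- function(df) {
    num <- vapply(df, is.numeric, TRUE)
    df[num] <- lapply(df[num], function(v) sprintf("%.6f", v))
    df
  }
  if (!is.null(per_target_path))
    write.table(fmt(report$per_target), per_target_path, sep = "\t",
                quote = FALSE, row.names = FALSE)
  if (!is.null(aggregate_path))
    write.table(fmt(report$aggregate), aggregate_path, sep = "\t",
                quote = FALSE, row.names = FALSE)
  invisible(c(per_target_path, aggregate_path))
}
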