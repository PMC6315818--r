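# The main modelling interface: fit an ensemble of feed-forward networks
# mapping energy features to transformed TM-scores, with the classic
# fitted-model methods (print, summary, coef, predict, plot, residuals).

#' Fit a neural-network decoy-scoring ensemble
#'
#' Trains `n_realizations` feed-forward networks (two hidden layers, bipolar
#' tanh activation, per-sample steepest descent with momentum), each with an
#' independent seeded 30%-of-targets overfit-protection split and weight
#' initialization.  Labels are TM-scores to the native structure; they are
#' transformed internally to `TMS' = 1 - 2 TMS` so that lower is better and
#' the native scores -1.  Features are winsorized at their 1st/99th
#' percentiles and z-scored with a scaler fitted once on the training rows
#' of the first split and reused at prediction time.
#'
#' @param x numeric feature matrix, one row per decoy: the 1296 energy
#'   features of [featurize_chains()], optionally with extra appended
#'   descriptive columns (e.g. the `"length"` extras).
#' @param tms numeric vector of TM-scores to native in \[0, 1\] (one per row).
#' @param targets character vector of target ids (groups decoys of one
#'   protein; overfit splits never separate them).
#' @param config a [network_config()].
#' @param seed master integer seed; all splits, initializations and epoch
#'   shuffles derive from it, so refitting is fully reproducible.
#' @return object of class `unresqa`: list with `nets` (trained
#'   `unresqa_net`s), `scaler`, `config`, `manifest_hash`, `n_in`, `seed`,
#'   `fitted` (ensemble TM-scale predictions on `x`), `tms` (labels),
#'   `targets`, and per-net `overfit_targets`.
#' @examples
#' set.seed(1)
#' x <- matrix(rnorm(40 * 5), 40, 5)
#' tms <- pmin(pmax(0.5 + 0.4 * tanh(x[, 1]), 0), 1)
#' fit <- unresqa(x, tms, targets = rep(paste0("T", 1:8), each = 5),
#'                config = network_config(hl1 = 3, hl2 = 3, n_max = 50,
#'                                        n_realizations = 2))
#' predict(fit, x[1:2, ])
#' @export
unresqa <- function(x, tms, targets, config = network_config(), seed = 1L) {
  x <- as.matrix(x)
  stopifnot(nrow(x) == length(tms), length(targets) == length(tms))
  if (any(tms < 0 | tms > 1)) stop("labels must be TM-scores in [0, 1]")
  y <- transform_tms(tms)
  net_seeds <- vapply(seq_len(config$n_realizations),
                      function(k) derive_seed(seed, paste0("net", k)), 0L)

  # scaler: fitted once, on the training rows of the first split
  over1 <- split_targets(targets, config$overfit_fraction,
                         derive_seed(net_seeds[1L], "split"))
  scaler <- fit_scaler(x[!over1, , drop = FALSE])
  Xs <- apply_scaler(scaler, x)

  nets <- lapply(net_seeds, function(s)
    train_network(Xs, y, targets, config, seed = s))

  hash <- if (ncol(x) >= 1296L &&
              identical(colnames(x)[1:1296], feature_manifest()))
    feature_manifest_hash() else NA_character_

  obj <- structure(list(nets = nets, scaler = scaler, config = config,
                        manifest_hash = hash, n_in = ncol(x), seed = seed,
                        net_seeds = net_seeds, tms = tms, targets = targets,
                        overfit_targets = lapply(nets, attr, "overfit_targets")),
                   class = "unresqa")
  obj$fitted <- predict(obj, x)$tms
  obj
}

#' Predict decoy quality with a fitted ensemble
#'
#' Applies the stored scaler, runs each network forward, and returns the
#' arithmetic mean and population standard deviation (the across-network
#' spread estimates prediction stability) of the transformed scores, plus
#' the back-transformed TM-scale prediction `(1 - mean) / 2`.
#'
#' @param object a fitted [unresqa()] ensemble.
#' @param newdata feature matrix (or single vector) on the same columns the
#'   ensemble was fitted on; if it carries the 1296-entry manifest column
#'   names they are checked against the stored manifest hash.
#' @param ... unused.
#' @return data.frame with columns `score` (mean transformed score), `std`
#'   and `tms` (back-transformed mean).
#' @export
predict.unresqa <- function(object, newdata, ...) {
  X <- if (is.null(dim(newdata))) matrix(newdata, nrow = 1L)
       else as.matrix(newdata)
  if (ncol(X) != object$n_in)
    stop("newdata has ", ncol(X), " columns; model expects ", object$n_in)
  if (!is.na(object$manifest_hash) && !is.null(colnames(X)) &&
      ncol(X) >= 1296L) {
    tf <- tempfile(); writeLines(colnames(X)[1:1296], tf)
    h <- unname(tools::md5sum(tf)); unlink(tf)
    if (h != object$manifest_hash)
      stop("feature manifest of newdata does not match the fitted model")
  }
  Xs <- apply_scaler(object$scaler, X)
  if (is.null(dim(Xs))) Xs <- matrix(Xs, nrow = 1L)
  P <- vapply(object$nets, function(net) nn_forward(net, Xs),
              numeric(nrow(Xs)))
  P <- matrix(P, nrow = nrow(Xs))
  m <- rowMeans(P)
  k <- ncol(P)
  stdev <- sqrt(rowSums((P - m)^2) / k)   # population std over realizations
  data.frame(score = m, std = stdev, tms = inverse_transform_tms(pmin(pmax(m, -1), 1)))
}

#' @export
print.unresqa <- function(x, ...) {
  cat("Decoy-scoring ensemble: ", length(x$nets), " networks (",
      x$config$hl1, "+", x$config$hl2, " hidden nodes), ", x$n_in,
      " input features\n", sep = "")
  cat("Fitted on ", length(x$tms), " decoys over ",
      length(unique(x$targets)), " targets (seed ", x$seed, ")\n", sep = "")
  invisible(x)
}

#' @export
summary.unresqa <- function(object, ...) {
  be <- vapply(object$nets, attr, 0, "best_epoch")
  bo <- vapply(object$nets, attr, 0, "best_overfit_sse")
  r <- cor(object$fitted, object$tms)
  out <- list(n_nets = length(object$nets), n_in = object$n_in,
              n_samples = length(object$tms),
              n_targets = length(unique(object$targets)),
              best_epoch = be, best_overfit_sse = bo,
              train_pearson = r, config = object$config)
  class(out) <- "summary.unresqa"
  out
}

#' @export
print.summary.unresqa <- function(x, ...) {
  cat("Ensemble of", x$n_nets, "networks on", x$n_in, "features;",
      x$n_samples, "decoys /", x$n_targets, "targets\n")
  cat("Best epochs:", paste(x$best_epoch, collapse = ", "), "\n")
  cat("Overfit-set SSE at best epoch:",
      paste(signif(x$best_overfit_sse, 4), collapse = ", "), "\n")
  cat("Pearson r (fitted vs label TMS):", round(x$train_pearson, 4), "\n")
  invisible(x)
}

#' @export
coef.unresqa <- function(object, ...) {
  lapply(object$nets, function(n) list(W1 = n$W1, W2 = n$W2, W3 = n$W3))
}

#' @export
residuals.unresqa <- function(object, ...) object$tms - object$fitted

#' Plot training history of a fitted ensemble
#'
#' Per-epoch overfit-protection error (sum of squared errors on the
#' held-out targets) for each network realization, on a log scale.
#'
#' @param x a fitted [unresqa()] ensemble.
#' @param ... passed to [graphics::matplot()].
#' @export
plot.unresqa <- function(x, ...) {
  hs <- lapply(x$nets, function(n) attr(n, "history")$overfit_sse)
  ne <- max(vapply(hs, length, 0L))
  M <- vapply(hs, function(h) c(h, rep(NA, ne - length(h))), numeric(ne))
  graphics::matplot(M, type = "l", lty = 1, log = "y", xlab = "epoch",
                    ylab = "overfit-set SSE (TMS' scale)", ...)
  invisible(x)
}

#' Save a fitted ensemble as a structured text model file
#'
#' Versioned key/value + block format at full double precision, containing
#' the configuration, the scaler, the manifest hash and all weight blocks;
#' [read_unresqa_model()] restores a model whose predictions are
#' bit-identical.
#'
#' @param object a fitted [unresqa()] ensemble.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_unresqa_model <- function(object, path) {
  stopifnot(inherits(object, "unresqa"))
  con <- file(path, "w")
  on.exit(close(con))
  wl <- function(...) writeLines(sprintf(...), con)
  num <- function(v) paste(sprintf("%.17g", as.vector(v)), collapse = " ")
  wl("@model unresqa v1")
  wl("@hash %s", object$manifest_hash)
  wl("@n_in %d", object$n_in)
  wl("@seed %d", object$seed)
  cfg <- object$config
  wl("@config %s", num(c(cfg$hl1, cfg$hl2, cfg$a, cfg$mu, cfg$momentum,
                         cfg$n_max, cfg$n_stop, cfg$overfit_fraction,
                         cfg$n_realizations, as.numeric(cfg$batch))))
  for (f in c("lower", "upper", "mean", "sd"))
    wl("@scaler %s %s", f, num(object$scaler[[f]]))
  for (k in seq_along(object$nets)) {
    net <- object$nets[[k]]
    for (b in c("W1", "W2", "W3"))
      wl("@net %d %s %d %d %s", k, b, nrow(net[[b]]), ncol(net[[b]]),
         num(net[[b]]))
  }
  invisible(path)
}

#' Load a model file written by [write_unresqa_model()]
#'
#' @param path model file path.
#' @return an `unresqa` object (prediction-capable; training history and
#'   fitted values are not stored in the file).
#' @export
read_unresqa_model <- function(path) {
  lines <- readLines(path)
  if (!startsWith(lines[1L], "@model unresqa v1"))
    stop("not an unresqa v1 model file")
  take <- function(tag) sub(paste0("^", tag, " "), "",
                            grep(paste0("^", tag, " "), lines, value = TRUE))
  nums <- function(s) as.numeric(strsplit(s, " ")[[1L]])
  cfgv <- nums(take("@config"))
  cfg <- network_config(hl1 = cfgv[1L], hl2 = cfgv[2L], a = cfgv[3L],
                        mu = cfgv[4L], momentum = cfgv[5L], n_max = cfgv[6L],
                        n_stop = cfgv[7L], overfit_fraction = cfgv[8L],
                        n_realizations = cfgv[9L], batch = cfgv[10L] > 0)
  n_in <- as.integer(take("@n_in"))
  sc <- list()
  for (f in c("lower", "upper", "mean", "sd"))
    sc[[f]] <- nums(sub(paste0("^", f, " "), "",
                        grep(paste0("^", f, " "), take("@scaler"), value = TRUE)))
  sc$n_features <- n_in
  class(sc) <- "unresqa_scaler"
  netlines <- take("@net")
  nets <- list()
  for (ln in netlines) {
    parts <- strsplit(ln, " ")[[1L]]
    k <- as.integer(parts[1L]); b <- parts[2L]
    nr <- as.integer(parts[3L]); nc <- as.integer(parts[4L])
    vals <- as.numeric(parts[-(1:4)])
    if (length(nets) < k)
      nets[[k]] <- structure(list(a = cfg$a, n_in = n_in),
                             class = "unresqa_net")
    nets[[k]][[b]] <- matrix(vals, nr, nc)
  }
  hash <- take("@hash")
  if (identical(hash, "NA")) hash <- NA_character_
  structure(list(nets = nets, scaler = sc, config = cfg,
                 manifest_hash = hash, n_in = n_in,
                 seed = as.integer(take("@seed")), tms = NULL,
                 targets = NULL, fitted = NULL),
            class = "unresqa")
}
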