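# Network primitives: configuration, initialization, forward pass, a single
# backpropagation step, and single-network training with held-out-target
# overfit protection.  The ensemble-level fitting interface lives in fit.R.

#' Network and training configuration
#'
#' Defaults are the published optimized values: 6 and 7 hidden nodes,
#' activation slope a = 0.2, learning rate mu = 0.003973, momentum P = 0.4,
#' at most 10000 epochs with stop patience 400, a 30% held-out-target
#' overfit-protection split, and six network realizations.
#'
#' @param hl1,hl2 hidden-layer sizes (positive integers).
#' @param a activation slope of `g(z) = tanh(a z)`.
#' @param mu learning rate of the steepest-descent update.
#' @param momentum contribution of the previous total weight update.
#' @param n_max maximum training epochs.
#' @param n_stop epochs without overfit-set improvement before stopping.
#' @param overfit_fraction fraction of targets held out for overfit
#'   protection, in (0, 1).
#' @param n_realizations number of independently initialized/split networks.
#' @param batch if `TRUE`, accumulate gradients over an epoch and update
#'   once per epoch instead of per sample (default per-sample).
#' @return list of class `unresqa_config`.
#' @export
network_config <- function(hl1 = 6L, hl2 = 7L, a = 0.2, mu = 0.003973,
                           momentum = 0.4, n_max = 10000L, n_stop = 400L,
                           overfit_fraction = 0.30, n_realizations = 6L,
                           batch = FALSE) {
  if (hl1 < 1L || hl2 < 1L) stop("hidden layers need at least one node")
  stopifnot(a > 0, mu > 0, momentum >= 0, n_max >= 1L, n_stop >= 1L,
            overfit_fraction > 0, overfit_fraction < 1, n_realizations >= 1L)
  structure(list(hl1 = as.integer(hl1), hl2 = as.integer(hl2), a = a,
                 mu = mu, momentum = momentum, n_max = as.integer(n_max),
                 n_stop = as.integer(n_stop),
                 overfit_fraction = overfit_fraction,
                 n_realizations = as.integer(n_realizations),
                 batch = isTRUE(batch)),
            class = "unresqa_config")
}

#' Initialize a network
#'
#' All-connected weights drawn uniformly in \[-0.5, 0.5\] from a seeded
#' stream; each layer carries a bias node, so the block connecting a layer
#' of h1 nodes to one of h2 nodes has (h1+1) x h2 weights.  Momentum
#' buffers start at zero.
#'
#' @param n_in input dimension (>= 1).
#' @param cfg a [network_config()].
#' @param seed integer seed.
#' @return list of class `unresqa_net` with weight blocks `W1`
#'   ((n_in+1) x hl1), `W2` ((hl1+1) x hl2), `W3` ((hl2+1) x 1), momentum
#'   buffers `V1..V3`, and the activation slope `a`.
#' @export
init_network <- function(n_in, cfg = network_config(), seed = 1L) {
  stopifnot(n_in >= 1L)
  with_private_seed(seed, {
    W1 <- matrix(runif((n_in + 1L) * cfg$hl1, -0.5, 0.5), n_in + 1L, cfg$hl1)
    W2 <- matrix(runif((cfg$hl1 + 1L) * cfg$hl2, -0.5, 0.5),
                 cfg$hl1 + 1L, cfg$hl2)
    W3 <- matrix(runif(cfg$hl2 + 1L, -0.5, 0.5), cfg$hl2 + 1L, 1L)
    structure(list(W1 = W1, W2 = W2, W3 = W3,
                   V1 = W1 * 0, V2 = W2 * 0, V3 = W3 * 0, a = cfg$a,
                   n_in = as.integer(n_in)),
              class = "unresqa_net")
  })
}

#' Forward pass through a network
#'
#' Each layer appends a bias input of 1, multiplies by its weight block and
#' applies the bipolar activation `g(z) = tanh(a z)`; the output node uses
#' the same activation, so predictions lie in (-1, 1) -- the transformed
#' TM-score scale.
#'
#' @param net an `unresqa_net`.
#' @param x scaled feature vector, or a matrix with one row per decoy.
#' @return numeric prediction(s) in (-1, 1).
#' @export
nn_forward <- function(net, x) {
  X <- if (is.null(dim(x))) matrix(x, nrow = 1L) else as.matrix(x)
  if (ncol(X) != net$n_in)
    stop("input dimension ", ncol(X), " does not match network (", net$n_in, ")")
  drop(nn_forward_cpp(X, net$W1, net$W2, net$W3, net$a))
}

#' One backpropagation step with momentum
#'
#' Updates every weight block by `dw = -mu * d(e^2)/dw + P * dw_prev` for
#' the squared error against a single sample, where `dw_prev` is the
#' previous total update (momentum buffers stored in the network).
#'
#' @param net an `unresqa_net`.
#' @param x scaled feature vector.
#' @param target transformed TM-score in \[-1, 1\].
#' @param cfg a [network_config()] supplying `mu` and `momentum`.
#' @return the updated network, with attribute `sq_error` = squared error
#'   before the update.
#' @export
backprop_step <- function(net, x, target, cfg = network_config()) {
  if (length(x) != net$n_in) stop("input dimension mismatch")
  res <- nn_step_cpp(as.numeric(x), target, net$W1, net$W2, net$W3,
                     net$V1, net$V2, net$V3, net$a, cfg$mu, cfg$momentum)
  out <- net
  out[c("W1", "W2", "W3", "V1", "V2", "V3")] <-
    res[c("W1", "W2", "W3", "V1", "V2", "V3")]
  attr(out, "sq_error") <- res$sq_error
  out
}

# split targets into training / overfit-protection groups (all decoys of a
# target stay together); returns logical "in overfit set" per row
split_targets <- function(target_ids, fraction, seed) {
  u <- unique(target_ids)
  n_over <- max(1L, round(fraction * length(u)))
  if (n_over >= length(u))
    stop("overfit split would leave no training targets")
  over <- with_private_seed(seed, sample(u, n_over))
  target_ids %in% over
}

#' Train a single network
#'
#' Splits targets into training and overfit-protection partitions (grouping
#' all decoys of a target together), then runs steepest-descent
#' backpropagation with momentum: each epoch visits the training samples in
#' a fresh seeded random order, the sum of squared errors on the overfit
#' set is evaluated after every epoch, the best-so-far weights are kept,
#' and training stops after `n_stop` epochs without overfit-set improvement
#' or at `n_max` epochs.
#'
#' @param features scaled feature matrix (rows = decoys).
#' @param labels transformed TM-scores in \[-1, 1\].
#' @param target_ids character vector grouping rows into targets.
#' @param cfg a [network_config()].
#' @param seed integer seed (initialization, split and shuffles).
#' @return an `unresqa_net` (best-so-far weights) with attributes `history`
#'   (data.frame of per-epoch train/overfit SSE), `best_epoch`,
#'   `best_overfit_sse` and `overfit_targets`.
#' @export
train_network <- function(features, labels, target_ids, cfg = network_config(),
                          seed = 1L) {
  X <- as.matrix(features)
  y <- as.numeric(labels)
  stopifnot(nrow(X) == length(y), length(target_ids) == length(y))
  if (nrow(X) < 10L) stop("need at least 10 samples to train")
  if (any(abs(y) > 1)) stop("labels must lie in [-1, 1]")
  over <- split_targets(target_ids, cfg$overfit_fraction,
                        derive_seed(seed, "split"))
  net <- init_network(ncol(X), cfg, derive_seed(seed, "init"))
  res <- with_private_seed(derive_seed(seed, "shuffle"),
    nn_train_cpp(X, y, which(!over) - 1L, which(over) - 1L,
                 net$W1, net$W2, net$W3, cfg$a, cfg$mu, cfg$momentum,
                 cfg$n_max, cfg$n_stop, cfg$batch))
  net$W1 <- res$W1; net$W2 <- res$W2; net$W3 <- res$W3
  attr(net, "history") <- data.frame(epoch = seq_along(res$train_sse),
                                     train_sse = res$train_sse,
                                     overfit_sse = res$overfit_sse)
  attr(net, "best_epoch") <- res$best_epoch
  attr(net, "best_overfit_sse") <- res$best_overfit_sse
  attr(net, "overfit_targets") <- unique(target_ids[over])
  net
}
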