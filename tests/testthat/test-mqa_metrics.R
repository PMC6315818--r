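perfect_table <- function(tms, target = "T1")
  target_table(target, sprintf("m%02d", seq_along(tms)), tms,
               transform_tms(tms))

test_that("top-k mean TM-score ranks by score ascending", {
  t5 <- target_table("T1", paste0("m", 1:5),
                     tms = c(0.9, 0.8, 0.7, 0.6, 0.5),
                     score = c(1, 2, 3, 4, 5))
  expect_equal(top_k_mean_tms(t5, k = 5), 0.70)
  expect_equal(top_k_mean_tms(t5, k = 2), 0.85)
  # a perfect scorer selects the k largest tms values
  set.seed(1)
  tms <- runif(20, 0.2, 0.95)
  tp <- perfect_table(tms)
  expect_equal(top_k_mean_tms(tp, 5), mean(sort(tms, decreasing = TRUE)[1:5]))
  # constant tms: any ranking gives the constant
  tc <- target_table("T1", paste0("m", 1:6), rep(0.4, 6), rnorm(6))
  expect_equal(top_k_mean_tms(tc, 5), 0.4)
  expect_error(top_k_mean_tms(t5, k = 6), "exceeds")
})

test_that("per-target Pearson follows the reported sign convention", {
  set.seed(2)
  tms <- runif(15, 0.2, 0.9)
  expect_equal(pearson_per_target(perfect_table(tms)), 1)
  anti <- target_table("T1", paste0("m", 1:15), tms, transform_tms(1 - tms))
  expect_equal(pearson_per_target(anti), -1)
  # textbook-formula oracle on the 4-point table
  tb <- target_table("T1", paste0("m", 1:4),
                     tms = c(0.2, 0.4, 0.6, 0.8),
                     score = transform_tms(c(0.1, 0.5, 0.4, 0.9)))
  x <- c(0.2, 0.4, 0.6, 0.8); y <- c(0.1, 0.5, 0.4, 0.9)
  oracle <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  expect_equal(pearson_per_target(tb), oracle, tolerance = 1e-12)
  flat <- target_table("T1", paste0("m", 1:5), rep(0.5, 5), rnorm(5))
  expect_warning(r <- pearson_per_target(flat), "zero variance")
  expect_true(is.na(r))
})

test_that("directional accuracy distinguishes scorers and is null-centered", {
  set.seed(3)
  tms <- runif(20, 0.2, 0.95)
  expect_equal(directional_accuracy(perfect_table(tms)), 1)
  anti <- target_table("T1", paste0("m", 1:20), tms, -transform_tms(tms))
  expect_equal(directional_accuracy(anti), -1)
  expect_error(directional_accuracy(perfect_table(tms[1:10])), "at least 15")
  # random scores: mean DA within 3 standard errors of zero
  set.seed(4)
  das <- vapply(1:1000, function(k) {
    tt <- target_table("T1", sprintf("m%03d", 1:20),
                       runif(20, 0.1, 0.9), rnorm(20))
    directional_accuracy(tt)
  }, 0)
  expect_lt(abs(mean(das)), 3 / sqrt(1000))
})

test_that("second directional accuracy reproduces the ladder arithmetic", {
  tms <- seq(0.95, 0.25, by = -0.05)   # 15 models
  # perfect scorer: top5 mean minus mean of ranks 10-15
  hand <- mean(tms[1:5]) - mean(tms[10:15])
  expect_equal(hand, 0.475)
  expect_equal(second_directional_accuracy(perfect_table(tms)), hand)
  anti <- target_table("T1", sprintf("m%02d", 1:15), tms, -transform_tms(tms))
  expect_equal(second_directional_accuracy(anti), -hand)
  tc <- target_table("T1", sprintf("m%02d", 1:15), rep(0.5, 15), rnorm(15))
  expect_equal(second_directional_accuracy(tc), 0)
})

test_that("rank-based statistics are invariant under monotone score maps", {
  set.seed(5)
  tms <- runif(18, 0.15, 0.95)
  sc <- rnorm(18)
  t1 <- target_table("T1", sprintf("m%02d", 1:18), tms, sc)
  # DA2, top-k and PNA depend on scores only through ranks / pairwise
  # comparisons, so any strictly increasing map leaves them unchanged;
  # DA compares window *means*, so its guarantee is affine maps only
  t2 <- target_table("T1", sprintf("m%02d", 1:18), tms, exp(3 * sc) + 7)
  expect_identical(order(t1$score, t1$model), order(t2$score, t2$model))
  expect_equal(second_directional_accuracy(t1), second_directional_accuracy(t2))
  expect_equal(top_k_mean_tms(t1), top_k_mean_tms(t2))
  t3 <- target_table("T1", sprintf("m%02d", 1:18), tms, 4 * sc - 2)
  expect_equal(directional_accuracy(t1), directional_accuracy(t3))
  M <- random_tm_matrix(6, 21)
  p <- build_native_path(M)
  s1 <- setNames(rnorm(6), p$order)
  expect_equal(path_to_native_accuracy(p, s1),
               path_to_native_accuracy(p, exp(2 * s1) + 3))
})

# exhaustive greedy reference: explicit loop over a names vector
greedy_oracle <- function(M, native = "native") {
  ids <- rownames(M)
  path <- native; cur <- native
  unused <- setdiff(ids, native)
  steps <- c()
  while (length(unused)) {
    best <- -Inf; pick <- NULL
    for (u in sort(unused)) if (M[cur, u] > best) { best <- M[cur, u]; pick <- u }
    steps <- c(steps, best); path <- c(path, pick)
    unused <- setdiff(unused, pick); cur <- pick
  }
  list(order = path, mean = mean(steps), span = M[native, path[length(path)]])
}

test_that("greedy folding path matches the exhaustive oracle on small tables", {
  for (seed in 1:200) {
    k <- sample(3:7, 1)
    M <- random_tm_matrix(k, seed)
    p <- build_native_path(M)
    o <- greedy_oracle(M)
    expect_identical(p$order, o$order)
    expect_equal(p$mean, o$mean)
    expect_equal(p$span, o$span)
  }
})

test_that("folding path edge cases: single model, native duplicate, validation", {
  M1 <- matrix(c(1, 0.6, 0.6, 1), 2, 2,
               dimnames = list(c("native", "m1"), c("native", "m1")))
  p1 <- build_native_path(M1)
  expect_identical(p1$order, c("native", "m1"))
  expect_equal(p1$mean, 0.6)
  expect_equal(p1$span, 0.6)
  # an exact duplicate of the native (TMS 1) is selected first
  M <- random_tm_matrix(5, 9)
  M["native", "m02"] <- M["m02", "native"] <- 1
  expect_identical(build_native_path(M)$order[2], "m02")
  bad <- random_tm_matrix(4, 2); bad[1, 2] <- bad[1, 2] + 0.1
  expect_error(build_native_path(bad), "symmetric")
  expect_error(build_native_path(matrix(0.5, 2, 3)), "square")
})

test_that("path-to-native accuracy counts score consistency toward native", {
  M <- random_tm_matrix(6, 11)
  p <- build_native_path(M)
  ids <- p$order
  # strictly decreasing toward native
  sc_down <- setNames(seq_along(ids) - 1, ids)  # native lowest
  expect_equal(path_to_native_accuracy(p, sc_down), 1)
  expect_equal(path_to_native_accuracy(p, -sc_down), -1)
  # alternating up/down over 4 steps averages to zero
  M5 <- random_tm_matrix(5, 12)
  p5 <- build_native_path(M5)
  sc <- setNames(c(0, 1, 0, 1, 0)[match(p5$order, p5$order)], p5$order)
  expect_equal(path_to_native_accuracy(p5, sc), 0)
  # unscored native anchor: that step is skipped, others still counted
  expect_equal(path_to_native_accuracy(p, sc_down[-1]), 1)
  expect_error(path_to_native_accuracy(p, sc_down[-(2:3)]), "missing score")
})

test_that("aggregation conventions", {
  expect_equal(aggregate_metric(0.7), c(mean = 0.7, std = 0))
  expect_equal(aggregate_metric(c(1, -1)), c(mean = 0, std = sqrt(2)))
  set.seed(6)
  tabs <- lapply(1:5, function(k)
    perfect_table(runif(20, 0.2, 0.9), target = paste0("T", k)))
  rep <- evaluate_scoring(tabs)
  agg <- rep$aggregate
  expect_equal(agg$mean[agg$metric == "da"], 1)
  expect_equal(agg$std[agg$metric == "da"], 0)
  expect_true(all(rep$per_target$pearson > 1 - 1e-9))
})

test_that("scores shifted by a constant leave all metrics unchanged", {
  set.seed(7)
  tms <- runif(20, 0.2, 0.9); sc <- rnorm(20)
  t1 <- target_table("T1", sprintf("m%02d", 1:20), tms, sc)
  t2 <- target_table("T1", sprintf("m%02d", 1:20), tms, sc + 5)
  expect_equal(top_k_mean_tms(t1), top_k_mean_tms(t2))
  expect_equal(directional_accuracy(t1), directional_accuracy(t2))
  expect_equal(second_directional_accuracy(t1), second_directional_accuracy(t2))
})
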