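# independent brute-force superposition oracle: minimize rmsd over Euler
# angles by coarse grid plus Nelder-Mead refinement
brute_force_rmsd <- function(P, Q) {
  rot <- function(a) {
    cz <- cos(a[1]); sz <- sin(a[1]); cy <- cos(a[2]); sy <- sin(a[2])
    cx <- cos(a[3]); sx <- sin(a[3])
    Rz <- rbind(c(cz, -sz, 0), c(sz, cz, 0), c(0, 0, 1))
    Ry <- rbind(c(cy, 0, sy), c(0, 1, 0), c(-sy, 0, cy))
    Rx <- rbind(c(1, 0, 0), c(0, cx, -sx), c(0, sx, cx))
    Rz %*% Ry %*% Rx
  }
  Pc <- sweep(P, 2, colMeans(P)); Qc <- sweep(Q, 2, colMeans(Q))
  obj <- function(a) sqrt(mean(rowSums((Pc %*% t(rot(a)) - Qc)^2)))
  grid <- seq(0, 2 * pi, length.out = 7)[-7]
  best <- Inf; besta <- c(0, 0, 0)
  for (a1 in grid) for (a2 in grid) for (a3 in grid) {
    v <- obj(c(a1, a2, a3))
    if (v < best) { best <- v; besta <- c(a1, a2, a3) }
  }
  optim(besta, obj, method = "Nelder-Mead",
        control = list(reltol = 1e-14, maxit = 5000))$value
}

test_that("kabsch recovers exact rigid motions and matches the brute-force oracle", {
  P <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 2, 0), c(1, 1, 3))
  th <- pi / 2
  Rz <- rbind(c(cos(th), -sin(th), 0), c(sin(th), cos(th), 0), c(0, 0, 1))
  sup <- kabsch(P, P %*% t(Rz))
  expect_equal(sup$rmsd, 0, tolerance = 1e-10)
  expect_equal(det(sup$rotation), 1, tolerance = 1e-10)
  sup2 <- kabsch(P, sweep(P, 2, c(1, 2, 3), "+"))
  expect_equal(sup2$rotation, diag(3), tolerance = 1e-10)
  expect_equal(unname(sup2$translation), c(1, 2, 3), tolerance = 1e-10)
  expect_equal(sup2$rmsd, 0, tolerance = 1e-10)
  # noisy copy: least-squares optimum matches grid+refine minimization
  set.seed(41)
  Q <- P %*% t(Rz) + matrix(rnorm(12, sd = 0.3), 4, 3)
  expect_equal(kabsch(P, Q)$rmsd, brute_force_rmsd(P, Q), tolerance = 1e-3)
  expect_error(kabsch(P[1:2, ], P[1:2, ]), "3")
})

test_that("the superposition convention maps P onto Q", {
  set.seed(42)
  P <- matrix(rnorm(30), 10, 3)
  rig <- random_rigid(5)
  Q <- P %*% rig$R + rep(rig$t, each = 10)
  sup <- kabsch(P, Q)
  aligned <- P %*% sup$rotation + rep(sup$translation, each = 10)
  expect_equal(aligned, Q, tolerance = 1e-8)
})

test_that("TM-score: identity, rigid invariance, and input validation", {
  nat <- make_native(30, seed = 1)
  expect_equal(tm_score(nat, nat), 1)
  rot <- apply_rigid(nat, random_rigid(9))
  expect_equal(tm_score(rot, nat), 1, tolerance = 1e-9)
  expect_equal(tm_score(nat, rot), 1, tolerance = 1e-9)
  short <- make_native(16, seed = 2)
  expect_error(tm_score(nat, short), "differ")
  expect_error(tm_score(nat$ca[1:15, ], nat$ca[1:15, ]), "16")
  other <- make_native(30, seed = 3)
  expect_error(tm_score(nat, other), "sequences differ")
})

# reference implementation of the fragment-seed search: every contiguous
# fragment (stride 1), full iterative extension, pure R
tm_oracle <- function(P, Q) {
  L <- nrow(Q)
  d0 <- max(1.24 * (L - 15)^(1 / 3) - 1.8, 0.5)
  score_from <- function(idx) {
    s <- kabsch(P[idx, , drop = FALSE], Q[idx, , drop = FALSE])
    Pa <- P %*% s$rotation + rep(s$translation, each = L)
    d <- sqrt(rowSums((Pa - Q)^2))
    list(score = sum(1 / (1 + (d / d0)^2)) / L, d = d)
  }
  best <- 0
  for (lf in unique(pmax(c(L, L %/% 2, L %/% 4, 4), 4))) {
    for (start in 1:(L - lf + 1)) {
      idx <- start:(start + lf - 1)
      for (it in 1:30) {
        r <- score_from(idx)
        best <- max(best, r$score)
        cut <- d0
        nidx <- which(r$d < cut)
        while (length(nidx) < 3) { cut <- cut + 0.5; nidx <- which(r$d < cut) }
        if (identical(nidx, idx)) break
        idx <- nidx
      }
    }
  }
  best
}

test_that("TM-score matches the exhaustive-seed oracle", {
  nat <- make_native(20, seed = 31)
  # copy with every Ca displaced 100 A in alternating directions
  P <- nat$ca
  P[, 1] <- P[, 1] + 100 * rep_len(c(1, -1), 20)
  expect_equal(unresqa:::tm_score_cpp(P, nat$ca, max(1.24 * 5^(1/3) - 1.8, 0.5),
                            stride = 2L, max_iter = 30L),
               tm_oracle(P, nat$ca), tolerance = 1e-6)
  # moderately perturbed decoys at stride 1 equal the oracle exactly
  for (s in 1:3) {
    dec <- perturb_chain(nat, 0.3, seed = s)
    d0 <- max(1.24 * 5^(1/3) - 1.8, 0.5)
    expect_equal(unresqa:::tm_score_cpp(dec$ca, nat$ca, d0, 1L, 30L),
                 tm_oracle(dec$ca, nat$ca), tolerance = 1e-6)
  }
})

test_that("score transformation and its inverse", {
  expect_equal(transform_tms(1), -1)
  expect_equal(transform_tms(0.5), 0)
  expect_equal(transform_tms(0), 1)
  expect_error(transform_tms(1.2), "0, 1")
  expect_error(inverse_transform_tms(-1.5), "-1, 1")
  t <- seq(0, 1, by = 0.05)
  expect_equal(inverse_transform_tms(transform_tms(t)), t)
})

test_that("TM-score decreases in expectation with growing noise", {
  nat <- make_native(30, seed = 51)
  sig <- c(0.05, 0.2, 0.6, 1.5)
  means <- vapply(sig, function(s)
    mean(vapply(1:20, function(k)
      tm_score(perturb_chain(nat, s, seed = k), nat), 0)), 0)
  expect_true(all(diff(means) < 0))
})

test_that("heuristic asymmetry is bounded", {
  nat <- make_native(40, seed = 61)
  for (s in c(0.1, 0.4, 1)) {
    dec <- perturb_chain(nat, s, seed = 5)
    expect_lt(abs(tm_score(dec, nat) - tm_score(nat, dec)), 0.02)
  }
})

test_that("pairwise matrices are symmetric with unit diagonal", {
  nat <- make_native(25, seed = 71)
  chains <- list(native = nat,
                 a = perturb_chain(nat, 0.1, 1, id = "a"),
                 b = perturb_chain(nat, 0.5, 2, id = "b"))
  M <- pairwise_tm_matrix(chains)
  expect_equal(M, t(M))
  expect_equal(diag(M), c(native = 1, a = 1, b = 1))
  expect_true(all(M > 0 & M <= 1))
})
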