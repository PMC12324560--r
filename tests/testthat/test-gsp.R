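test_that("normalized Laplacian matches closed forms", {
  # complete graph K4: eigenvalues {0, 4/3, 4/3, 4/3}
  K4 <- matrix(1, 4, 4); diag(K4) <- 0
  gs <- graph_spectrum(normalized_laplacian(K4))
  expect_equal(gs$eigenvalues, c(0, 4 / 3, 4 / 3, 4 / 3), tolerance = 1e-10)
  # independent oracle: direct decomposition of the explicit matrix
  L_direct <- diag(4) - K4 / 3
  expect_equal(sort(eigen(L_direct, symmetric = TRUE)$values),
               gs$eigenvalues, tolerance = 1e-12)

  # path P2: {0, 2}
  P2 <- matrix(c(0, 1, 1, 0), 2, 2)
  expect_equal(graph_spectrum(normalized_laplacian(P2), cutoff = 1)$eigenvalues,
               c(0, 2), tolerance = 1e-12)

  # connected graph: nullspace eigenvector proportional to D^(1/2) 1
  A <- random_sc(15, seed = 2)
  L <- normalized_laplacian(A)
  gsA <- graph_spectrum(L)
  v <- gsA$eigenvectors[, 1]
  ref <- sqrt(rowSums(A)); ref <- ref / sqrt(sum(ref^2))
  expect_lt(min(max(abs(v - ref)), max(abs(v + ref))), 1e-8)

  # isolated node convention: L[i,i] = 1, off-diagonals 0
  Ai <- rbind(cbind(random_sc(4, seed = 3), 0), 0)
  Li <- normalized_laplacian(Ai)
  expect_equal(Li[5, ], c(0, 0, 0, 0, 1))

  expect_error(normalized_laplacian(matrix(0, 3, 3)), "all-zero")
  expect_error(normalized_laplacian(matrix(rnorm(9), 3, 3)), "symmetric")
})

test_that("spectrum is deterministic, bounded and reconstructs the Laplacian", {
  L <- normalized_laplacian(random_sc(50, seed = 4))
  gs <- graph_spectrum(L)
  expect_true(all(diff(gs$eigenvalues) >= -1e-10))
  expect_true(all(gs$eigenvalues >= -1e-8 & gs$eigenvalues <= 2 + 1e-8))
  U <- gs$eigenvectors
  expect_lt(max(abs(crossprod(U) - diag(50))), 1e-8)
  expect_lt(max(abs(U %*% diag(gs$eigenvalues) %*% t(U) - L)), 1e-8)
  expect_identical(gs, graph_spectrum(L))   # bitwise repeatable
  expect_equal(gs$cutoff, 25)
  expect_error(graph_spectrum(L, cutoff = 50), "cutoff")
})

test_that("GFT round trip, Parseval and harmonic selectivity hold", {
  gs <- random_spectrum(20, seed = 6)
  set.seed(9)
  X <- matrix(rnorm(30 * 20), 30, 20)
  xhat <- gft(X, gs)
  expect_lt(max(abs(igft(xhat, gs) - X)), 1e-10 * max(abs(X)))
  expect_equal(rowSums(X^2), rowSums(xhat^2), tolerance = 1e-10)
  # the k-th harmonic maps to the k-th standard basis vector
  co <- gft(matrix(gs$eigenvectors[, 7], 1), gs)
  expect_equal(as.numeric(co), replace(numeric(20), 7, 1), tolerance = 1e-10)
  expect_error(gft(matrix(0, 3, 5), gs), "regions")
})

test_that("graph PSD matches its loop oracle and concentrates per harmonic", {
  gs <- random_spectrum(10, seed = 12)
  set.seed(13)
  X <- matrix(rnorm(100 * 10), 100, 10)
  ps <- as.numeric(graph_psd(X, gs))
  Xc <- sweep(X, 2, colMeans(X))
  oracle <- sapply(1:10, function(k) {
    s <- 0
    for (t in 1:100) s <- s + sum(Xc[t, ] * gs$eigenvectors[, k])^2
    sqrt(s)
  })
  expect_lt(max(abs(ps - oracle) / oracle), 1e-12)

  # single-harmonic signal: PSD concentrated at that harmonic
  sig <- matrix(rnorm(200), 200, 1) %*% t(gs$eigenvectors[, 4])
  ps4 <- as.numeric(graph_psd(sig, gs))
  expect_gt(ps4[4] / sum(ps4), 0.99)
  expect_equal(as.numeric(graph_psd(matrix(0, 5, 10), gs)), numeric(10))
  # mean-square mode is the norm mode divided by sqrt(T)
  expect_equal(as.numeric(graph_psd(X, gs, mode = "mean_square")),
               ps / sqrt(100), tolerance = 1e-12)
})

test_that("graph filtering splits energy into complementary idempotent bands", {
  gs <- random_spectrum(24, seed = 20)
  set.seed(21)
  X <- matrix(rnorm(40 * 24), 40, 24)
  lo <- graph_filter(X, gs, "low")
  hi <- graph_filter(X, gs, "high")
  expect_lt(max(abs(lo + hi - X)), 1e-10 * max(abs(X)))
  expect_equal(sum(X^2), sum(lo^2) + sum(hi^2), tolerance = 1e-8)
  expect_lt(max(abs(graph_filter(lo, gs, "low") - lo)), 1e-10)
  # signal built from low harmonics only: high-pass output vanishes
  Xl <- matrix(rnorm(40 * gs$cutoff), 40) %*% t(gs$eigenvectors[, 1:gs$cutoff])
  expect_lt(max(abs(graph_filter(Xl, gs, "high"))), 1e-10)
  # default cutoff at R = 274 is 137
  expect_equal(random_spectrum(274, seed = 1)$cutoff, 137)
})

test_that("coupled/decoupled FC reduce correctly for band-limited signals", {
  gs <- random_spectrum(16, seed = 30)
  set.seed(31)
  Xl <- matrix(rnorm(200 * gs$cutoff), 200) %*% t(gs$eigenvectors[, 1:gs$cutoff])
  res <- suppressWarnings(coupled_decoupled_fc(Xl, gs))
  # no high content: coupled FC equals plain FC ...
  expect_lt(max(abs(res$coupled - pearson_fc(Xl))), 1e-8)
  # ... and decoupled entries fall to 0 by the degenerate-variance rule
  expect_true(all(res$decoupled_vec == 0))
  expect_length(res$coupled_vec, 16 * 15 / 2)
})

test_that("SDI matches the norm-ratio oracle and band constructions", {
  gs <- random_spectrum(12, seed = 40)
  set.seed(41)
  X <- matrix(rnorm(60 * 12), 60, 12)
  s <- as.numeric(sdi(X, gs))
  Xc <- sweep(X, 2, colMeans(X))
  lo <- graph_filter(Xc, gs, "low"); hi <- graph_filter(Xc, gs, "high")
  oracle <- sapply(1:12, function(r) sqrt(sum(hi[, r]^2)) / sqrt(sum(lo[, r]^2)))
  expect_lt(max(abs(s - oracle) / oracle), 1e-12)

  # pure low-band signal: SDI ~ 0 everywhere
  Xl <- matrix(rnorm(60 * gs$cutoff), 60) %*% t(gs$eigenvectors[, 1:gs$cutoff])
  expect_true(all(as.numeric(sdi(Xl, gs)) < 1e-6))

  # equal-energy coefficients across all harmonics: SDI centers on 1
  gs2 <- random_spectrum(300, seed = 42)
  set.seed(43)
  xh <- matrix(rnorm(500 * 300), 500, 300)
  s2 <- as.numeric(sdi(igft(xh, gs2), gs2))
  expect_lt(abs(mean(s2) - 1), 0.1)
  expect_lt(abs(median(s2) - 1), 0.1)

  # log2 option and degenerate low-energy cap
  expect_equal(as.numeric(sdi(X, gs, log2 = TRUE)), log2(s), tolerance = 1e-12)
  Xh <- matrix(rnorm(60 * (12 - gs$cutoff)), 60) %*%
    t(gs$eigenvectors[, (gs$cutoff + 1):12])
  expect_warning(sh <- sdi(Xh, gs, max_value = 99), "capped")
  expect_true(all(as.numeric(sh) == 99))
})

test_that("distance-binned consensus preserves the mean edge density", {
  spec <- cohort_spec(20, n_regions = 60, n_sessions = 1,
                      frames_per_session = 16, seed = 8)
  sc <- generate_sc(spec, noise_level = 0.4)
  cs <- consensus_sc(sc$subjects, sc$distances, n_bins = 10)
  expect_equal(cs, t(cs))
  expect_true(all(diag(cs) == 0) && all(cs >= 0))
  counts <- sapply(sc$subjects, function(a) sum(a[upper.tri(a)] > 0))
  out_count <- sum(cs[upper.tri(cs)] > 0)
  expect_lt(abs(out_count - mean(counts)) / mean(counts), 0.02)
  # nonzero pattern is a subset of the union of subject patterns
  union_mask <- Reduce(`|`, lapply(sc$subjects, function(a) a > 0))
  expect_true(all(union_mask[cs > 0]))

  # consensus of one subject is that subject; identical subjects pass through
  one <- consensus_sc(sc$subjects[1], sc$distances, n_bins = 10)
  expect_equal(one, sc$subjects[[1]])
  same <- consensus_sc(rep(sc$subjects[2], 5), sc$distances, n_bins = 10)
  expect_equal(same, sc$subjects[[2]])

  expect_error(consensus_sc(list()), "at least one")
  expect_warning(consensus_sc(sc$subjects[1:3], distances = NULL),
                 "single global bin")
})
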