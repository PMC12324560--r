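test_that("family-grouped splits keep families whole at the target size", {
  # singleton families, divisible case: exact test size
  ch <- data.frame(subject_id = sprintf("s%04d", 1:1000),
                   family_id = sprintf("f%04d", 1:1000))
  sp <- make_family_splits(ch, n_splits = 3, test_frac = 0.15, seed = 1)
  for (s in sp) {
    expect_length(s$test_ids, 150)
    expect_length(intersect(s$train_ids, s$test_ids), 0)
  }

  # mixed family sizes: no family straddles the split; sizes near 15%
  ch2 <- generate_cohort(cohort_spec(979, seed = 4))
  sizes <- unlist(lapply(1:10, function(seed) {
    sapply(make_family_splits(ch2, n_splits = 10, seed = seed), function(s) {
      fam_tr <- ch2$family_id[ch2$subject_id %in% s$train_ids]
      fam_te <- ch2$family_id[ch2$subject_id %in% s$test_ids]
      expect_length(intersect(fam_tr, fam_te), 0)
      length(s$test_ids)
    })
  }))
  expect_true(all(abs(sizes / 979 - 0.15) < 0.03))

  ch3 <- data.frame(subject_id = c("a", "b", "c"),
                    family_id = c("f1", "f1", "f1"))
  expect_error(make_family_splits(ch3), "single family")
})

test_that("fit_evaluate recovers realizable functions and stays honest on null", {
  set.seed(50)
  n <- 120
  ch <- data.frame(subject_id = sprintf("s%03d", 1:n),
                   family_id = sprintf("f%03d", 1:n))
  X <- matrix(rnorm(n * 5), n, 5, dimnames = list(ch$subject_id, NULL))
  y <- as.numeric(X %*% c(1, -2, 0.5, 3, -1))
  sp <- make_family_splits(ch, n_splits = 1, seed = 2)[[1]]
  # noiseless linear target: near-perfect test R^2
  res <- fit_evaluate(X, y, sp, "elastic_net", ch, seed = 1)
  expect_gt(res$metric, 0.99)
  # KRR solves the same problem
  expect_gt(fit_evaluate(X, y, sp, "krr", ch, seed = 1)$metric, 0.99)

  # target independent of features: R^2 distribution centered at/below zero
  sps <- make_family_splits(ch, n_splits = 10, seed = 3)
  null_m <- sapply(seq_along(sps), function(i) {
    set.seed(1000 + i)
    fit_evaluate(X, rnorm(n), sps[[i]], enet_small(), ch, seed = i)$metric
  })
  expect_lt(mean(null_m), 0.05)

  # perfectly separable binary target (unit margin): SVM accuracy 1
  Xm <- X
  Xm[, 1] <- X[, 1] + sign(X[, 1])   # open a gap around the boundary
  X <- Xm
  yb <- factor(ifelse(X[, 1] > 0, "a", "b"))
  expect_equal(fit_evaluate(X, yb, sp, "svm", ch, seed = 1)$metric, 1.0)
  expect_equal(fit_evaluate(X, yb, sp, "elastic_net_clf", ch, seed = 1)$metric, 1.0)

  # non-finite features are rejected with the offending subject named
  Xb <- X; Xb[3, 2] <- NA
  expect_error(fit_evaluate(Xb, y, sp, "elastic_net", ch, seed = 1), "s003")
  # task/target mismatches
  expect_error(bb_predict(X, y, ch, model = "svm"), "factor")
  expect_error(bb_predict(X, yb, ch, model = "krr"), "numeric")
})

test_that("the kernel ridge dual solution matches primal ridge", {
  set.seed(60)
  X <- matrix(rnorm(40 * 6), 40, 6)
  y <- rnorm(40)
  lambda <- 2.5
  # primal: (X'X + lambda I)^-1 X'y on centered y
  yc <- y - mean(y)
  beta <- solve(crossprod(X) + lambda * diag(6), crossprod(X, yc))
  primal <- as.numeric(X %*% beta) + mean(y)
  fit <- bbpredict:::fit_final(model_spec("krr"), X, y, list(lambda = lambda))
  dual <- bbpredict:::predict_final(model_spec("krr"), fit,
                                    list(lambda = lambda), X)
  expect_equal(dual, primal, tolerance = 1e-8)
})

test_that("permutation null has the right shape and consistency", {
  st <- simulate_study(tiny_spec(n = 40, r = 10, frames = 60, seed = 70),
                       effects = effect_spec("y", "sd", 0.4), features = "sd")
  ch <- st$cohort; X <- st$features$sd
  sps <- make_family_splits(ch, n_splits = 3, seed = 5)
  nm <- permutation_null(X, ch$y, sps, enet_small(), ch, n_perms = 4, seed = 9)
  expect_equal(dim(nm), c(3, 4))
  expect_true(all(is.finite(nm)))
  # n_perms = 0: empty null, significance unavailable
  fit0 <- bb_predict(X, "y", ch, model = enet_small(), n_splits = 2,
                     n_perms = 0, seed = 1)
  expect_true(is.na(fit0$p_value))
  # the identity permutation reproduces the real metric (same pipeline)
  real <- fit_evaluate(X, ch$y, sps[[1]], enet_small(), ch, seed = 11)$metric
  again <- fit_evaluate(X, ch$y[seq_len(nrow(ch))], sps[[1]], enet_small(),
                        ch, seed = 11)$metric
  expect_identical(real, again)
})

test_that("significance follows the 95th-percentile rule", {
  # real mean above all 1000 nulls
  s <- significance(rep(0.5, 10), rnorm(1000, 0, 0.05))
  expect_true(s$significant)
  expect_equal(s$p_value, 1 / 1001)
  # boundary: real mean equal to the 95th percentile is decided by strict >
  s2 <- significance(rep(0.5, 10), rep(0.5, 100))
  expect_false(s2$significant)
  expect_equal(s2$p_value, 1)
  s3 <- significance(0.4, c(0.1, 0.2, 0.39, 0.41))
  expect_equal(s3$p_value, 2 / 5)

  # type-I calibration: a real draw from the null rejects ~5% of the time
  set.seed(80)
  rej <- replicate(200, {
    nu <- rnorm(500)
    significance(rnorm(1), nu)$significant
  })
  expect_gt(mean(rej), 0.015)
  expect_lt(mean(rej), 0.10)
})

test_that("result summaries report the split statistics", {
  obj <- structure(list(feature = "fc", target = "y", model = "krr",
                        task = "regression",
                        per_split_metric = (1:10) / 10,
                        null_metrics = matrix(numeric(0), 0, 0),
                        p_value = 0.01, significant = TRUE),
                   class = "bb_prediction")
  s <- summary(obj)
  expect_equal(s$median, 0.55)
  expect_equal(s$q1, 0.325)     # type-7 quantiles
  expect_equal(s$q3, 0.775)
  obj$per_split_metric <- rep(0.4, 10)
  s2 <- summary(obj)
  expect_true(all(unlist(s2[c("mean", "median", "q1", "q3")]) == 0.4))
  expect_equal(s2$sd, 0)
  # empty result list gives an empty table with headers
  empty <- summarize_results(list())
  expect_equal(nrow(empty), 0)
  expect_true(all(c("feature", "mean", "p_value") %in% names(empty)))
  expect_equal(nrow(summarize_results(list(obj, obj))), 2)
})

test_that("nothing about the test set leaks into training decisions", {
  st <- simulate_study(tiny_spec(n = 50, r = 8, frames = 60, seed = 90),
                       effects = effect_spec("y", "sd", 0.5), features = "sd")
  ch <- st$cohort; X <- st$features$sd
  sp <- make_family_splits(ch, n_splits = 1, seed = 3)[[1]]
  res <- fit_evaluate(X, ch$y, sp, enet_small(), ch, seed = 7)
  # scramble the test subjects' feature rows
  X2 <- X
  set.seed(1)
  X2[sp$test_ids, ] <- X[sample(sp$test_ids), ]
  res2 <- fit_evaluate(X2, ch$y, sp, enet_small(), ch, seed = 7)
  expect_identical(res$scaler, res2$scaler)
  expect_identical(res$params, res2$params)

  # consensus SC built by the provider depends on training subjects only
  prov <- gsp_feature_provider(st$ts, st$sc$subjects, st$sc$distances,
                               "psd", n_bins = 5)
  sc2 <- st$sc$subjects
  sc2[[sp$test_ids[1]]] <- sc2[[sp$test_ids[1]]] * 2
  prov2 <- gsp_feature_provider(st$ts, sc2, st$sc$distances, "psd", n_bins = 5)
  expect_identical(prov(sp$train_ids)[sp$train_ids, ],
                   prov2(sp$train_ids)[sp$train_ids, ])
})

test_that("a full prediction run is bitwise reproducible for a fixed seed", {
  st <- simulate_study(tiny_spec(n = 40, r = 8, frames = 60, seed = 91),
                       effects = effect_spec("y", "sd", 0.5), features = "sd")
  f1 <- bb_predict(st$features$sd, "y", st$cohort, model = enet_small(),
                   n_splits = 3, n_perms = 5, seed = 12)
  f2 <- bb_predict(st$features$sd, "y", st$cohort, model = enet_small(),
                   n_splits = 3, n_perms = 5, seed = 12)
  expect_identical(f1[names(f1) != "details"], f2[names(f2) != "details"])
  expect_identical(f1$details, f2$details)
})
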