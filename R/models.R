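MODEL_NAMES <- c("elastic_net", "krr", "elastic_net_clf", "svm")

#' Model specification for the prediction pipeline
#'
#' Names one of the four model families and its hyperparameter grid, searched
#' by family-grouped inner cross-validation. Defaults: elastic net with
#' regularization strength on a 7-point log grid `1e-3..1e3` crossed with
#' mixing ratios 0.1/0.5/0.9; kernel ridge regression (linear kernel) and
#' linear SVM with the same 7-point log grid for the ridge penalty / cost.
#'
#' @param name `"elastic_net"` or `"krr"` (regression), `"elastic_net_clf"`
#'   or `"svm"` (classification).
#' @param hyper_grid named list overriding the default grid: `lambda` and
#'   `alpha` for the elastic nets, `lambda` for KRR, `cost` for SVM.
#' @param inner_folds number of inner CV folds (default 3).
#' @return Object of class `model_spec` with fields `name`, `task`,
#'   `hyper_grid`, `inner_folds`.
#' @export
model_spec <- function(name = MODEL_NAMES, hyper_grid = NULL,
                       inner_folds = 3L) {
  name <- match.arg(name)
  task <- if (name %in% c("elastic_net", "krr")) "regression" else "classification"
  loggrid <- 10^seq(-3, 3, length.out = 7L)
  grid <- switch(name,
    elastic_net = ,
    elastic_net_clf = list(lambda = loggrid, alpha = c(0.1, 0.5, 0.9)),
    krr = list(lambda = loggrid),
    svm = list(cost = loggrid))
  if (!is.null(hyper_grid)) grid[names(hyper_grid)] <- hyper_grid
  if (any(lengths(grid) == 0L)) stop("hyperparameter grid must be non-empty")
  structure(list(name = name, task = task, hyper_grid = grid,
                 inner_folds = as.integer(inner_folds)),
            class = "model_spec")
}

as_model_spec <- function(x) {
  if (inherits(x, "model_spec")) x else model_spec(x)
}

# ---- scaling helpers -------------------------------------------------------

fit_scaler <- function(X) {
  mu <- colMeans(X)
  sdv <- sqrt(colSums(sweep(X, 2L, mu)^2) / max(1L, nrow(X) - 1L))
  sdv[sdv == 0] <- 1
  list(center = mu, scale = sdv)
}

apply_scaler <- function(X, scaler)
  sweep(sweep(X, 2L, scaler$center), 2L, scaler$scale, "/")

r_squared <- function(y, yhat, baseline = c("test", "train"), train_mean = NULL) {
  baseline <- match.arg(baseline)
  ref <- if (baseline == "train") train_mean else mean(y)
  sst <- sum((y - ref)^2)
  if (sst == 0) return(NA_real_)
  1 - sum((y - yhat)^2) / sst
}

metric_value <- function(task, y, yhat, baseline = "test", train_mean = NULL) {
  if (task == "regression") r_squared(y, yhat, baseline, train_mean)
  else mean(as.character(y) == as.character(yhat))
}

# Family-grouped fold assignment: families shuffled, each assigned greedily
# to the currently smallest fold. Returns a fold index per observation.
group_folds <- function(families, k, seed) {
  fams <- unique(families)
  with_seed(seed, fams <- sample_vec(fams))
  sizes <- table(families)[fams]
  fold_of_fam <- integer(length(fams))
  load <- numeric(k)
  for (i in seq_along(fams)) {
    j <- which.min(load)
    fold_of_fam[i] <- j
    load[j] <- load[j] + sizes[i]
  }
  fold_of_fam[match(families, fams)]
}

# ---- per-family fitting ----------------------------------------------------

# Elastic net: one glmnet path per alpha; metrics for every lambda at once.
cv_elastic_net <- function(X, y, folds, grid, family, task) {
  lambdas <- sort(grid$lambda, decreasing = TRUE)
  res <- array(NA_real_, c(length(grid$alpha), length(lambdas), max(folds)))
  for (f in seq_len(max(folds))) {
    tr <- folds != f
    for (a in seq_along(grid$alpha)) {
      fit <- glmnet::glmnet(X[tr, , drop = FALSE], y[tr],
                            family = family, alpha = grid$alpha[a],
                            lambda = lambdas, standardize = FALSE)
      pred <- stats::predict(fit, X[!tr, , drop = FALSE], s = lambdas,
                             type = if (task == "regression") "response" else "class")
      for (l in seq_along(lambdas))
        res[a, l, f] <- metric_value(task, y[!tr], pred[, l])
    }
  }
  m <- apply(res, c(1L, 2L), mean, na.rm = TRUE)
  best <- arrayInd(which.max(t(m)), dim(t(m)))   # lambda varies fastest
  list(alpha = grid$alpha[best[1L, 2L]], lambda = lambdas[best[1L, 1L]])
}

krr_solve <- function(K, y, lambda) {
  eg <- eigen(K, symmetric = TRUE)
  vals <- pmax(eg$values, 0)
  function(lam) eg$vectors %*% ((crossprod(eg$vectors, y)) / (vals + lam))
}

cv_krr <- function(X, y, folds, grid) {
  lambdas <- grid$lambda
  res <- matrix(NA_real_, length(lambdas), max(folds))
  for (f in seq_len(max(folds))) {
    tr <- folds != f
    Xtr <- X[tr, , drop = FALSE]
    ymu <- mean(y[tr])
    solver <- krr_solve(tcrossprod(Xtr), y[tr] - ymu)
    Kte <- X[!tr, , drop = FALSE] %*% t(Xtr)
    for (l in seq_along(lambdas)) {
      pred <- as.numeric(Kte %*% solver(lambdas[l])) + ymu
      res[l, f] <- metric_value("regression", y[!tr], pred)
    }
  }
  list(lambda = lambdas[which.max(rowMeans(res, na.rm = TRUE))])
}

cv_svm <- function(X, y, folds, grid) {
  costs <- grid$cost
  res <- matrix(NA_real_, length(costs), max(folds))
  for (f in seq_len(max(folds))) {
    tr <- folds != f
    for (ci in seq_along(costs)) {
      fit <- e1071::svm(X[tr, , drop = FALSE], factor(y[tr]),
                        kernel = "linear", cost = costs[ci], scale = FALSE)
      pred <- stats::predict(fit, X[!tr, , drop = FALSE])
      res[ci, f] <- metric_value("classification", y[!tr], pred)
    }
  }
  list(cost = costs[which.max(rowMeans(res, na.rm = TRUE))])
}

select_hyperparams <- function(model, X, y, folds) {
  switch(model$name,
    elastic_net = cv_elastic_net(X, y, folds, model$hyper_grid,
                                 "gaussian", "regression"),
    elastic_net_clf = cv_elastic_net(X, as.integer(factor(y)) - 1L, folds,
                                     model$hyper_grid, "binomial",
                                     "classification"),
    krr = cv_krr(X, y, folds, model$hyper_grid),
    svm = cv_svm(X, y, folds, model$hyper_grid))
}

fit_final <- function(model, X, y, params) {
  switch(model$name,
    elastic_net = glmnet::glmnet(X, y, family = "gaussian",
                                 alpha = params$alpha,
                                 lambda = sort(model$hyper_grid$lambda,
                                               decreasing = TRUE),
                                 standardize = FALSE),
    elastic_net_clf = glmnet::glmnet(X, as.integer(factor(y)) - 1L,
                                     family = "binomial",
                                     alpha = params$alpha,
                                     lambda = sort(model$hyper_grid$lambda,
                                                   decreasing = TRUE),
                                     standardize = FALSE),
    krr = {
      ymu <- mean(y)
      list(Xtr = X, ymu = ymu,
           coef = krr_solve(tcrossprod(X), y - ymu)(params$lambda))
    },
    svm = e1071::svm(X, factor(y), kernel = "linear", cost = params$cost,
                     scale = FALSE))
}

predict_final <- function(model, fit, params, Xte, levels = NULL) {
  switch(model$name,
    elastic_net = as.numeric(stats::predict(fit, Xte, s = params$lambda)),
    elastic_net_clf = {
      cls <- as.integer(stats::predict(fit, Xte, s = params$lambda,
                                       type = "class"))
      levels[cls + 1L]
    },
    krr = as.numeric(Xte %*% t(fit$Xtr) %*% fit$coef) + fit$ymu,
    svm = as.character(stats::predict(fit, Xte)))
}
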