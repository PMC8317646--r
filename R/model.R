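#' Hyperparameter grids for the four regressor families
#'
#' Returns the grid explored by [grid_search_fit()] for a family, enumerated
#' in a fixed order (earlier rows win ties on the cross-validation score):
#'
#' * `ridge` (18 combinations): polynomial feature degree 1-3 and
#'   regularization penalty in `{1e-4, 1e-3, 1e-2, 1e-1, 10, 1e2}`;
#' * `random_forest` (18): 100/200/300 trees, 5/6/7 candidate features per
#'   split, maximum depth 6/7;
#' * `mlp` (24): 1/2 hidden layers of 3/4 neurons, relu/tanh activation,
#'   L2 penalty in `{1e-3, 1e-2, 1e-1}`;
#' * `svr` (60): linear/poly/rbf/sigmoid kernel, cost in
#'   `{2^-5, 2^-3, 2^-1, 2, 2^3}`, epsilon in `{1e-3, 1e-2, 1e-1}`.
#'
#' @param family one of `"ridge"`, `"random_forest"`, `"mlp"`, `"svr"`.
#' @return data.frame of hyperparameter combinations with attribute `family`.
#' @export
hyper_grid <- function(family = c("ridge", "random_forest", "mlp", "svr")) {
  family <- match.arg(family)
  g <- switch(family,
    ridge = expand.grid(degree = c(1L, 2L, 3L),
                        penalty = c(1e-4, 1e-3, 1e-2, 1e-1, 10, 1e2),
                        KEEP.OUT.ATTRS = FALSE),
    random_forest = expand.grid(num_trees = c(100L, 200L, 300L),
                                max_features = c(5L, 6L, 7L),
                                max_depth = c(6L, 7L),
                                KEEP.OUT.ATTRS = FALSE),
    mlp = expand.grid(hidden_layers = c(1L, 2L),
                      neurons = c(3L, 4L),
                      activation = c("relu", "tanh"),
                      penalty = c(1e-3, 1e-2, 1e-1),
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE),
    svr = expand.grid(kernel = c("linear", "poly", "rbf", "sigmoid"),
                      cost = 2^c(-5, -3, -1, 1, 3),
                      epsilon = c(1e-3, 1e-2, 1e-1),
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  )
  attr(g, "family") <- family
  g
}

#' Standardize feature columns with training statistics
#'
#' Learns per-column location (mean) and scale (standard deviation) from the
#' training rows only and applies them to the whole matrix, so no information
#' from the test rows leaks into the transform. A zero-variance column gets
#' scale 1 (it becomes all-zero rather than dividing by zero).
#'
#' @param X numeric matrix.
#' @param train_rows 1-based indices of the training rows.
#' @return List with `X` (the transformed matrix), `center` and `scale`.
#' @export
scale_columns <- function(X, train_rows) {
  X <- as.matrix(X)
  ctr <- colMeans(X[train_rows, , drop = FALSE])
  scl <- apply(X[train_rows, , drop = FALSE], 2, stats::sd)
  scl[scl < 1e-12] <- 1
  list(X = sweep(sweep(X, 2, ctr), 2, scl, "/"), center = ctr, scale = scl)
}

# -- polynomial ridge regression (closed form) -------------------------------

# Index sets of all monomials of total degree 1..degree over p features.
poly_terms <- function(p, degree) {
  out <- list()
  rec <- function(prefix, start, k) {
    if (k == 0) { out[[length(out) + 1]] <<- prefix; return(invisible()) }
    for (j in start:p) rec(c(prefix, j), j, k - 1)
  }
  for (k in seq_len(degree)) rec(integer(0), 1L, k)
  out
}

poly_expand <- function(X, degree) {
  if (degree == 1) return(X)
  terms <- poly_terms(ncol(X), degree)
  out <- vapply(terms, function(ix) {
    v <- X[, ix[1]]
    for (j in ix[-1]) v <- v * X[, j]
    v
  }, numeric(nrow(X)))
  colnames(out) <- vapply(terms, function(ix) paste(ix, collapse = "*"),
                          character(1))
  out
}

# Ridge with unpenalized intercept on polynomially expanded features.
fit_ridge <- function(X, y, degree, penalty) {
  Xe <- poly_expand(X, degree)
  ctr <- colMeans(Xe)
  Xc <- sweep(Xe, 2, ctr)
  ybar <- mean(y)
  A <- crossprod(Xc)
  diag(A) <- diag(A) + penalty
  beta <- solve(A, crossprod(Xc, y - ybar))
  list(beta = as.vector(beta), intercept = ybar - sum(ctr * beta),
       x_center = ctr, degree = degree)
}

predict_ridge <- function(model, X) {
  Xe <- poly_expand(X, model$degree)
  as.vector(Xe %*% model$beta) + model$intercept
}

# -- family dispatch ---------------------------------------------------------

svr_kernel <- c(linear = "linear", poly = "polynomial", rbf = "radial",
                sigmoid = "sigmoid")

# ranger interprets seed = 0 as "no seed"; shift so a pipeline seed of 0
# still gives reproducible forests.
ranger_seed <- function(seed) as.integer(seed) + 1L

fit_one <- function(family, params, X, y, seed) {
  switch(family,
    ridge = fit_ridge(X, y, params$degree, params$penalty),
    random_forest = ranger::ranger(
      x = X, y = y, num.trees = params$num_trees, mtry = params$max_features,
      max.depth = params$max_depth, seed = ranger_seed(seed), num.threads = 1
    ),
    mlp = mlp_fit(X, y, hidden = rep(params$neurons, params$hidden_layers),
                  activation = params$activation, alpha = params$penalty,
                  seed = seed, maxit = params$maxit %||% 100),
    svr = e1071::svm(x = X, y = y, type = "eps-regression",
                     kernel = svr_kernel[[params$kernel]], cost = params$cost,
                     epsilon = params$epsilon, scale = FALSE)
  )
}

predict_one <- function(family, model, X) {
  if (inherits(model, "constant_model"))
    return(rep(model$constant, nrow(X)))
  switch(family,
    ridge = predict_ridge(model, X),
    random_forest = stats::predict(model, data = X,
                                   num.threads = 1)$predictions,
    mlp = stats::predict(model, X),
    svr = as.vector(stats::predict(model, X))
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Contiguous (or seeded-shuffle) assignment of training rows to folds.
cv_folds <- function(train_rows, folds, shuffle = FALSE, seed = 0) {
  rows <- train_rows
  if (shuffle) rows <- with_seed(seed, sample(rows))
  split(rows, cut(seq_along(rows), folds, labels = FALSE))
}

#' Grid-search cross-validated fit of one regressor family
#'
#' Scores every hyperparameter combination of the family's grid by k-fold
#' cross-validation (mean squared error) on the training rows only, selects
#' the combination with the lowest mean CV error (ties broken by grid order),
#' refits it on the full training set, and predicts the test rows. Feature
#' columns are standardized with training-row statistics before any fit, so
#' the test rows never influence scaling, fold assignment or model selection.
#'
#' A combination whose fit fails (e.g. does not converge) is scored as worst
#' rather than aborting the search. All stochastic components (random forest
#' bootstrap, MLP initialization) are seeded with `seed`, making repeated runs
#' identical. For the random forest, the CV scores of the nested tree counts
#' at fixed `(max_features, max_depth)` are read off a single largest forest
#' per fold (its first `n` trees form the seeded `n`-tree forest); the
#' selected combination is refit with its exact tree count.
#'
#' @param family one of `"ridge"`, `"random_forest"`, `"mlp"`, `"svr"`.
#' @param X numeric feature matrix for the whole session (e.g. 360 x 7).
#' @param y numeric target vector (interpolated SPSL trace).
#' @param split list with 0-based `train` and `test` epoch indices, as
#'   returned by [make_split()].
#' @param folds number of cross-validation folds (default 5).
#' @param seed seed for all stochastic components (default 0).
#' @param shuffle shuffle training rows (with `seed`) before the contiguous
#'   fold assignment; off by default, giving deterministic contiguous folds.
#' @param grid hyperparameter grid (defaults to [hyper_grid()] for the
#'   family).
#' @param clip_predictions clip test predictions into the 1-5 SPSL scale
#'   (off by default).
#' @param mlp_maxit L-BFGS iteration cap for MLP fits (default 100; the 3-4 neuron networks converge well within it).
#' @return An object of class `stress_fit`: list with `family`, `cv` (the
#'   grid with a `cv_mse` column), `cv_per_fold` (combinations x folds matrix
#'   of held-out MSEs), `best` (named list of selected hyperparameters),
#'   `best_index`, `model`, `center`/`scale`, `split`, `predictions` (at the
#'   test rows) and `train_mse`.
#' @export
grid_search_fit <- function(family, X, y, split, folds = 5, seed = 0,
                            shuffle = FALSE, grid = NULL,
                            clip_predictions = FALSE, mlp_maxit = 100) {
  family <- match.arg(family, c("ridge", "random_forest", "mlp", "svr"))
  if (is.null(grid)) grid <- hyper_grid(family)
  X <- as.matrix(X)
  train_rows <- split$train + 1L
  test_rows <- split$test + 1L
  sc <- scale_columns(X, train_rows)
  Xs <- sc$X
  fold_rows <- cv_folds(train_rows, folds, shuffle = shuffle, seed = seed)

  cv_mse <- matrix(NA_real_, nrow(grid), folds)
  for (f in seq_len(folds)) {
    hold <- fold_rows[[f]]
    fit_rows <- setdiff(train_rows, hold)
    Xf <- Xs[fit_rows, , drop = FALSE]; yf <- y[fit_rows]
    Xh <- Xs[hold, , drop = FALSE]; yh <- y[hold]
    if (family == "random_forest") {
      groups <- unique(grid[, c("max_features", "max_depth")])
      for (gi in seq_len(nrow(groups))) {
        in_grp <- grid$max_features == groups$max_features[gi] &
          grid$max_depth == groups$max_depth[gi]
        big <- tryCatch(
          ranger::ranger(x = Xf, y = yf,
                         num.trees = max(grid$num_trees[in_grp]),
                         mtry = groups$max_features[gi],
                         max.depth = groups$max_depth[gi],
                         seed = ranger_seed(seed), num.threads = 1),
          error = function(e) NULL)
        for (ci in which(in_grp)) {
          cv_mse[ci, f] <- if (is.null(big)) Inf else
            mean((stats::predict(big, data = Xh, num.trees = grid$num_trees[ci],
                                 num.threads = 1)$predictions - yh)^2)
        }
      }
    } else {
      for (ci in seq_len(nrow(grid))) {
        params <- as.list(grid[ci, , drop = FALSE])
        params$maxit <- mlp_maxit
        cv_mse[ci, f] <- tryCatch({
          m <- fit_one(family, params, Xf, yf, seed)
          mean((predict_one(family, m, Xh) - yh)^2)
        }, error = function(e) Inf)
      }
    }
  }
  cv_per_fold <- cv_mse
  grid$cv_mse <- rowMeans(cv_mse)
  best_index <- which.min(grid$cv_mse)
  best <- as.list(grid[best_index, setdiff(names(grid), "cv_mse"),
                       drop = FALSE])
  best$maxit <- mlp_maxit
  Xtr <- Xs[train_rows, , drop = FALSE]
  # a degenerate refit (e.g. a support-vector machine on a constant target
  # ends up with no support vectors) falls back to a constant-mean model
  model <- tryCatch(fit_one(family, best, Xtr, y[train_rows], seed),
                    error = function(e)
                      structure(list(constant = mean(y[train_rows])),
                                class = "constant_model"))
  preds <- predict_one(family, model, Xs[test_rows, , drop = FALSE])
  if (clip_predictions) preds <- pmin(5, pmax(1, preds))
  if (!all(is.finite(preds))) stop("non-finite test predictions")
  train_mse <- mean((predict_one(family, model, Xtr) - y[train_rows])^2)
  best$maxit <- NULL
  structure(
    list(family = family, cv = grid, cv_per_fold = cv_per_fold, best = best,
         best_index = best_index, model = model, center = sc$center,
         scale = sc$scale, split = split, predictions = preds,
         train_mse = train_mse, seed = seed),
    class = "stress_fit"
  )
}

#' @export
print.stress_fit <- function(x, ...) {
  cat(sprintf("stress_fit [%s]: best CV MSE %.4f with %s\n", x$family,
              x$cv$cv_mse[x$best_index],
              paste(names(x$best), unlist(x$best), sep = "=", collapse = ", ")))
  invisible(x)
}

#' Write a human-readable fit report
#'
#' Serializes the outcome of a grid search as YAML: the family, the selected
#' hyperparameters, the full cross-validation table, the training error and
#' the test predictions.
#'
#' @param fit a `stress_fit`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_fit_report <- function(fit, path) {
  stopifnot(inherits(fit, "stress_fit"))
  yaml::write_yaml(list(
    family = fit$family,
    best_hyperparameters = fit$best,
    cv_table = lapply(seq_len(nrow(fit$cv)),
                      function(i) as.list(fit$cv[i, , drop = FALSE])),
    train_mse = fit$train_mse,
    test_predictions = as.numeric(fit$predictions)
  ), path)
  invisible(path)
}

#' Predict from a fitted stress regressor
#'
#' Applies the training-derived column scaling and the selected model to new
#' feature rows.
#'
#' @param object a `stress_fit`.
#' @param newdata feature matrix on the original (unscaled) feature scale.
#' @param ... unused.
#' @return Numeric vector of predictions.
#' @export
predict.stress_fit <- function(object, newdata, ...) {
  Xs <- sweep(sweep(as.matrix(newdata), 2, object$center), 2, object$scale, "/")
  predict_one(object$family, object$model, Xs)
}
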