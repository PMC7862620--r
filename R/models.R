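## Scoring models: published linear coefficient sets, multiple linear
## regression, epsilon-SVR (SMO), random forest, tenfold cross-validation,
## grid tuning and the one-term-at-a-time ablation protocol.

#' Linear scoring-function coefficients
#'
#' A named weight per descriptor term plus an intercept, i.e. the predicted
#' binding free energy is `sum_t w_t * x_t + c0` (kcal/mol).
#'
#' @param weights named numeric vector of per-term weights.
#' @param intercept intercept `c0` in kcal/mol.
#' @param id model identifier (provenance).
#' @return object of class `linear_coefficients`.
#' @export
linear_coefficients <- function(weights, intercept, id = "custom") {
  if (is.null(names(weights)) || any(!nzchar(names(weights))))
    stop("weights must be named by term")
  structure(list(weights = weights, intercept = intercept,
                 term_set = names(weights), id = id),
            class = "linear_coefficients")
}

#' @export
print.linear_coefficients <- function(x, ...) {
  cat(sprintf("<linear_coefficients '%s'>\n", x$id))
  print(c(x$weights, c0 = x$intercept))
  invisible(x)
}

#' Load a shipped scoring-function coefficient set
#'
#' The package ships the published multiple-linear-regression coefficient
#' sets as human-readable JSON: `"general-random"` and `"general-all"`
#' (trained on diverse complexes), `"protease"` (protease-specific),
#' `"ippi"` (protein-protein-interaction inhibitors, two solvation terms)
#' and `"ippi-onesolv"` (the 5-term merged-solvation layout).
#'
#' @param id one of the model identifiers above.
#' @return a [linear_coefficients()] object.
#' @examples
#' predict_linear(c(E_coul = 0, E_vdW = 0, E_lipo = 0, E_entropy = 0,
#'                  E_polar_solv = 0, E_np_solv = 0),
#'                published_model("general-random"))  # the intercept
#' @export
published_model <- function(id = c("general-random", "general-all",
                                   "protease", "ippi", "ippi-onesolv")) {
  id <- match.arg(id)
  path <- system.file("extdata", "models", paste0(id, ".json"),
                      package = "plscore", mustWork = TRUE)
  read_linear_model(path)
}

#' Read a linear model from JSON
#' @param path JSON file with fields `id`, `terms`, `weights`, `intercept`.
#' @return a [linear_coefficients()] object.
#' @export
read_linear_model <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  w <- unlist(j$weights)[j$terms]
  linear_coefficients(w, j$intercept, id = j$id)
}

#' Write a linear model to JSON
#' @param coef a [linear_coefficients()] object.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_linear_model <- function(coef, path) {
  jsonlite::write_json(
    list(id = coef$id, terms = coef$term_set,
         weights = as.list(coef$weights), intercept = coef$intercept),
    path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Apply a linear scoring function to descriptors
#'
#' @param desc a named numeric vector (e.g. a `descriptor_vector`), or a data
#'   frame / matrix with one column per term and one row per complex.
#' @param coef a [linear_coefficients()] object.
#' @return predicted binding free energy (kcal/mol), one value per row.
#' @export
predict_linear <- function(desc, coef) {
  stopifnot(inherits(coef, "linear_coefficients"))
  if (is.null(dim(desc))) desc <- t(as.matrix(desc))
  desc <- as.data.frame(desc)
  missing_terms <- setdiff(coef$term_set, names(desc))
  if (length(missing_terms) > 0L)
    stop("descriptor vector is missing term(s): ",
         paste(missing_terms, collapse = ", "))
  x <- as.matrix(desc[coef$term_set])
  drop(x %*% coef$weights[coef$term_set]) + coef$intercept
}

#' Fit a multiple linear regression scoring function
#'
#' Ordinary least squares of the target free energies on the descriptor
#' columns, with an implicit intercept.
#'
#' @param features data frame or matrix of descriptor columns (any
#'   `complex_id` / `dG_exp` columns are ignored).
#' @param targets experimental free energies, kcal/mol.
#' @param id identifier stored on the result.
#' @return a [linear_coefficients()] object.
#' @export
fit_mlr <- function(features, targets, id = "mlr") {
  X <- as_feature_matrix(features)
  if (nrow(X) <= ncol(X)) stop("need more observations than terms")
  fit <- stats::lm.fit(cbind(`(Intercept)` = 1, X), targets)
  if (fit$rank < ncol(X) + 1L)
    stop("rank-deficient design matrix (collinear or constant column)")
  co <- fit$coefficients
  linear_coefficients(co[-1], unname(co[1]), id = id)
}

#' Model specification for the nonlinear learners
#'
#' @param algorithm `"mlr"`, `"svr"` or `"rf"`.
#' @param C SVR complexity parameter (box constraint).
#' @param epsilon SVR insensitive-loss half-width.
#' @param kernel SVR kernel: `"rbf"` (`exp(-gamma ||x-y||^2)`) or `"puk"`
#'   (Pearson VII universal kernel with `sigma`, `omega`).
#' @param gamma rbf kernel width.
#' @param sigma,omega puk kernel parameters.
#' @param num_trees,num_features random-forest size and per-split feature
#'   subset (`numTrees`, `numFeatures`).
#' @param min_node minimum node size before a forest node becomes a leaf.
#' @param bootstrap bootstrap-resample each tree's training set.
#' @param standardize z-score features before fitting; default `TRUE` for
#'   SVR, `FALSE` otherwise (scaler is stored in the model).
#' @param seed integer seed for all stochastic steps.
#' @return object of class `model_spec`.
#' @export
model_spec <- function(algorithm = c("mlr", "svr", "rf"),
                       C = 1, epsilon = 0.01,
                       kernel = c("rbf", "puk"), gamma = 0.1,
                       sigma = 1, omega = 1,
                       num_trees = 500L, num_features = 2L,
                       min_node = 5L, bootstrap = TRUE,
                       standardize = NULL, seed = 1L) {
  algorithm <- match.arg(algorithm)
  kernel <- match.arg(kernel)
  stopifnot(C > 0, epsilon > 0, gamma > 0, sigma > 0, omega > 0,
            num_trees >= 1, num_features >= 1)
  if (is.null(standardize)) standardize <- algorithm == "svr"
  structure(list(algorithm = algorithm, C = C, epsilon = epsilon,
                 kernel = kernel, gamma = gamma, sigma = sigma,
                 omega = omega, num_trees = as.integer(num_trees),
                 num_features = as.integer(num_features),
                 min_node = as.integer(min_node), bootstrap = bootstrap,
                 standardize = standardize, seed = as.integer(seed)),
            class = "model_spec")
}

#' Kernel function evaluation
#'
#' Evaluates the SVR kernel between two point sets.  `rbf` is
#' `exp(-gamma ||x - y||^2)`; `puk` is the Pearson VII universal kernel
#' `1 / (1 + (2 sqrt(2^(1/omega) - 1) ||x - y|| / sigma)^2)^omega`.  Both
#' equal 1 at zero distance.
#'
#' @param X,Y numeric matrices with matching column count.
#' @param spec a [model_spec()] carrying the kernel parameters.
#' @return the `nrow(X) x nrow(Y)` kernel matrix.
#' @export
kernel_matrix <- function(X, Y, spec) {
  d2 <- outer(rowSums(X^2), rowSums(Y^2), "+") - 2 * X %*% t(Y)
  d2 <- pmax(d2, 0)
  if (spec$kernel == "rbf") {
    exp(-spec$gamma * d2)
  } else {
    h <- 2 * sqrt(2^(1 / spec$omega) - 1) / spec$sigma
    1 / (1 + h^2 * d2)^spec$omega
  }
}

standardizer <- function(X) {
  mu <- colMeans(X)
  sd <- apply(X, 2, stats::sd)
  sd[sd == 0] <- 1
  list(mu = mu, sd = sd,
       apply = function(Z) sweep(sweep(Z, 2, mu), 2, sd, "/"))
}

#' Fit an epsilon-insensitive support vector regression
#'
#' Solves the SVR dual with a sequential-minimal-optimization solver on the
#' precomputed kernel matrix.  Prediction errors smaller than `epsilon` are
#' ignored (the insensitive loss); `C` bounds the dual coefficients.
#'
#' @param features descriptor table (see [fit_mlr()]).
#' @param targets experimental free energies, kcal/mol.
#' @param spec a [model_spec()] with `algorithm = "svr"`.
#' @param tol SMO duality-gap tolerance.
#' @param max_iter SMO iteration cap; non-convergence is an error.
#' @return object of class `pl_svr` with a [predict][stats::predict] method.
#' @export
fit_svr <- function(features, targets, spec = model_spec("svr"),
                    tol = 1e-3, max_iter = 500000L) {
  stopifnot(spec$algorithm == "svr")
  X <- as_feature_matrix(features)
  sc <- if (spec$standardize) standardizer(X) else NULL
  Xs <- if (is.null(sc)) X else sc$apply(X)
  K <- kernel_matrix(Xs, Xs, spec)
  fit <- .svr_smo_cpp(K, as.numeric(targets), spec$C, spec$epsilon,
                      tol, as.integer(max_iter))
  if (!fit$converged && fit$iterations >= max_iter)
    stop(sprintf(paste0("SVR did not converge: gap %.3g after %d iterations",
                        " (C=%g, epsilon=%g, kernel=%s)"),
                 fit$gap, fit$iterations, spec$C, spec$epsilon, spec$kernel))
  structure(list(spec = spec, X = Xs, beta = fit$beta, b = fit$b,
                 scaler = sc, n = nrow(Xs),
                 terms = colnames(X), iterations = fit$iterations),
            class = "pl_svr")
}

#' @export
predict.pl_svr <- function(object, newdata, ...) {
  Xn <- as_feature_matrix(newdata)
  if (!is.null(object$terms) && !is.null(colnames(Xn)))
    Xn <- Xn[, object$terms, drop = FALSE]
  if (!is.null(object$scaler)) Xn <- object$scaler$apply(Xn)
  drop(kernel_matrix(Xn, object$X, object$spec) %*% object$beta) + object$b
}

#' Fit a random-forest scoring function
#'
#' Bagged CART regression trees: each tree is grown on a bootstrap resample
#' (optional) and each node split considers a random subset of
#' `num_features` descriptors.  The forest prediction is the arithmetic mean
#' of the per-tree predictions, which [predict.pl_rf()] can also return
#' per tree.
#'
#' @inheritParams fit_svr
#' @param spec a [model_spec()] with `algorithm = "rf"`.
#' @return object of class `pl_rf`.
#' @export
fit_rf <- function(features, targets, spec = model_spec("rf")) {
  stopifnot(spec$algorithm == "rf")
  X <- as_feature_matrix(features)
  y <- as.numeric(targets)
  if (spec$num_features > ncol(X))
    stop("config error: num_features exceeds the number of terms")
  sc <- if (spec$standardize) standardizer(X) else NULL
  Xs <- if (is.null(sc)) X else sc$apply(X)
  n <- nrow(Xs)
  trees <- with_seed(spec$seed, {
    tree_seeds <- sample.int(.Machine$integer.max, spec$num_trees)
    lapply(seq_len(spec$num_trees), function(t) {
      idx <- if (spec$bootstrap) sample.int(n, n, replace = TRUE)
             else seq_len(n)
      .rf_build_tree_cpp(Xs, y, idx - 1L, spec$num_features,
                         spec$min_node, tree_seeds[t])
    })
  })
  structure(list(spec = spec, trees = trees, scaler = sc,
                 terms = colnames(X), n = n),
            class = "pl_rf")
}

#' Predict from a random forest
#'
#' @param object a `pl_rf` model.
#' @param newdata descriptor table.
#' @param per_tree if `TRUE`, return the `n x num_trees` matrix of per-tree
#'   predictions instead of their mean.
#' @param ... unused.
#' @return predicted free energies, or the per-tree matrix.
#' @export
predict.pl_rf <- function(object, newdata, per_tree = FALSE, ...) {
  Xn <- as_feature_matrix(newdata)
  if (!is.null(object$terms) && !is.null(colnames(Xn)))
    Xn <- Xn[, object$terms, drop = FALSE]
  if (!is.null(object$scaler)) Xn <- object$scaler$apply(Xn)
  preds <- vapply(object$trees, function(tr) .rf_predict_tree_cpp(tr, Xn),
                  numeric(nrow(Xn)))
  if (is.null(dim(preds))) preds <- matrix(preds, nrow = nrow(Xn))
  if (per_tree) preds else rowMeans(preds)
}

fit_by_spec <- function(features, targets, spec) {
  switch(spec$algorithm,
         mlr = fit_mlr(features, targets),
         svr = fit_svr(features, targets, spec),
         rf = fit_rf(features, targets, spec))
}

predict_by_model <- function(model, features) {
  if (inherits(model, "linear_coefficients")) predict_linear(features, model)
  else stats::predict(model, features)
}

#' k-fold cross-validation of a scoring model
#'
#' Seeded random partition into `k` near-equal folds; each fold is predicted
#' by a model trained on the remaining folds, and Pearson R / RMSE are
#' computed per fold and averaged.
#'
#' @param features descriptor table.
#' @param targets experimental free energies.
#' @param spec a [model_spec()] selecting the learner.
#' @param k number of folds (default 10).
#' @param seed partition seed.
#' @param fit_fun,predict_fun optional overrides: `fit_fun(features,
#'   targets)` returning a model and `predict_fun(model, features)` returning
#'   predictions, used instead of `spec` (handy for oracle tests).
#' @return object of class `cv_result`: `per_fold_R`, `mean_R`,
#'   `per_fold_RMSE`, `mean_RMSE`, `fold_assignments`.
#' @export
kfold_cv <- function(features, targets, spec = model_spec("mlr"),
                     k = 10L, seed = 1L,
                     fit_fun = NULL, predict_fun = NULL) {
  X <- as.data.frame(as_feature_matrix(features))
  y <- as.numeric(targets)
  n <- nrow(X)
  if (n < k) stop("n < k: not enough observations for ", k, " folds")
  folds <- with_seed(seed, sample(rep_len(seq_len(k), n)))
  if (is.null(fit_fun)) {
    fit_fun <- function(f, t) fit_by_spec(f, t, spec)
    predict_fun <- predict_by_model
  }
  per_R <- per_RMSE <- numeric(k)
  for (f in seq_len(k)) {
    test <- folds == f
    model <- fit_fun(X[!test, , drop = FALSE], y[!test])
    pred <- predict_fun(model, X[test, , drop = FALSE])
    per_R[f] <- if (sum(test) >= 3 && stats::sd(pred) > 0 &&
                    stats::sd(y[test]) > 0)
      pearson_r(pred, y[test]) else NA_real_
    per_RMSE[f] <- rmse(pred, y[test])
  }
  structure(list(per_fold_R = per_R, mean_R = mean(per_R, na.rm = TRUE),
                 per_fold_RMSE = per_RMSE, mean_RMSE = mean(per_RMSE),
                 fold_assignments = folds, k = k),
            class = "cv_result")
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf("<cv_result: %d folds, mean R = %.3f, mean RMSE = %.3f>\n",
              x$k, x$mean_R, x$mean_RMSE))
  invisible(x)
}

#' Default hyperparameter tuning grids
#'
#' @return named list of grids for `"svr"` and `"rf"`, each a data frame of
#'   hyperparameter combinations understood by [tune_model()].
#' @export
default_grids <- function() {
  svr <- rbind(
    expand.grid(C = c(0.1, 1, 10, 100), epsilon = c(0.001, 0.01, 0.1),
                kernel = "rbf", gamma = c(0.01, 0.1, 1),
                sigma = NA, omega = NA, stringsAsFactors = FALSE),
    expand.grid(C = c(0.1, 1, 10, 100), epsilon = c(0.001, 0.01, 0.1),
                kernel = "puk", gamma = NA,
                sigma = c(0.5, 1, 3), omega = c(0.5, 1, 3),
                stringsAsFactors = FALSE))
  rf <- expand.grid(num_trees = c(100, 500, 1000), num_features = 1:6)
  list(svr = svr, rf = rf)
}

#' Grid-search model tuning by cross-validation
#'
#' Fits every row of the hyperparameter grid with [kfold_cv()] and selects
#' the winner by highest mean Pearson R, breaking ties by lowest mean RMSE
#' and then by grid order (simplest first).
#'
#' @param features,targets training table.
#' @param algorithm `"svr"` or `"rf"`.
#' @param grid data frame of hyperparameter rows; default from
#'   [default_grids()].
#' @param k,seed cross-validation settings.
#' @return list with `best_spec`, `best_model` (refit on all data),
#'   `results` (the grid with `mean_R`, `mean_RMSE` columns).
#' @export
tune_model <- function(features, targets, algorithm = c("svr", "rf"),
                       grid = NULL, k = 10L, seed = 1L) {
  algorithm <- match.arg(algorithm)
  if (is.null(grid)) grid <- default_grids()[[algorithm]]
  grid <- as.data.frame(grid)
  res_R <- res_RMSE <- numeric(nrow(grid))
  specs <- vector("list", nrow(grid))
  for (g in seq_len(nrow(grid))) {
    row <- grid[g, , drop = FALSE]
    args <- as.list(row[!vapply(row, function(v) is.na(v) || !nzchar(as.character(v)), TRUE)])
    args$algorithm <- algorithm
    args$seed <- seed
    spec <- do.call(model_spec, args)
    specs[[g]] <- spec
    cv <- kfold_cv(features, targets, spec, k = k, seed = seed)
    res_R[g] <- cv$mean_R
    res_RMSE[g] <- cv$mean_RMSE
  }
  ord <- order(-res_R, res_RMSE, seq_len(nrow(grid)))
  best <- ord[1]
  grid$mean_R <- res_R
  grid$mean_RMSE <- res_RMSE
  list(best_spec = specs[[best]],
       best_model = fit_by_spec(features, targets, specs[[best]]),
       results = grid)
}

#' One-term-at-a-time ablation selection
#'
#' Starting from the basic two-term function (Coulomb + van der Waals), each
#' candidate descriptor class is added one variant at a time; the variant
#' with the best cross-validated mean Pearson R wins its class, and the
#' final term set is the base plus the winner of every class.
#'
#' @param base_features data frame with the base term columns.
#' @param candidate_variants named list: class name to a named list of
#'   candidate columns (numeric vectors aligned with `base_features` rows).
#' @param targets experimental free energies.
#' @param k,seed cross-validation settings.
#' @return list with `report` (one row per evaluated combination: class,
#'   variant, `mean_R`, `mean_RMSE`), `chosen` (named character: winning
#'   variant per class) and `final_features` (base plus winners).
#' @export
ablation_selection <- function(base_features, candidate_variants, targets,
                               k = 10L, seed = 1L) {
  base_features <- as.data.frame(base_features)
  report <- list()
  chosen <- character(0)
  final <- base_features
  for (cls in names(candidate_variants)) {
    variants <- candidate_variants[[cls]]
    if (length(variants) == 0L) {
      warning("empty candidate class skipped: ", cls)
      next
    }
    best_R <- -Inf; best_RMSE <- Inf; best_name <- NULL; best_col <- NULL
    for (vn in names(variants)) {
      feats <- cbind(base_features, stats::setNames(
        data.frame(variants[[vn]]), vn))
      cv <- kfold_cv(feats, targets, model_spec("mlr"), k = k, seed = seed)
      report[[length(report) + 1L]] <-
        data.frame(class = cls, variant = vn, mean_R = cv$mean_R,
                   mean_RMSE = cv$mean_RMSE, stringsAsFactors = FALSE)
      better <- cv$mean_R > best_R ||
        (cv$mean_R == best_R && cv$mean_RMSE < best_RMSE)
      if (better) {
        best_R <- cv$mean_R; best_RMSE <- cv$mean_RMSE
        best_name <- vn; best_col <- variants[[vn]]
      }
    }
    chosen[cls] <- best_name
    final <- cbind(final, stats::setNames(data.frame(best_col), best_name))
  }
  list(report = do.call(rbind, report), chosen = chosen,
       final_features = final)
}

#' Save a trained model to a directory
#'
#' Linear models are written as human-readable JSON; nonlinear models use R
#' native serialization with a JSON metadata sidecar.
#'
#' @param model a `linear_coefficients`, `pl_svr` or `pl_rf` object.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
save_model <- function(model, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  if (inherits(model, "linear_coefficients")) {
    write_linear_model(model, file.path(dir, "model.json"))
  } else {
    saveRDS(model, file.path(dir, "model.rds"))
    jsonlite::write_json(
      list(class = class(model)[1], algorithm = model$spec$algorithm,
           n_train = model$n, terms = model$terms,
           seed = model$spec$seed),
      file.path(dir, "metadata.json"), auto_unbox = TRUE, pretty = TRUE)
  }
  invisible(dir)
}
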