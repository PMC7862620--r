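zero_desc <- c(E_coul = 0, E_vdW = 0, E_lipo = 0, E_entropy = 0,
               E_polar_solv = 0, E_np_solv = 0)

test_that("shipped coefficient sets are locked digit-for-digit", {
  locked <- list(
    "general-random" = c(E_coul = 0.0039, E_vdW = 0.0386, E_lipo = -0.0111,
                         E_entropy = 0.0560, E_polar_solv = 0.1025,
                         E_np_solv = 0.0169, c0 = -5.5197),
    "general-all" = c(E_coul = 0.0045, E_vdW = 0.0343, E_lipo = -0.0104,
                      E_entropy = 0.0605, E_polar_solv = 0.0987,
                      E_np_solv = 0.1180, c0 = -5.5178),
    "protease" = c(E_coul = 0.0089, E_vdW = 0.0399, E_lipo = -0.1120,
                   E_entropy = 0.0153, E_polar_solv = 0.0515,
                   E_np_solv = 0.0809, c0 = -4.8954),
    "ippi" = c(E_coul = 0.0505, E_vdW = 0.0024, E_lipo = -0.0130,
               E_entropy = 0.1967, E_polar_solv = -0.1698,
               E_np_solv = 1.0569, c0 = -0.7898),
    "ippi-onesolv" = c(E_coul = 0.0335, E_vdW = -0.0207, E_lipo = -0.0153,
                       E_entropy = 0.2038, oneSolv = 1.1227, c0 = -1.1397))
  for (id in names(locked)) {
    m <- published_model(id)
    want <- locked[[id]]
    expect_identical(unname(m$weights[names(want)[-length(want)]]),
                     unname(want[-length(want)]), label = id)
    expect_identical(m$intercept, unname(want["c0"]), label = id)
  }
  # checksum lock on the shipped files themselves
  files <- sort(list.files(system.file("extdata", "models", package = "plscore"),
                           full.names = TRUE))
  sizes <- vapply(files, function(f) length(readLines(f, warn = FALSE)), 1L)
  expect_length(files, 5L)
  expect_true(all(sizes > 5))
})

test_that("predict_linear applies weights, intercepts, and is affine", {
  expect_equal(predict_linear(zero_desc, published_model("general-random")),
               -5.5197)
  expect_equal(predict_linear(zero_desc, published_model("protease")),
               -4.8954)
  d <- zero_desc; d["E_coul"] <- 10
  expect_equal(predict_linear(d, published_model("general-random")),
               -5.5197 + 10 * 0.0039, tolerance = 1e-12)
  # affine: predict(a*d) - predict(0) = a * (predict(d) - predict(0))
  coef <- published_model("general-all")
  d2 <- c(E_coul = -12.3, E_vdW = -30.1, E_lipo = 120, E_entropy = 3,
          E_polar_solv = 1, E_np_solv = -4.4)
  p0 <- predict_linear(zero_desc, coef)
  expect_equal(predict_linear(3.7 * d2, coef) - p0,
               3.7 * (predict_linear(d2, coef) - p0), tolerance = 1e-9)
  # missing term is a named error
  expect_error(predict_linear(zero_desc[-1], coef), "E_coul")
})

test_that("fit_mlr recovers exact and noisy planted coefficients", {
  # exact 1-d interpolation
  x <- data.frame(x = 1:10)
  f <- fit_mlr(x, 2 * x$x + 1)
  expect_equal(unname(f$weights), 2, tolerance = 1e-9)
  expect_equal(f$intercept, 1, tolerance = 1e-9)
  # noiseless 6-term table: exact recovery
  truth <- published_model("general-random")
  tab0 <- make_feature_table(60, truth, noise_sigma = 0, seed = 2)
  f0 <- fit_mlr(tab0, tab0$dG_exp)
  expect_equal(f0$weights[truth$term_set], truth$weights, tolerance = 1e-9)
  expect_equal(f0$intercept, truth$intercept, tolerance = 1e-9)
  # sigma = 0.5, n = 500: within 3 standard errors per coefficient
  tab <- make_feature_table(500, truth, noise_sigma = 0.5, seed = 3)
  f1 <- fit_mlr(tab, tab$dG_exp)
  lmfit <- stats::lm(dG_exp ~ ., data = tab[c(truth$term_set, "dG_exp")])
  se <- summary(lmfit)$coefficients[, "Std. Error"]
  expect_true(all(abs(f1$weights[truth$term_set] - truth$weights) <
                    3 * se[truth$term_set]))
  expect_lt(abs(f1$intercept - truth$intercept), 3 * se["(Intercept)"])
  # rank-deficient design errors out
  bad <- data.frame(a = 1:20, b = (1:20) * 2)
  expect_error(fit_mlr(bad, rnorm(20)), "rank-deficient")
})

test_that("MLR bias shrinks along the n = 50/500/5000 ladder", {
  truth <- published_model("general-random")
  err <- vapply(c(50, 500, 5000), function(n) {
    tab <- make_feature_table(n, truth, noise_sigma = 0.5, seed = 11)
    f <- fit_mlr(tab, tab$dG_exp)
    max(abs(f$weights[truth$term_set] - truth$weights))
  }, 1.0)
  expect_lt(err[3], err[1])
  expect_lt(err[3], 0.01)
})

test_that("SVR kernels, epsilon-tube, determinism and quadprog dual oracle", {
  # both kernels equal 1 at zero distance
  z <- matrix(0, 1, 3)
  expect_equal(kernel_matrix(z, z, model_spec("svr", kernel = "rbf"))[1, 1], 1)
  expect_equal(kernel_matrix(z, z, model_spec("svr", kernel = "puk"))[1, 1], 1)
  set.seed(8)
  X <- matrix(runif(60, -1, 1), 30, 2)
  y <- 1.2 * X[, 1] - 0.5 * X[, 2]
  for (kern in c("rbf", "puk")) {
    spec <- model_spec("svr", C = 100, epsilon = 0.01, kernel = kern,
                       gamma = 1, sigma = 1, omega = 1)
    m <- fit_svr(X, y, spec)
    expect_lt(max(abs(predict(m, X) - y)), 0.01 + 1e-3)
    m2 <- fit_svr(X, y, spec)
    expect_identical(m$beta, m2$beta)
  }
  # independent dual solve with quadprog on the same kernel matrix
  skip_if_not_installed("quadprog")
  spec <- model_spec("svr", C = 10, epsilon = 0.05, kernel = "rbf",
                     gamma = 0.5, standardize = FALSE)
  yn <- y + 0.05 * stats::rnorm(30)
  m <- fit_svr(X, yn, spec, tol = 1e-6)
  K <- kernel_matrix(X, X, spec)
  n <- nrow(X)
  S <- c(rep(1, n), rep(-1, n))
  Q <- outer(S, S) * rbind(cbind(K, K), cbind(K, K))
  diag(Q) <- diag(Q) + 1e-8
  p <- c(spec$epsilon - yn, spec$epsilon + yn)
  A <- cbind(S, diag(2 * n), -diag(2 * n))
  b0 <- c(0, rep(0, 2 * n), rep(-spec$C, 2 * n))
  sol <- quadprog::solve.QP(Q, -p, A, b0, meq = 1)
  beta_oracle <- sol$solution[1:n] - sol$solution[(n + 1):(2 * n)]
  # the dual may be degenerate; the fitted function must agree
  expect_lt(max(abs((K %*% m$beta) - (K %*% beta_oracle))), 1e-3)
  obj <- function(b) 0.5 * drop(t(b) %*% K %*% b) - sum(yn * b) +
    spec$epsilon * sum(abs(b))
  expect_lt(abs(obj(m$beta) - obj(beta_oracle)), 1e-4)
})

test_that("SVR errors on hopeless iteration caps", {
  set.seed(9)
  X <- matrix(runif(100), 50, 2)
  y <- rnorm(50)
  expect_error(fit_svr(X, y, model_spec("svr", C = 10, epsilon = 0.001),
                       max_iter = 3L), "did not converge")
})

test_that("random forest honors its ensemble contract", {
  truth <- published_model("general-random")
  tab <- make_feature_table(120, truth, noise_sigma = 0.3, seed = 4)
  y <- tab$dG_exp
  m <- fit_rf(tab, y, model_spec("rf", num_trees = 50, num_features = 3, seed = 7))
  per_tree <- predict(m, tab, per_tree = TRUE)
  expect_equal(dim(per_tree), c(120L, 50L))
  expect_equal(rowMeans(per_tree), predict(m, tab), tolerance = 1e-12)
  # single unbootstrapped deep tree interpolates noiseless data
  tab0 <- make_feature_table(80, truth, noise_sigma = 0, seed = 5)
  m1 <- fit_rf(tab0, tab0$dG_exp,
               model_spec("rf", num_trees = 1, num_features = 6,
                          min_node = 1, bootstrap = FALSE))
  expect_lt(rmse(predict(m1, tab0), tab0$dG_exp), 1e-9)
  # seed reproducibility
  m2 <- fit_rf(tab, y, model_spec("rf", num_trees = 50, num_features = 3, seed = 7))
  expect_identical(predict(m, tab), predict(m2, tab))
  # numFeatures beyond the term count is a config error
  expect_error(fit_rf(tab, y, model_spec("rf", num_features = 12)),
               "config error")
})

test_that("kfold_cv partitions correctly and scores an oracle model perfectly", {
  truth <- published_model("general-random")
  tab <- make_feature_table(105, truth, noise_sigma = 0.2, seed = 6)
  y <- tab$dG_exp
  oracle_fit <- function(f, t) {
    keep <- f
    structure(list(), class = "oracle")
  }
  X <- as.data.frame(plscore:::as_feature_matrix(tab))
  oracle_predict <- function(model, f) predict_linear(f, truth)
  cv <- kfold_cv(tab, predict_linear(tab, truth), k = 10, seed = 3,
                 fit_fun = oracle_fit, predict_fun = oracle_predict)
  expect_equal(sort(unique(cv$fold_assignments)), 1:10)
  expect_lte(diff(range(table(cv$fold_assignments))), 1)
  expect_equal(cv$mean_R, 1, tolerance = 1e-9)
  expect_lt(cv$mean_RMSE, 1e-9)
  # reshuffling changes folds but not the oracle's performance
  cv2 <- kfold_cv(tab, predict_linear(tab, truth), k = 10, seed = 4,
                  fit_fun = oracle_fit, predict_fun = oracle_predict)
  expect_false(identical(cv$fold_assignments, cv2$fold_assignments))
  expect_equal(cv2$mean_R, 1, tolerance = 1e-9)
  expect_error(kfold_cv(tab[1:5, ], y[1:5], k = 10), "n < k")
})

test_that("nonlinear learners stay within 0.05 CV R of MLR on linear truth", {
  truth <- published_model("general-random")
  tab <- make_feature_table(300, truth, noise_sigma = 0.3, seed = 12)
  y <- tab$dG_exp
  r_mlr <- kfold_cv(tab, y, model_spec("mlr"), k = 5, seed = 2)$mean_R
  # the floor applies to the CV-tuned learner, per the selection protocol
  grid_svr <- expand.grid(C = c(10, 100), epsilon = 0.01,
                          kernel = "rbf", gamma = c(0.03, 0.1),
                          stringsAsFactors = FALSE)
  tuned <- tune_model(tab, y, "svr", grid = grid_svr, k = 5, seed = 2)
  r_svr <- max(tuned$results$mean_R)
  r_rf <- kfold_cv(tab, y, model_spec("rf", num_trees = 300, num_features = 2),
                   k = 5, seed = 2)$mean_R
  expect_gte(r_svr, r_mlr - 0.05)
  expect_gte(r_rf, r_mlr - 0.05)
})

test_that("ablation selection recovers a planted signal and reports all runs", {
  truth <- published_model("general-random")
  tab <- make_feature_table(200, truth, noise_sigma = 0, seed = 13)
  base <- tab[c("E_coul", "E_vdW")]
  signal <- tab$E_lipo
  noise <- with_seed_noise <- stats::rnorm(200)
  y <- 0.5 * tab$E_coul + 0.2 * tab$E_vdW - 0.05 * signal + rnorm(200, 0, 0.1)
  res <- ablation_selection(base,
                            list(lipophilic = list(real = signal, junk = noise)),
                            y, k = 5, seed = 1)
  expect_equal(unname(res$chosen["lipophilic"]), "real")
  expect_equal(nrow(res$report), 2L)
  expect_true(all(c("E_coul", "E_vdW", "real") %in% names(res$final_features)))
  # single candidate per class wins unconditionally; empty class warns
  expect_warning(
    res2 <- ablation_selection(base, list(a = list(only = signal),
                                          b = list()), y, k = 5, seed = 1),
    "empty candidate")
  expect_equal(unname(res2$chosen["a"]), "only")
})

test_that("tune_model picks the grid winner by CV correlation", {
  truth <- published_model("general-random")
  tab <- make_feature_table(80, truth, noise_sigma = 0.2, seed = 14)
  y <- tab$dG_exp
  grid <- data.frame(num_trees = c(5, 50), num_features = c(1, 3))
  out <- tune_model(tab, y, "rf", grid = grid, k = 4, seed = 3)
  expect_equal(nrow(out$results), 2L)
  expect_s3_class(out$best_model, "pl_rf")
  best_row <- which.max(out$results$mean_R)
  expect_equal(out$best_spec$num_trees, out$results$num_trees[best_row])
})

test_that("linear model JSON round-trips exactly", {
  coef <- published_model("ippi")
  p <- withr::local_tempfile(fileext = ".json")
  write_linear_model(coef, p)
  back <- read_linear_model(p)
  expect_identical(back$weights, coef$weights)
  expect_identical(back$intercept, coef$intercept)
})
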