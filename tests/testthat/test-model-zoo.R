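make_design <- function(n, p, seed = 1) {
  with_seed(seed, matrix(rbinom(n * p, 1, 0.3), n, p))
}

test_that("elastic net recovers exact sparse signals in the OLS limit", {
  X <- make_design(200, 50)
  y <- 2 * X[, 17]
  m <- fit_model(model_spec("elastic_net", lambda = 0, mixing = 0.5), X, y)
  cf <- coef(m)
  expect_equal(cf[18], 2, tolerance = 1e-6)
  expect_lt(max(abs(cf[-c(1, 18)])), 1e-6)
  expect_equal(predict(m, X), y, tolerance = 1e-6)
})

test_that("heavy L1 shrinkage collapses to the intercept model", {
  X <- make_design(200, 50)
  y <- with_seed(2, 2 * X[, 17] + rnorm(200))
  m <- fit_model(model_spec("elastic_net", lambda = 1e3, mixing = 1), X, y)
  cf <- coef(m)
  expect_true(all(cf[-1] == 0))
  expect_equal(cf[1], mean(y), tolerance = 1e-6)
})

test_that("svr fits a smooth one-feature function to within epsilon", {
  x <- cbind(seq(0, 1, length.out = 30))
  y <- sin(2 * base::pi * x[, 1])
  m <- fit_model(model_spec("svr", kernel = "rbf", cost = 100,
                            epsilon = 0.01, gamma = 10), x, y)
  rmse <- sqrt(mean((predict(m, x) - y)^2))
  expect_lt(rmse, 0.01 + 0.01)
})

test_that("model fitting validates its inputs", {
  X <- make_design(10, 5)
  expect_error(fit_model(model_spec("elastic_net"), X, c(1, 2)), "rows")
  expect_error(fit_model(model_spec("elastic_net"), X[1:3, ], rep(1, 3)),
               "at least 5")
  expect_error(fit_model(model_spec("elastic_net"), X, c(rep(1, 9), NA)),
               "non-finite")
  expect_error(model_spec("elastic_net", mixing = 2), "mixing")
  expect_error(model_spec("svr", cost = -1), "cost")
  expect_error(model_spec("neural_net", hidden = c(8, 8, 8, 8)), "1-3")
})

test_that("neural-net training is bit-reproducible under a fixed seed", {
  X <- make_design(80, 30)
  y <- with_seed(3, X[, 1] * 1.5 - X[, 2] * X[, 3] + rnorm(80, sd = 0.05))
  spec <- model_spec("neural_net", hidden = c(16L, 8L), max_epochs = 200L,
                     seed = 7)
  a <- fit_model(spec, X, y)
  b <- fit_model(spec, X, y)
  expect_identical(a$par, b$par)
  expect_identical(predict(a, X), predict(b, X))
  expect_true(is.logical(a$converged))
  # a different init seed gives a different network
  c_ <- fit_model(model_spec("neural_net", hidden = c(16L, 8L),
                             max_epochs = 200L, seed = 8), X, y)
  expect_false(identical(a$par$W[[1]], c_$par$W[[1]]))
  # and it actually learns the signal
  expect_gt(1 - mean((predict(a, X) - y)^2) / var(y), 0.8)
})

test_that("deep-ensemble averaging is deterministic and shrinks variance", {
  X <- make_design(100, 20)
  y <- with_seed(11, X[, 1] - 0.5 * X[, 2] + rnorm(100, sd = 0.1))
  spec <- model_spec("neural_net", hidden = 16L, max_epochs = 150L,
                     n_ensemble = 3L, seed = 5)
  a <- fit_model(spec, X, y); b <- fit_model(spec, X, y)
  expect_length(a$members, 3L)
  expect_identical(predict(a, X), predict(b, X))
  # member nets differ (independent inits) but the average tracks them
  p1 <- predict(structure(c(list(spec = a$spec), a$members[[1]]),
                          class = "orbgap_model"), X)
  expect_false(identical(p1, predict(a, X)))
})

test_that("cross-validation reports honest out-of-fold scores", {
  # identifiable noiseless linear problem: out-of-fold R2 is essentially 1
  X <- make_design(200, 30, seed = 6)
  w <- with_seed(4, rnorm(30))
  lin <- as.numeric(X %*% w)
  strata <- rep(c("a", "b"), each = 100)
  res <- orbgap:::cv_xy(model_spec("elastic_net", lambda = 1e-6, mixing = 0),
                        X, lin, strata, 3, 1)
  expect_gt(res$mean_r2, 0.999)
  # pure-noise target cannot be predicted (n = 200 under the null)
  noise <- with_seed(5, rnorm(200))
  res_n <- orbgap:::cv_xy(model_spec("elastic_net", lambda = 1e-2, mixing = 0.5),
                          X, noise, strata, 3, 1)
  expect_lt(res_n$mean_r2, 0.1)
  # determinism of the full record interface
  rec <- generate_corpus(12, classes = c("alkene", "nitroso", "azo"), seed = 6)
  cfg <- featurizer_config("path", 512)
  ev1 <- cross_validate(model_spec("elastic_net"), cfg, rec, "lubo", k = 3, seed = 2)
  ev2 <- cross_validate(model_spec("elastic_net"), cfg, rec, "lubo", k = 3, seed = 2)
  expect_identical(ev1$fold_r2, ev2$fold_r2)
  expect_equal(ev1$k, 3L)
  expect_length(ev1$fold_r2, 3L)
  expect_error(cross_validate(model_spec("elastic_net"), cfg, rec, k = 1), "k")
})

test_that("degenerate folds are flagged and excluded, not averaged in", {
  rec <- generate_corpus(8, classes = c("alkene", "carbonyl"), seed = 9)
  X <- feature_matrix(rec$smiles, featurizer_config("path", 512))
  y <- rep(1, nrow(rec))   # constant target: every fold is degenerate
  w <- testthat::capture_warnings(
    res <- orbgap:::cv_xy(model_spec("elastic_net"), X, y, rec$class, 3, 1))
  expect_true(all(grepl("constant", w)))
  expect_gte(length(w), 1L)
  expect_true(all(res$flagged))
})

test_that("grid search scores every cell and applies the tie-break order", {
  rec <- generate_corpus(10, classes = c("alkene", "nitroso", "azo"), seed = 8)
  grid <- list(
    featurizers = list(featurizer_config("path", 512),
                       featurizer_config("circular", 512, radius = 2)),
    models = list(model_spec("elastic_net", lambda = 1e-3, mixing = 0.5),
                  model_spec("svr", kernel = "linear", cost = 1),
                  model_spec("neural_net", hidden = 16L, max_epochs = 100L)))
  gr <- grid_search(grid, rec, target = "lubo", k = 3, seed = 4, quiet = TRUE)
  expect_equal(nrow(gr$cells), 6L)
  expect_equal(dim(gr$matrix), c(2L, 3L))
  expect_true(all(is.finite(gr$cells$mean_r2) | gr$cells$failed))
  expect_s3_class(gr, "orbgap_grid")
  # best cell is the argmax of the finite cells
  expect_equal(gr$best$mean_r2, max(gr$cells$mean_r2, na.rm = TRUE))
  tf <- tempfile(fileext = ".csv")
  write_grid(gr, tf)
  expect_equal(nrow(read.csv(tf)), 6L)
})

test_that("on a noiseless sparse linear target linear and nn models agree", {
  # 5 active bits drawn from the well-populated columns of a real
  # fingerprint design; both families should essentially recover the truth
  rec <- generate_corpus(20, seed = 10)
  cfg <- featurizer_config("path", 512)
  X <- feature_matrix(rec$smiles, cfg)
  freq <- colMeans(X)
  active <- order(abs(freq - 0.5))[1:5]
  w <- with_seed(6, runif(5, 1, 2))
  y <- as.numeric(X[, active] %*% w)
  enet <- orbgap:::cv_xy(model_spec("elastic_net", lambda = 1e-4, mixing = 1),
                         X, y, rec$class, 3, 3)
  nn <- orbgap:::cv_xy(model_spec("neural_net", hidden = c(64L, 32L)),
                       X, y, rec$class, 3, 3)
  expect_gt(enet$mean_r2, 0.95)
  expect_gt(nn$mean_r2, 0.9)
  expect_lt(abs(enet$mean_r2 - nn$mean_r2), 0.1)
})

test_that("added label noise never improves validation accuracy", {
  base_rec <- generate_corpus(12, classes = c("alkene", "nitroso", "azo"),
                              noise_sd = 0, seed = 12)
  cfg <- featurizer_config("path", 512)
  X <- feature_matrix(base_rec$smiles, cfg)
  spec <- model_spec("elastic_net", lambda = 1e-3, mixing = 0.5)
  r2_at_noise <- vapply(c(0.05, 0.3), function(ns) {
    y <- with_seed(42, base_rec$lubo + rnorm(nrow(base_rec), sd = ns))
    orbgap:::cv_xy(spec, X, y, base_rec$class, 3, 7)$mean_r2
  }, 0)
  expect_gt(r2_at_noise[1], r2_at_noise[2])
})
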