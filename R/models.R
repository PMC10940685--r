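# Regression model zoo: elastic net (glmnet), epsilon-SVR (e1071) and a
# deterministic feed-forward neural network (1-3 hidden layers, full-batch
# Adam, fixed seed).  Cross-validation and the descriptor x model accuracy
# grid live here too.

#' Specify a regression model
#'
#' @param family `"elastic_net"`, `"svr"` or `"neural_net"`.
#' @param ... family hyperparameters.
#'   Elastic net: `lambda` (penalty strength, >= 0), `mixing` (L1 fraction in
#'   `[0, 1]`).  SVR: `kernel` (`"linear"`/`"rbf"`), `cost` (> 0), `epsilon`
#'   (>= 0), `gamma` (> 0, rbf only).  Neural net: `hidden` (1-3 layer
#'   sizes), `activation` (`"relu"`/`"tanh"`), `learning_rate`, `max_epochs`,
#'   `patience`, `seed`, `l2`.
#' @return an `orbgap_modelspec`.
#' @export
model_spec <- function(family = c("elastic_net", "svr", "neural_net"), ...) {
  family <- match.arg(family)
  opts <- list(...)
  spec <- switch(family,
    elastic_net = {
      s <- modifyList(list(lambda = 0.01, mixing = 0.5), opts)
      if (s$lambda < 0) stopf("lambda must be >= 0")
      if (s$mixing < 0 || s$mixing > 1) stopf("mixing must be in [0, 1]")
      s
    },
    svr = {
      s <- modifyList(list(kernel = "rbf", cost = 1, epsilon = 0.05,
                           gamma = 0.01), opts)
      if (!s$kernel %in% c("linear", "rbf")) stopf("kernel must be linear or rbf")
      if (s$cost <= 0) stopf("cost must be > 0")
      if (s$epsilon < 0) stopf("epsilon must be >= 0")
      if (s$kernel == "rbf" && s$gamma <= 0) stopf("gamma must be > 0")
      s
    },
    neural_net = {
      s <- modifyList(list(hidden = c(64L, 32L), activation = "relu",
                           learning_rate = 0.01, max_epochs = 600L,
                           patience = 60L, seed = 1L, l2 = 3e-3,
                           val_fraction = 0, skip = FALSE, center = TRUE,
                           lr_decay = TRUE, dropout = 0, swa = TRUE,
                           n_ensemble = 1L), opts)
      if (length(s$hidden) < 1L || length(s$hidden) > 3L)
        stopf("neural_net supports 1-3 hidden layers")
      if (!s$activation %in% c("relu", "tanh"))
        stopf("activation must be relu or tanh")
      s
    })
  structure(c(list(family = family), spec), class = "orbgap_modelspec")
}

modelspec_id <- function(spec) {
  switch(spec$family,
    elastic_net = sprintf("enet_l%g_m%g", spec$lambda, spec$mixing),
    svr = if (spec$kernel == "rbf")
            sprintf("svr_rbf_C%g_g%g", spec$cost, spec$gamma)
          else sprintf("svr_lin_C%g", spec$cost),
    neural_net = sprintf("nn_%s_%s_lr%g_l2%g%s", paste(spec$hidden, collapse = "x"),
                         spec$activation, spec$learning_rate, spec$l2,
                         if ((spec$n_ensemble %||% 1L) > 1L)
                           sprintf("_e%d", spec$n_ensemble) else ""))
}

# number of free hyperparameters, used for tie-breaking in grid search
modelspec_n_params <- function(spec) {
  switch(spec$family,
    elastic_net = 2L,
    svr = if (spec$kernel == "rbf") 3L else 2L,
    neural_net = 3L + length(spec$hidden))
}

#' Fit a regression model
#'
#' @param spec an `orbgap_modelspec`.
#' @param x numeric feature matrix (rows = observations).
#' @param y numeric response.
#' @return an `orbgap_model` (supports [predict()]); neural nets carry a
#'   `converged` flag.
#' @export
fit_model <- function(spec, x, y) {
  stopifnot(inherits(spec, "orbgap_modelspec"))
  x <- as.matrix(x)
  if (nrow(x) != length(y)) stopf("features rows (%d) != targets (%d)", nrow(x), length(y))
  if (nrow(x) < 5L) stopf("need at least 5 observations")
  if (!all(is.finite(x)) || !all(is.finite(y)))
    stopf("non-finite features or targets")
  fit <- switch(spec$family,
    elastic_net = fit_enet(spec, x, y),
    svr = fit_svr(spec, x, y),
    neural_net = {
      if ((spec$n_ensemble %||% 1L) > 1L) {
        # deep ensemble: average predictions of independently seeded nets
        members <- lapply(seq_len(spec$n_ensemble), function(e) {
          sp <- spec; sp$seed <- spec$seed + 1000L * (e - 1L)
          fit_mlp(sp, x, y)
        })
        list(members = members, ensemble = TRUE,
             converged = all(vapply(members, `[[`, TRUE, "converged")),
             n_features = ncol(x))
      } else fit_mlp(spec, x, y)
    })
  structure(c(list(spec = spec), fit), class = "orbgap_model")
}

fit_enet <- function(spec, x, y) {
  # descending path ending at the requested lambda stabilizes the
  # coordinate-descent solve, including the lambda -> 0 OLS limit
  lam <- spec$lambda
  path <- if (lam > 0) lam * c(100, 10, 1) else c(0.1, 0.01, 0)
  keep <- which(apply(x, 2L, function(col) stats::var(col) > 0))
  if (length(keep) < 2L) keep <- seq_len(min(2L, ncol(x)))
  g <- glmnet::glmnet(x[, keep, drop = FALSE], y, alpha = spec$mixing,
                      lambda = path, standardize = FALSE, thresh = 1e-10,
                      maxit = 1e6)
  list(object = g, s = lam, keep = keep, n_features = ncol(x))
}

fit_svr <- function(spec, x, y) {
  args <- list(x = x, y = y, type = "eps-regression", scale = FALSE,
               kernel = if (spec$kernel == "rbf") "radial" else "linear",
               cost = spec$cost, epsilon = spec$epsilon)
  if (spec$kernel == "rbf") args$gamma <- spec$gamma
  list(object = do.call(e1071::svm, args), n_features = ncol(x))
}

# --- neural network -------------------------------------------------------

# elementwise combine of two nested parameter lists with matching shape
mapply_params <- function(a, b, f) {
  if (is.list(a)) return(mapply(mapply_params, a, b,
                                MoreArgs = list(f = f), SIMPLIFY = FALSE))
  f(a, b)
}

act_fun <- function(name) {
  if (name == "relu") list(f = function(z) pmax(z, 0),
                           df = function(z, a) (z > 0) * 1)
  else list(f = tanh, df = function(z, a) 1 - a^2)
}

init_mlp <- function(sizes, activation, seed) {
  with_seed(seed, {
    W <- list(); b <- list()
    for (l in seq_len(length(sizes) - 1L)) {
      fan_in <- sizes[l]
      sdw <- if (activation == "relu") sqrt(2 / fan_in) else sqrt(1 / fan_in)
      W[[l]] <- matrix(rnorm(fan_in * sizes[l + 1L], sd = sdw),
                       fan_in, sizes[l + 1L])
      b[[l]] <- rep(0, sizes[l + 1L])
    }
    list(W = W, b = b)
  })
}

mlp_forward <- function(par, X, act) {
  L <- length(par$W)
  Z <- vector("list", L); A <- vector("list", L)
  cur <- X
  for (l in seq_len(L)) {
    Z[[l]] <- sweep(cur %*% par$W[[l]], 2L, par$b[[l]], `+`)
    A[[l]] <- if (l < L) act$f(Z[[l]]) else Z[[l]]
    cur <- A[[l]]
  }
  out <- cur[, 1L]
  # optional linear skip path: hidden stack models the nonlinear residual
  if (!is.null(par$w_skip)) out <- out + as.numeric(X %*% par$w_skip)
  list(Z = Z, A = A, out = out)
}

fit_mlp <- function(spec, x, y) {
  y_c <- mean(y); y_s <- sd(y); if (!is.finite(y_s) || y_s == 0) y_s <- 1
  yt <- (y - y_c) / y_s
  x_c <- if (isTRUE(spec$center)) colMeans(x) else numeric(ncol(x))
  x <- sweep(x, 2L, x_c)
  # internal validation split for early stopping (patience on held-out loss)
  n_all <- nrow(x)
  n_val <- if (spec$val_fraction > 0 && n_all >= 20L)
    max(3L, round(spec$val_fraction * n_all)) else 0L
  val_idx <- if (n_val > 0L)
    with_seed(spec$seed + 1L, sample.int(n_all, n_val)) else integer(0)
  x_val <- x[val_idx, , drop = FALSE]; y_val <- yt[val_idx]
  if (n_val > 0L) { x <- x[-val_idx, , drop = FALSE]; yt <- yt[-val_idx] }
  sizes <- c(ncol(x), spec$hidden, 1L)
  act <- act_fun(spec$activation)
  par <- init_mlp(sizes, spec$activation, spec$seed)
  if (isTRUE(spec$skip)) par$w_skip <- numeric(ncol(x))
  L <- length(par$W)
  n <- nrow(x)
  # Adam state
  mW <- lapply(par$W, function(w) w * 0); vW <- mW
  mb <- lapply(par$b, function(b) b * 0); vb <- mb
  ms <- par$w_skip * 0; vs <- ms
  b1 <- 0.9; b2 <- 0.999; eps <- 1e-8
  lr0 <- spec$learning_rate
  best_loss <- Inf; best_par <- par; stale <- 0L; converged <- FALSE
  # stochastic weight averaging over the tail of the decayed schedule
  swa_from <- if (isTRUE(spec$swa)) ceiling(0.6 * spec$max_epochs) else Inf
  swa_sum <- NULL; swa_n <- 0L
  drop_rng <- if (spec$dropout > 0)
    with_seed(spec$seed + 2L, sample.int(.Machine$integer.max, 1L)) else NULL
  for (t in seq_len(spec$max_epochs)) {
    lr <- if (isTRUE(spec$lr_decay))
      lr0 * (0.55 + 0.45 * cos(pi * t / spec$max_epochs)) else lr0
    fw <- mlp_forward(par, x, act)
    resid <- fw$out - yt
    monitor <- if (n_val > 0L)
      mean((mlp_forward(par, x_val, act)$out - y_val)^2)
    else mean(resid^2)
    if (monitor < best_loss - 1e-7) { best_loss <- monitor; best_par <- par; stale <- 0L }
    else {
      stale <- stale + 1L
      if (stale >= spec$patience && t < swa_from) { converged <- TRUE; break }
    }
    # backprop (optionally with dropout on the first hidden layer)
    drop_mask <- NULL
    if (spec$dropout > 0) {
      drop_mask <- with_seed(drop_rng + t, matrix(
        rbinom(n * ncol(fw$A[[1L]]), 1, 1 - spec$dropout) / (1 - spec$dropout),
        n, ncol(fw$A[[1L]])))
      fw$A[[1L]] <- fw$A[[1L]] * drop_mask
      if (L > 1L) {
        cur <- fw$A[[1L]]
        for (l in 2:L) {
          fw$Z[[l]] <- sweep(cur %*% par$W[[l]], 2L, par$b[[l]], `+`)
          fw$A[[l]] <- if (l < L) act$f(fw$Z[[l]]) else fw$Z[[l]]
          cur <- fw$A[[l]]
        }
        resid <- cur[, 1L] - yt
      }
    }
    delta <- matrix(2 * resid / n, n, 1L)
    g_skip <- if (isTRUE(spec$skip))
      as.numeric(crossprod(x, delta)) + spec$l2 * par$w_skip else NULL
    gW <- vector("list", L); gb <- vector("list", L)
    for (l in rev(seq_len(L))) {
      a_prev <- if (l == 1L) x else fw$A[[l - 1L]]
      gW[[l]] <- crossprod(a_prev, delta) + spec$l2 * par$W[[l]]
      gb[[l]] <- colSums(delta)
      if (l > 1L) {
        delta <- (delta %*% t(par$W[[l]])) * act$df(fw$Z[[l - 1L]], fw$A[[l - 1L]])
        if (l == 2L && !is.null(drop_mask)) delta <- delta * drop_mask
      }
    }
    for (l in seq_len(L)) {
      mW[[l]] <- b1 * mW[[l]] + (1 - b1) * gW[[l]]
      vW[[l]] <- b2 * vW[[l]] + (1 - b2) * gW[[l]]^2
      mb[[l]] <- b1 * mb[[l]] + (1 - b1) * gb[[l]]
      vb[[l]] <- b2 * vb[[l]] + (1 - b2) * gb[[l]]^2
      mhW <- mW[[l]] / (1 - b1^t); vhW <- vW[[l]] / (1 - b2^t)
      mhb <- mb[[l]] / (1 - b1^t); vhb <- vb[[l]] / (1 - b2^t)
      par$W[[l]] <- par$W[[l]] - lr * mhW / (sqrt(vhW) + eps)
      par$b[[l]] <- par$b[[l]] - lr * mhb / (sqrt(vhb) + eps)
    }
    if (isTRUE(spec$skip)) {
      ms <- b1 * ms + (1 - b1) * g_skip
      vs <- b2 * vs + (1 - b2) * g_skip^2
      par$w_skip <- par$w_skip -
        lr * (ms / (1 - b1^t)) / (sqrt(vs / (1 - b2^t)) + eps)
    }
    if (t >= swa_from) {
      if (is.null(swa_sum)) swa_sum <- rapply(par, function(z) z * 0, how = "replace")
      swa_sum <- mapply_params(swa_sum, par, `+`)
      swa_n <- swa_n + 1L
    }
  }
  if (swa_n > 0L) {
    best_par <- rapply(swa_sum, function(z) z / swa_n, how = "replace")
    converged <- TRUE
  }
  list(par = best_par, activation = spec$activation, y_center = y_c,
       y_scale = y_s, x_center = x_c, converged = converged,
       final_loss = best_loss, n_features = ncol(x))
}

#' @export
predict.orbgap_model <- function(object, newx, ...) {
  newx <- as.matrix(newx)
  if (ncol(newx) != object$n_features)
    stopf("feature dimension mismatch: model %d, input %d",
          object$n_features, ncol(newx))
  switch(object$spec$family,
    elastic_net = as.numeric(predict(object$object,
                                     newx[, object$keep, drop = FALSE],
                                     s = object$s)),
    svr = as.numeric(predict(object$object, newx)),
    neural_net = {
      if (isTRUE(object$ensemble)) {
        preds <- vapply(object$members, function(m) {
          act <- act_fun(m$activation)
          xc <- sweep(newx, 2L, m$x_center)
          mlp_forward(m$par, xc, act)$out * m$y_scale + m$y_center
        }, numeric(nrow(newx)))
        if (is.null(dim(preds))) mean(preds) else rowMeans(preds)
      } else {
        act <- act_fun(object$activation)
        xc <- sweep(newx, 2L, object$x_center)
        mlp_forward(object$par, xc, act)$out * object$y_scale + object$y_center
      }
    })
}

#' Model coefficients (elastic net)
#'
#' @param object fitted `orbgap_model` of the elastic-net family.
#' @param ... ignored.
#' @return numeric vector: intercept followed by one weight per feature bit.
#' @export
coef.orbgap_model <- function(object, ...) {
  if (object$spec$family != "elastic_net")
    stopf("coefficients are only available for elastic_net models")
  cf <- as.numeric(coef(object$object, s = object$s))
  full <- numeric(object$n_features + 1L)
  full[1L] <- cf[1L]
  full[object$keep + 1L] <- cf[-1L]
  full
}

# --- cross-validation ------------------------------------------------------

r_squared <- function(y, yhat) {
  ss_tot <- sum((y - mean(y))^2)
  if (ss_tot == 0) return(NA_real_)
  1 - sum((y - yhat)^2) / ss_tot
}

stratified_folds <- function(strata, k, seed) {
  with_seed(seed, {
    fold <- integer(length(strata))
    for (cls in unique(strata)) {
      idx <- which(strata == cls)
      idx <- idx[sample.int(length(idx))]
      fold[idx] <- rep_len(sample.int(k), length(idx))
    }
    fold
  })
}

# shared CV core on a precomputed design matrix
cv_xy <- function(spec, X, y, strata, k, seed) {
  fold <- stratified_folds(strata, k, seed)
  r2 <- rmse <- rep(NA_real_, k)
  flagged <- logical(k)
  for (f in seq_len(k)) {
    test <- fold == f
    if (sum(!test) < 5L || sum(test) < 1L) { flagged[f] <- TRUE; next }
    y_tr <- y[!test]
    if (stats::var(y_tr) == 0 || stats::var(y[test]) == 0) {
      flagged[f] <- TRUE
      warnf("fold %d has a (near-)constant target; excluded from the mean", f)
      next
    }
    m <- fit_model(spec, X[!test, , drop = FALSE], y_tr)
    pred <- predict(m, X[test, , drop = FALSE])
    r2[f] <- r_squared(y[test], pred)
    rmse[f] <- sqrt(mean((y[test] - pred)^2))
  }
  list(fold_r2 = r2, fold_rmse = rmse, flagged = flagged,
       mean_r2 = mean(r2[!flagged], na.rm = TRUE),
       sd_r2 = sd(r2[!flagged], na.rm = TRUE),
       mean_rmse = mean(rmse[!flagged], na.rm = TRUE))
}

#' Cross-validate a model/featurizer combination on a labeled dataset
#'
#' k-fold cross-validation with folds stratified by class tag; per-fold and
#' aggregate R-squared and RMSE.  Deterministic under `seed`.
#'
#' @param spec an `orbgap_modelspec`.
#' @param feat_config an `orbgap_featconfig`.
#' @param records labeled dataset (data.frame).
#' @param target `"hobo"` or `"lubo"`.
#' @param k number of folds (>= 2).
#' @param seed integer seed.
#' @return an `orbgap_evaluation`: fold metrics, `mean_r2`, `sd_r2`,
#'   `mean_rmse`, `k`, `seed`, `target`, spec and config.
#' @export
cross_validate <- function(spec, feat_config, records, target = c("hobo", "lubo"),
                           k = 5L, seed = 1L) {
  target <- match.arg(target)
  if (k < 2L) stopf("k must be >= 2")
  if (nrow(records) < 2L * k) stopf("need at least 2k records")
  X <- feature_matrix(records$smiles, feat_config)
  res <- cv_xy(spec, X, records[[target]], records$class, k, seed)
  structure(c(list(spec = spec, feat_config = feat_config, target = target,
                   k = k, seed = seed), res),
            class = "orbgap_evaluation")
}

# --- grid search -----------------------------------------------------------

#' Desk-scale model/descriptor grid
#'
#' The default grid pairs circular and path fingerprints at two sizes with
#' elastic-net, SVR and neural-net hyperparameter menus (~200 fitted model
#' configurations per target when cross-validated).  `full = TRUE` expands
#' the menus toward an exhaustive sweep.
#'
#' @param full expand bit sizes and hyperparameter menus.
#' @return list with `featurizers` (list of configs) and `models` (list of
#'   specs).
#' @export
default_grid <- function(full = FALSE) {
  bit_sizes <- if (full) c(512L, 1024L, 2048L, 4096L) else c(512L, 2048L)
  radii <- if (full) c(2L, 3L, 4L) else c(2L, 4L)
  feats <- list()
  for (b in bit_sizes) {
    for (r in radii)
      feats[[length(feats) + 1L]] <- featurizer_config("circular", b, radius = r)
    feats[[length(feats) + 1L]] <- featurizer_config("path", b)
  }
  models <- list()
  for (lam in if (full) 10^seq(-4, 0, by = 0.5) else c(1e-3, 1e-2, 1e-1))
    for (mx in if (full) seq(0, 1, by = 0.25) else c(0.25, 0.75))
      models[[length(models) + 1L]] <- model_spec("elastic_net", lambda = lam, mixing = mx)
  for (C in if (full) c(0.1, 1, 10, 100) else c(1, 10)) {
    models[[length(models) + 1L]] <- model_spec("svr", kernel = "linear", cost = C)
    for (g in if (full) c(0.001, 0.01, 0.1) else c(0.005, 0.05))
      models[[length(models) + 1L]] <- model_spec("svr", kernel = "rbf",
                                                  cost = C, gamma = g)
  }
  if (full) {
    for (h in list(32L, c(64L, 32L), c(96L, 48L, 24L), c(128L, 64L, 32L),
                   c(64L, 32L, 16L)))
      for (act in c("relu", "tanh"))
        for (lr in c(0.003, 0.01, 0.03))
          for (l2 in c(1e-3, 3e-3, 1e-2))
            models[[length(models) + 1L]] <-
              model_spec("neural_net", hidden = h, activation = act,
                         learning_rate = lr, l2 = l2)
  } else {
    models[[length(models) + 1L]] <- model_spec("neural_net", hidden = c(64L, 32L))
    models[[length(models) + 1L]] <- model_spec("neural_net", hidden = c(64L, 32L, 16L),
                                                l2 = 1e-2)
    models[[length(models) + 1L]] <- model_spec("neural_net", hidden = c(96L, 48L, 24L),
                                                dropout = 0.2)
    models[[length(models) + 1L]] <- model_spec("neural_net", hidden = c(64L, 32L, 16L),
                                                dropout = 0.2)
  }
  list(featurizers = feats, models = models)
}

#' Cross-validated accuracy grid over descriptor x model combinations
#'
#' Every combination of featurizer config and model spec is k-fold
#' cross-validated; cells hold the mean validation R-squared.  A failing
#' combination flags its cell instead of aborting the grid.  The best cell is
#' the argmax of mean R-squared, ties broken by the simpler family
#' (elastic_net < svr < neural_net) and then by fewer hyperparameters.
#'
#' @param grid list with `featurizers` and `models` (see [default_grid()]).
#' @param records labeled dataset.
#' @param target `"hobo"` or `"lubo"`.
#' @param k folds.
#' @param seed integer seed.
#' @param quiet suppress progress output.
#' @return an `orbgap_grid`: `cells` (data.frame), `matrix` (featurizers x
#'   models), `best` (featurizer config, model spec, mean R2), metadata.
#' @export
grid_search <- function(grid, records, target = c("hobo", "lubo"), k = 3L,
                        seed = 1L, quiet = FALSE) {
  target <- match.arg(target)
  feats <- grid$featurizers; models <- grid$models
  if (length(feats) == 0L || length(models) == 0L)
    stopf("grid must contain at least one featurizer and one model")
  mols <- lapply(records$smiles, parse_smiles)
  y <- records[[target]]
  fam_rank <- c(elastic_net = 1L, svr = 2L, neural_net = 3L)
  cells <- list()
  M <- matrix(NA_real_, length(feats), length(models),
              dimnames = list(vapply(feats, featconfig_id, ""),
                              vapply(models, modelspec_id, "")))
  for (fi in seq_along(feats)) {
    X <- feature_matrix(mols, feats[[fi]])
    if (!quiet) message(sprintf("featurizer %s (%d/%d)",
                                featconfig_id(feats[[fi]]), fi, length(feats)))
    for (mi in seq_along(models)) {
      # one shared fold assignment across cells: paired model comparison
      res <- tryCatch(
        cv_xy(models[[mi]], X, y, records$class, k, derive_seed(seed, "folds")),
        error = function(e) NULL)
      ok <- !is.null(res) && is.finite(res$mean_r2)
      if (ok) M[fi, mi] <- res$mean_r2
      cells[[length(cells) + 1L]] <- data.frame(
        featurizer = featconfig_id(feats[[fi]]),
        model = modelspec_id(models[[mi]]),
        family = models[[mi]]$family,
        mean_r2 = if (ok) res$mean_r2 else NA_real_,
        sd_r2 = if (ok) res$sd_r2 else NA_real_,
        mean_rmse = if (ok) res$mean_rmse else NA_real_,
        failed = !ok, stringsAsFactors = FALSE)
    }
  }
  cells <- do.call(rbind, cells)
  ok_idx <- which(!cells$failed)
  if (length(ok_idx) == 0L) stopf("every grid cell failed")
  n_par <- vapply(models, modelspec_n_params, 0L)
  fi_of <- rep(seq_along(feats), each = length(models))
  mi_of <- rep(seq_along(models), times = length(feats))
  key <- order(-cells$mean_r2,
               fam_rank[cells$family],
               n_par[mi_of],
               na.last = TRUE)
  best_row <- key[1L]
  structure(list(
    cells = cells, matrix = M,
    best = list(featurizer = feats[[fi_of[best_row]]],
                model = models[[mi_of[best_row]]],
                mean_r2 = cells$mean_r2[best_row]),
    target = target, k = k, seed = seed,
    dataset_checksum = content_checksum(records)),
    class = "orbgap_grid")
}

#' @export
print.orbgap_grid <- function(x, ...) {
  cat(sprintf("<orbgap_grid> %d featurizers x %d models, target %s\n",
              nrow(x$matrix), ncol(x$matrix), x$target))
  cat(sprintf("best: %s + %s (mean validation R2 = %.3f)\n",
              featconfig_id(x$best$featurizer), modelspec_id(x$best$model),
              x$best$mean_r2))
  invisible(x)
}

#' Export an accuracy grid as CSV
#'
#' @param grid an `orbgap_grid`.
#' @param path output CSV path (cells in long format).
#' @export
write_grid <- function(grid, path) {
  write.csv(grid$cells, path, row.names = FALSE)
  invisible(path)
}
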