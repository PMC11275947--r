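# Five reference regressors run on the concatenated view features. The
# environment this package targets ships no tree/SVM/NN modelling packages,
# so random forest and GBM run on an in-package CART regression tree, the
# RBF-kernel SVM is a least-squares SVM (closed-form kernel system), and the
# simple neural network reuses the package's MLP machinery.

# ---- CART regression tree (flat representation) ---------------------------
# Deterministic given the caller's RNG state (used for mtry sampling only).
cart_fit <- function(x, y, max_depth = 25L, min_node = 5L, mtry = ncol(x)) {
  n_cap <- 4L * length(y) + 4L
  feature <- integer(n_cap); threshold <- numeric(n_cap)
  left <- integer(n_cap); right <- integer(n_cap); value <- numeric(n_cap)
  n_nodes <- 1L
  stack <- list(list(idx = seq_along(y), depth = 0L, id = 1L))
  while (length(stack) > 0L) {
    fr <- stack[[length(stack)]]
    stack[[length(stack)]] <- NULL
    idx <- fr$idx
    yi <- y[idx]
    value[fr$id] <- mean(yi)
    feature[fr$id] <- 0L
    if (fr$depth >= max_depth || length(idx) < 2L * min_node ||
        stats::var(yi) == 0) next
    fs <- if (mtry < ncol(x)) sample.int(ncol(x), mtry) else seq_len(ncol(x))
    best <- list(score = -Inf, f = 0L, thr = NA_real_)
    for (f in fs) {
      xs <- x[idx, f]
      o <- order(xs)
      xo <- xs[o]; yo <- yi[o]
      csum <- cumsum(yo)
      tot <- csum[length(csum)]
      i <- seq_len(length(yo) - 1L)
      ok <- xo[i] < xo[i + 1L] & i >= min_node & (length(yo) - i) >= min_node
      if (!any(ok)) next
      i <- i[ok]
      score <- csum[i]^2 / i + (tot - csum[i])^2 / (length(yo) - i)
      j <- which.max(score)
      if (score[j] > best$score + 1e-12) {
        best <- list(score = score[j], f = f,
                     thr = (xo[i[j]] + xo[i[j] + 1L]) / 2)
      }
    }
    if (best$f == 0L) next
    go_left <- x[idx, best$f] <= best$thr
    lid <- n_nodes + 1L; rid <- n_nodes + 2L
    n_nodes <- n_nodes + 2L
    if (n_nodes > n_cap) {  # grow storage
      grow <- function(v) c(v, v * 0)
      feature <- grow(feature); threshold <- grow(threshold)
      left <- grow(left); right <- grow(right); value <- grow(value)
      n_cap <- 2L * n_cap
    }
    feature[fr$id] <- best$f
    threshold[fr$id] <- best$thr
    left[fr$id] <- lid
    right[fr$id] <- rid
    stack[[length(stack) + 1L]] <- list(idx = idx[go_left],
                                        depth = fr$depth + 1L, id = lid)
    stack[[length(stack) + 1L]] <- list(idx = idx[!go_left],
                                        depth = fr$depth + 1L, id = rid)
  }
  list(feature = feature[seq_len(n_nodes)],
       threshold = threshold[seq_len(n_nodes)],
       left = left[seq_len(n_nodes)], right = right[seq_len(n_nodes)],
       value = value[seq_len(n_nodes)])
}

cart_predict <- function(tree, x) {
  n <- nrow(x)
  out <- numeric(n)
  for (s in seq_len(n)) {
    node <- 1L
    while (tree$feature[node] > 0L) {
      node <- if (x[s, tree$feature[node]] <= tree$threshold[node]) {
        tree$left[node]
      } else tree$right[node]
    }
    out[s] <- tree$value[node]
  }
  out
}

# bagged trees with per-split feature subsampling (mtry = p/3, nodesize 5:
# the classic random-forest regression defaults)
rf_fit_predict <- function(xtr, ytr, xte, n_trees = 100L, seed = 1L) {
  mtry <- max(1L, floor(ncol(xtr) / 3))
  with_seed(seed, {
    preds <- matrix(0, nrow(xte), n_trees)
    for (t in seq_len(n_trees)) {
      boot <- sample.int(nrow(xtr), replace = TRUE)
      tree <- cart_fit(xtr[boot, , drop = FALSE], ytr[boot],
                       max_depth = 25L, min_node = 5L, mtry = mtry)
      preds[, t] <- cart_predict(tree, xte)
    }
    rowMeans(preds)
  })
}

# stagewise least-squares boosting with depth-3 trees, shrinkage 0.1
gbm_fit_predict <- function(xtr, ytr, xte, n_stages = 100L, shrinkage = 0.1,
                            max_depth = 3L, seed = 1L) {
  with_seed(seed, {
    f0 <- mean(ytr)
    resid <- ytr - f0
    pred <- rep(f0, nrow(xte))
    for (t in seq_len(n_stages)) {
      tree <- cart_fit(xtr, resid, max_depth = max_depth, min_node = 2L)
      resid <- resid - shrinkage * cart_predict(tree, xtr)
      pred <- pred + shrinkage * cart_predict(tree, xte)
    }
    pred
  })
}

# least-squares SVM regression with an RBF kernel: solves the dual linear
# system [[K + I/C, 1], [1', 0]] [alpha; b] = [y; 0] in closed form.
# gamma defaults to 1 / (p * var(X)) (the usual "scale" heuristic).
lssvm_fit_predict <- function(xtr, ytr, xte, cost = 1, gamma = NULL) {
  if (is.null(gamma)) {
    v <- stats::var(as.vector(xtr))
    gamma <- if (v > 0) 1 / (ncol(xtr) * v) else 1
  }
  rbf <- function(a, b) {
    d2 <- outer(rowSums(a^2), rowSums(b^2), "+") - 2 * tcrossprod(a, b)
    exp(-gamma * pmax(d2, 0))
  }
  n <- nrow(xtr)
  lhs <- rbind(cbind(rbf(xtr, xtr) + diag(n) / cost, 1),
               c(rep(1, n), 0))
  sol <- solve(lhs, c(ytr, 0))
  drop(rbf(xte, xtr) %*% sol[seq_len(n)]) + sol[n + 1L]
}

baseline_names <- c("linreg", "rf", "gbm", "svm_rbf", "simple_nn")

#' Run one baseline regressor
#'
#' Fits one of the five reference models on the training split of the
#' concatenated view features and evaluates on the test split. Fixed
#' settings per model: `linreg` is ordinary least squares; `rf` a
#' random forest of 100 trees (per-split feature subsampling, mtry = p/3,
#' minimum node size 5); `gbm` gradient boosting with 100 depth-3 stages and
#' shrinkage 0.1; `svm_rbf` a least-squares SVM with RBF kernel
#' (`gamma = 1/(p Var(X))`, cost 1); `simple_nn` a one-hidden-layer network
#' of 64 ReLU units trained with Adam. Features are standardized with
#' train-split statistics for `svm_rbf` and `simple_nn`. Deterministic given
#' `seed`.
#'
#' @param name One of `"linreg"`, `"rf"`, `"gbm"`, `"svm_rbf"`,
#'   `"simple_nn"`.
#' @param x Feature matrix (samples x features), typically
#'   `cbind(fm_tf$values, fm_hm$values)` — see [concat_views()].
#' @param y Expression target.
#' @param masks Split masks from [split_samples()]; the same masks used for
#'   the graph model in any comparison.
#' @param seed Integer seed.
#' @param settings Optional named list overriding the fixed settings
#'   (`n_trees`, `n_stages`, `shrinkage`, `max_depth`, `cost`, `gamma`,
#'   `hidden`, `lr`, `epochs`).
#' @return List with `name`, `metrics` (see [compute_metrics()], on the test
#'   split), `y_pred` (test predictions), `settings`.
#' @export
run_baseline <- function(name, x, y, masks, seed = 1L, settings = list()) {
  if (!name %in% baseline_names) {
    stop("unknown baseline '", name, "'; available: ",
         paste(baseline_names, collapse = ", "))
  }
  xtr <- x[masks$train, , drop = FALSE]
  ytr <- y[masks$train]
  xte <- x[masks$test, , drop = FALSE]
  yte <- y[masks$test]
  std <- function() {
    mu <- colMeans(xtr)
    sdv <- apply(xtr, 2L, stats::sd)
    sdv[sdv == 0] <- 1
    list(tr = sweep(sweep(xtr, 2L, mu), 2L, sdv, "/"),
         te = sweep(sweep(xte, 2L, mu), 2L, sdv, "/"))
  }
  used <- list()
  y_pred <- switch(name,
    linreg = {
      fit <- stats::lm.fit(cbind(1, xtr), ytr)
      beta <- fit$coefficients
      beta[is.na(beta)] <- 0
      drop(cbind(1, xte) %*% beta)
    },
    rf = {
      used <- utils::modifyList(list(n_trees = 100L), settings)
      rf_fit_predict(xtr, ytr, xte, n_trees = used$n_trees, seed = seed)
    },
    gbm = {
      used <- utils::modifyList(list(n_stages = 100L, shrinkage = 0.1,
                                     max_depth = 3L), settings)
      gbm_fit_predict(xtr, ytr, xte, used$n_stages, used$shrinkage,
                      used$max_depth, seed = seed)
    },
    svm_rbf = {
      used <- utils::modifyList(list(cost = 1, gamma = NULL), settings)
      s <- std()
      lssvm_fit_predict(s$tr, ytr, s$te, used$cost, used$gamma)
    },
    simple_nn = {
      used <- utils::modifyList(list(hidden = 64L, lr = 0.01, epochs = 200L),
                                settings)
      s <- std()
      params <- mlp_train(s$tr, ytr, used$hidden, used$lr, used$epochs, seed)
      mlp_forward(s$te, params)$yhat
    })
  list(name = name, metrics = compute_metrics(yte, y_pred), y_pred = y_pred,
       settings = used)
}

#' Concatenate the two views' feature matrices
#'
#' Baselines see `[X_tf | X_hm]`, the same information the graph model gets.
#' Both inputs must be row-aligned (see [align_views()]).
#'
#' @param fm_tf,fm_hm `feature_matrix` objects or plain matrices.
#' @return Numeric matrix with the views' bins side by side.
#' @export
concat_views <- function(fm_tf, fm_hm) {
  a <- if (inherits(fm_tf, "feature_matrix")) fm_tf$values else fm_tf
  b <- if (inherits(fm_hm, "feature_matrix")) fm_hm$values else fm_hm
  if (nrow(a) != nrow(b)) stop("views are not row-aligned")
  cbind(a, b)
}

#' Run every baseline and tabulate the comparison
#'
#' One row per model with the standard metric columns (MSE, RMSE, MAE, R2),
#' mirroring the usual model-comparison table; a fitted graph model's test
#' metrics can be appended for a direct comparison. A baseline that errors
#' is reported with `NA` metrics and the run continues.
#'
#' @param x Concatenated feature matrix (see [concat_views()]).
#' @param y Expression target.
#' @param masks Split masks shared with the graph model.
#' @param seed Integer seed.
#' @param fit Optional `"genet"` fit whose test metrics are appended
#'   as a final row.
#' @return Data frame with columns `model`, `MSE`, `RMSE`, `MAE`, `R2`.
#' @export
run_all_baselines <- function(x, y, masks, seed = 1L, fit = NULL) {
  rows <- lapply(baseline_names, function(nm) {
    r <- tryCatch(run_baseline(nm, x, y, masks, seed), error = function(e) e)
    if (inherits(r, "error")) {
      warning("baseline ", nm, " failed: ", conditionMessage(r))
      data.frame(model = nm, MSE = NA_real_, RMSE = NA_real_, MAE = NA_real_,
                 R2 = NA_real_)
    } else {
      m <- r$metrics
      data.frame(model = nm, MSE = m$mse, RMSE = m$rmse, MAE = m$mae,
                 R2 = m$r2)
    }
  })
  tab <- do.call(rbind, rows)
  if (!is.null(fit)) {
    m <- fit$metrics$test
    tab <- rbind(tab, data.frame(model = "genet", MSE = m$mse, RMSE = m$rmse,
                                 MAE = m$mae, R2 = m$r2))
  }
  tab
}
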