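#' Cross-feature discovery tensor
#'
#' For each sample the two views' soft class-label vectors are combined into
#' a c x c label-correlation matrix: entry `(i, j)` is
#' `p_tf[i] * p_hm[j]`, the outer product of the per-view predictions. When
#' both inputs lie on the probability simplex the entries are non-negative
#' and sum to 1 (mass conservation), and if one view is uniform the tensor's
#' rows (columns) are proportional to the other view's prediction.
#'
#' @param p_tf,p_hm Soft label vectors of equal length c, or n x c matrices
#'   (one row per sample).
#' @return For vector input, a c x c matrix; for matrix input, an n x c^2
#'   matrix whose rows are the row-major flattened per-sample tensors (see
#'   [flatten_tensor()]).
#' @export
build_cross_feature_tensor <- function(p_tf, p_hm) {
  if (is.matrix(p_tf) || is.matrix(p_hm)) {
    if (!is.matrix(p_tf) || !is.matrix(p_hm) ||
        !all(dim(p_tf) == dim(p_hm))) {
      stop("view predictions must have identical dimensions")
    }
    c <- ncol(p_tf)
    # row-major layout: column (i-1)*c + j holds p_tf[, i] * p_hm[, j]
    return(p_tf[, rep(seq_len(c), each = c), drop = FALSE] *
             p_hm[, rep(seq_len(c), times = c), drop = FALSE])
  }
  if (length(p_tf) != length(p_hm)) {
    stop("view predictions must have equal length, got ", length(p_tf),
         " and ", length(p_hm))
  }
  outer(p_tf, p_hm)
}

#' Flatten / restore a cross-feature tensor
#'
#' Row-major flattening of a c x c tensor into a length-c^2 vector;
#' `unflatten_tensor()` inverts it exactly.
#'
#' @param t A c x c matrix.
#' @param v A length-c^2 vector.
#' @return A vector (flatten) or square matrix (unflatten).
#' @export
flatten_tensor <- function(t) {
  as.vector(t(t))
}

#' @rdname flatten_tensor
#' @export
unflatten_tensor <- function(v) {
  c <- sqrt(length(v))
  if (c != round(c)) stop("flattened tensor length must be a perfect square")
  matrix(v, as.integer(c), as.integer(c), byrow = TRUE)
}

#' Regression head over the flattened fusion tensor
#'
#' `yhat = w2' ReLU(W1 v + b1) + b2`: one hidden ReLU layer then a linear
#' output, mapping the c^2 label-correlation features to a single expression
#' value. Deterministic.
#'
#' @param v Length-c^2 vector, or an n x c^2 matrix of flattened tensors.
#' @param params Head parameters (`w1` c^2 x hidden, `b1`, `w2` hidden x 1,
#'   `b2`).
#' @return Predicted expression: a scalar, or a length-n vector for matrix
#'   input.
#' @export
fusion_forward <- function(v, params) {
  if (!is.matrix(v)) v <- matrix(v, nrow = 1L)
  if (ncol(v) != nrow(params$w1)) {
    stop("flattened tensor length ", ncol(v), " does not match head input ",
         nrow(params$w1))
  }
  drop(mlp_forward(v, params)$yhat)
}

# ---- end-to-end fusion loss ------------------------------------------------
# Mean squared error of the fused prediction over `mask`, as a function of
# both GCNs' parameters and the head. Used for joint fine-tuning and for the
# finite-difference gradient check.

# softmax vector-Jacobian product, row-wise: dz = p * (dp - rowSums(dp * p))
softmax_vjp <- function(dp, p) {
  p * (dp - rowSums(dp * p))
}

#' End-to-end fusion loss and gradients
#'
#' Computes the fused prediction (two GCN forward passes in evaluation mode,
#' cross-feature tensor, regression head) and the mean squared error over
#' `mask`, together with the exact backpropagated gradients with respect to
#' every parameter of both GCNs and the head. The gradient path runs through
#' the outer-product tensor and each view's softmax.
#'
#' @param x_tf,x_hm Per-view feature matrices (n x bins).
#' @param a_tf,a_hm Per-view normalized adjacencies.
#' @param params List with elements `tf`, `hm` (GCN parameter lists) and
#'   `head` (fusion head parameters).
#' @param y Continuous expression target (length n).
#' @param mask Logical mask of samples entering the loss.
#' @param dropout_masks Optional list of 0/1 dropout masks (`tf`, `hm`) for
#'   the GCN hidden layers (training mode); `NULL` for the deterministic
#'   evaluation-mode pass.
#' @param keep_prob Keep probability matching `dropout_masks`.
#' @param entropy_weight Weight of a negative-entropy penalty on both views'
#'   soft labels (0 disables). Keeping the codes soft preserves gradient
#'   flow and within-class resolution for samples in the tails of the
#'   expression distribution.
#' @return List with `loss`, `yhat`, and `grads` (same shape as `params`).
#' @export
genet_fusion_grad <- function(x_tf, x_hm, a_tf, a_hm, params, y, mask,
                              dropout_masks = NULL, keep_prob = 1,
                              entropy_weight = 0) {
  fwd_tf <- gcn_forward(x_tf, a_tf, params$tf, dropout_masks$tf, keep_prob)
  fwd_hm <- gcn_forward(x_hm, a_hm, params$hm, dropout_masks$hm, keep_prob)
  p_tf <- fwd_tf$prob
  p_hm <- fwd_hm$prob
  cc <- ncol(p_tf)
  v <- build_cross_feature_tensor(p_tf, p_hm)
  hf <- mlp_forward(v, params$head)
  m <- sum(mask)
  res <- hf$yhat - y
  loss <- sum(res[mask]^2) / m
  dy <- numeric(length(y))
  dy[mask] <- 2 * res[mask] / m
  dy <- matrix(dy, ncol = 1L)
  # head gradients
  gw2 <- crossprod(hf$h, dy)
  gb2 <- sum(dy)
  dh <- dy %*% t(params$head$w2)
  dh[hf$h <= 0] <- 0
  gw1 <- crossprod(v, dh)
  gb1 <- colSums(dh)
  dv <- dh %*% t(params$head$w1)
  # tensor -> per-view probability gradients (row-major column layout)
  dp_tf <- matrix(0, nrow(p_tf), cc)
  dp_hm <- matrix(0, nrow(p_hm), cc)
  for (a in seq_len(cc)) {
    cols <- (a - 1L) * cc + seq_len(cc)
    dp_tf[, a] <- rowSums(dv[, cols, drop = FALSE] * p_hm)
    dp_hm <- dp_hm + dv[, cols, drop = FALSE] * p_tf[, a]
  }
  if (entropy_weight > 0) {
    # negative-entropy penalty keeps the soft labels away from one-hot
    # saturation, preserving within-class resolution of the fused code
    m_ent <- length(y)
    eps <- 1e-12
    loss <- loss + entropy_weight *
      (sum(p_tf * log(p_tf + eps)) + sum(p_hm * log(p_hm + eps))) / m_ent
    dp_tf <- dp_tf + entropy_weight * (log(p_tf + eps) + 1) / m_ent
    dp_hm <- dp_hm + entropy_weight * (log(p_hm + eps) + 1) / m_ent
  }
  dz_tf <- softmax_vjp(dp_tf, p_tf)
  dz_hm <- softmax_vjp(dp_hm, p_hm)
  list(loss = loss, yhat = hf$yhat,
       grads = list(tf = gcn_backprop(dz_tf, fwd_tf, a_tf, params$tf,
                                      dropout_masks$tf, keep_prob),
                    hm = gcn_backprop(dz_hm, fwd_hm, a_hm, params$hm,
                                      dropout_masks$hm, keep_prob),
                    head = list(w1 = gw1, b1 = gb1, w2 = gw2, b2 = gb2)))
}

#' Fit the two-view graph model for expression prediction
#'
#' The full model: per-view cosine-similarity sample graphs, one two-layer
#' GCN per view trained to classify quantile-binned expression, fusion of
#' the two soft predictions through the cross-feature discovery tensor, and
#' a small regression head on the flattened tensor.
#'
#' Training runs in two stages. Stage 1 pre-trains each view's GCN on the
#' masked cross-entropy of the binned labels for `pretrain_epochs` epochs,
#' with dropout. Stage 2 fine-tunes the fusion objective end to end for up
#' to `epochs` epochs: each epoch takes one full backpropagated gradient of
#' the fusion MSE over the training mask and steps every block (tf GCN, hm
#' GCN, regression head) on it, regularized by dropout
#' (`stage2_dropout`), L2 weight decay (`stage2_weight_decay`) and a
#' negative-entropy penalty on the soft labels (`entropy_weight`) that keeps
#' the class codes from saturating to one-hot — saturation costs resolution
#' exactly where expression is most extreme. `stage2_ce_weight > 0`
#' additionally anchors the view GCNs to their classification losses during
#' this stage. Early stopping monitors validation MSE of the deterministic
#' (evaluation-mode) model with the given `patience`, and the best
#' parameters are restored.
#'
#' GCN inputs are column-standardized internally (`standardize = TRUE`);
#' similarity graphs are always built from the raw, non-negative signal
#' features, where cosine similarity has its intended meaning.
#'
#' @param fm_tf,fm_hm Per-view feature matrices ([build_feature_matrix()]
#'   objects or plain matrices), row-aligned (see [align_views()]).
#' @param y Continuous expression target, one value per sample.
#' @param masks Train/validation/test masks from [split_samples()]; when
#'   `NULL`, a 70/15/15 split is drawn with `seed`.
#' @param n_classes Number of expression quantile bins c (default 5).
#' @param hidden_size GCN hidden width, also used for the fusion head
#'   (default 128).
#' @param lr Adam learning rate for all stages (default 0.01).
#' @param epochs Maximum stage-2 epochs (default 300; early stopping usually
#'   ends training well before).
#' @param pretrain_epochs Stage-1 epochs per view (default 50).
#' @param dropout GCN dropout rate (default 0.5).
#' @param weight_decay L2 penalty on GCN weights in stage 1 (default 5e-4).
#' @param avg_degree,edge_scale Similarity-graph construction parameters;
#'   see [build_similarity_graph()] for the defaults and their rationale.
#' @param stage2_ce_weight Weight of the classification anchor added to the
#'   view GCNs' stage-2 gradients (default 0: classification shapes the
#'   views in stage 1 only; 1 keeps the views pinned to their class
#'   semantics throughout).
#' @param stage2_dropout Apply dropout to the stage-2 training steps
#'   (default `TRUE`).
#' @param stage2_weight_decay L2 penalty on all weight matrices during
#'   stage 2 (default 5e-3).
#' @param entropy_weight Anti-saturation penalty on the soft labels during
#'   stage 2 (default 0.01; see [genet_fusion_grad()]).
#' @param patience Early-stopping patience on validation MSE (default 60).
#' @param seed Integer seed driving every stochastic element.
#' @param graphs Optional pre-built list of two `similarity_graph`s
#'   (`tf`, `hm`); built from the feature matrices when `NULL`.
#' @param standardize Column-standardize the GCN input features (default
#'   `TRUE`; graph construction is unaffected).
#' @param sample_ids Optional sample identifiers (taken from `fm_tf` when it
#'   is a `feature_matrix`).
#' @return An object of class `"genet"`; see [predict.genet()],
#'   [summary.genet()], [residuals.genet()], [plot.genet()].
#' @examples
#' sim <- generate_dataset(synthetic_config(n_genes = 12, n_cell_lines = 4,
#'                                          seed = 7))
#' fit <- genet_fit(sim$fm_tf, sim$fm_hm, sim$expression$expression,
#'                  epochs = 20, pretrain_epochs = 10, hidden_size = 32,
#'                  n_classes = 3, seed = 7)
#' summary(fit)
#' @export
genet_fit <- function(fm_tf, fm_hm, y, masks = NULL, n_classes = 5L,
                      hidden_size = 128L, lr = 0.01, epochs = 300L,
                      pretrain_epochs = 50L, dropout = 0.5,
                      weight_decay = 5e-4, avg_degree = 1, edge_scale = 0.1,
                      stage2_ce_weight = 0, stage2_dropout = TRUE,
                      stage2_weight_decay = 5e-3, entropy_weight = 0.01,
                      patience = 60L, seed = 1L, graphs = NULL,
                      sample_ids = NULL, standardize = TRUE) {
  if (inherits(fm_tf, "feature_matrix")) {
    if (is.null(sample_ids)) sample_ids <- fm_tf$sample_ids
    x_tf <- fm_tf$values
  } else x_tf <- fm_tf
  x_hm <- if (inherits(fm_hm, "feature_matrix")) fm_hm$values else fm_hm
  n <- nrow(x_tf)
  if (nrow(x_hm) != n || length(y) != n) {
    stop("views and expression target must be row-aligned (see align_views)")
  }
  if (is.null(sample_ids)) sample_ids <- as.character(seq_len(n))
  if (is.null(masks)) masks <- split_samples(n, seed = seed)
  if (is.null(graphs)) {
    graphs <- list(tf = build_similarity_graph(x_tf, avg_degree, edge_scale),
                   hm = build_similarity_graph(x_hm, avg_degree, edge_scale))
  }
  a_tf <- graphs$tf$norm_adjacency
  a_hm <- graphs$hm$norm_adjacency

  if (standardize) {
    x_tf <- standardize_columns(x_tf)
    x_hm <- standardize_columns(x_hm)
  }

  labels <- discretize_expression(y, n_classes, masks$train)
  y_onehot <- diag(n_classes)[labels + 1L, , drop = FALSE]

  # stage 1: pre-train each view's classifier
  gcn_tf <- train_view_gcn(x_tf, a_tf, labels, masks, hidden_size, lr,
                           pretrain_epochs, dropout, weight_decay,
                           seed = seed)
  gcn_hm <- train_view_gcn(x_hm, a_hm, labels, masks, hidden_size, lr,
                           pretrain_epochs, dropout, weight_decay,
                           seed = seed + 1L)

  params <- list(tf = gcn_tf$params, hm = gcn_hm$params,
                 head = with_seed(seed + 2L,
                                  mlp_init(n_classes^2, hidden_size)))
  states <- list(tf = adam_init(params$tf), hm = adam_init(params$hm),
                 head = adam_init(params$head))

  best <- list(params = params, val_mse = Inf, epoch = 0L)
  wait <- 0L
  history <- data.frame(epoch = integer(0), fusion_train_mse = numeric(0),
                        fusion_val_mse = numeric(0))

  with_seed(seed + 3L, {
    for (e in seq_len(epochs)) {
      # stage 2: one full backward pass of the fusion MSE per epoch; all
      # three blocks (tf GCN, hm GCN, head) step on it. Dropout and L2
      # weight decay regularize the training steps; early stopping below
      # always evaluates the deterministic model.
      dm <- if (stage2_dropout && dropout > 0) {
        list(tf = matrix(stats::rbinom(n * hidden_size, 1L, 1 - dropout), n),
             hm = matrix(stats::rbinom(n * hidden_size, 1L, 1 - dropout), n))
      } else NULL
      fg <- genet_fusion_grad(x_tf, x_hm, a_tf, a_hm, params, y, masks$train,
                              dm, 1 - dropout, entropy_weight)
      if (!is.finite(fg$loss)) {
        stop("fusion loss diverged (", fg$loss, ") at epoch ", e,
             "; lower the learning rate")
      }
      if (stage2_weight_decay > 0) {
        for (blk in names(fg$grads)) {
          for (wn in c("w1", "w2")) {
            fg$grads[[blk]][[wn]] <- fg$grads[[blk]][[wn]] +
              stage2_weight_decay * params[[blk]][[wn]]
          }
        }
      }
      for (vw in c("tf", "hm")) {
        g <- fg$grads[[vw]]
        if (stage2_ce_weight > 0) {
          xv <- if (vw == "tf") x_tf else x_hm
          av <- if (vw == "tf") a_tf else a_hm
          lg <- gcn_ce_loss_grad(xv, av, params[[vw]], y_onehot, masks$train,
                                 weight_decay)
          if (!is.finite(lg$loss)) {
            stop("view GCN loss diverged (", lg$loss, ") at fusion epoch ", e)
          }
          g <- Map(function(a, b) a + stage2_ce_weight * b, g, lg$grads)
        }
        st <- adam_step(params[[vw]], g, states[[vw]], lr)
        params[[vw]] <- st$params
        states[[vw]] <- st$state
      }
      st <- adam_step(params$head, fg$grads$head, states$head, lr)
      params$head <- st$params
      states$head <- st$state

      ev <- genet_predict_internal(x_tf, x_hm, a_tf, a_hm, params)
      val_mse <- mean((ev$yhat[masks$val] - y[masks$val])^2)
      history[e, ] <- list(e, mean((ev$yhat[masks$train] - y[masks$train])^2),
                           val_mse)
      if (val_mse < best$val_mse - 1e-12) {
        best <- list(params = params, val_mse = val_mse, epoch = e)
        wait <- 0L
      } else {
        wait <- wait + 1L
        if (wait >= patience) break
      }
    }
  })

  params <- best$params
  ev <- genet_predict_internal(x_tf, x_hm, a_tf, a_hm, params)
  metrics <- lapply(list(train = masks$train, val = masks$val,
                         test = masks$test),
                    function(m) compute_metrics(y[m], ev$yhat[m]))
  structure(list(params = params, graphs = graphs, masks = masks,
                 y = y, fitted = ev$yhat, view_prob = ev$prob,
                 sample_ids = sample_ids, labels = labels,
                 cutpoints = attr(labels, "cutpoints"),
                 metrics = metrics, history = history,
                 best_epoch = best$epoch,
                 x_tf = x_tf, x_hm = x_hm,
                 config = list(n_classes = n_classes,
                               hidden_size = hidden_size, lr = lr,
                               epochs = epochs,
                               pretrain_epochs = pretrain_epochs,
                               dropout = dropout,
                               weight_decay = weight_decay,
                               avg_degree = avg_degree,
                               edge_scale = edge_scale,
                               stage2_ce_weight = stage2_ce_weight,
                               stage2_dropout = stage2_dropout,
                               stage2_weight_decay = stage2_weight_decay,
                               entropy_weight = entropy_weight,
                               patience = patience, seed = seed)),
            class = "genet")
}

# evaluation-mode forward pass of the whole model
genet_predict_internal <- function(x_tf, x_hm, a_tf, a_hm, params) {
  p_tf <- gcn_forward(x_tf, a_tf, params$tf)$prob
  p_hm <- gcn_forward(x_hm, a_hm, params$hm)$prob
  v <- build_cross_feature_tensor(p_tf, p_hm)
  list(yhat = fusion_forward(v, params$head), prob = list(tf = p_tf, hm = p_hm))
}

#' @export
print.genet <- function(x, ...) {
  cat("Two-view GCN expression model\n")
  cat(sprintf("  %d samples, %d expression classes, hidden size %d\n",
              length(x$y), x$config$n_classes, x$config$hidden_size))
  cat(sprintf("  best epoch %d (val MSE %.4g)\n", x$best_epoch,
              x$metrics$val$mse))
  cat(sprintf("  test: MSE %.4g, RMSE %.4g, MAE %.4g, R2 %.4g\n",
              x$metrics$test$mse, x$metrics$test$rmse, x$metrics$test$mae,
              x$metrics$test$r2))
  invisible(x)
}

#' Summarize a fitted two-view expression model
#'
#' @param object A `"genet"` fit.
#' @param ... Unused.
#' @return The fit, invisibly; prints per-split metrics.
#' @export
summary.genet <- function(object, ...) {
  print(object)
  tab <- do.call(rbind, lapply(object$metrics, function(m)
    data.frame(mse = m$mse, rmse = m$rmse, mae = m$mae, r2 = m$r2,
               pearson_r = m$pearson_r)))
  cat("\nMetrics by split:\n")
  print(round(tab, 4))
  invisible(object)
}

#' Predictions from a fitted model
#'
#' The model is transductive — it is fitted over one fixed sample graph — so
#' predictions are available for the samples it was fitted on, selected by
#' split.
#'
#' @param object A `"genet"` fit.
#' @param subset `"all"`, `"train"`, `"val"` or `"test"`.
#' @param ... Unused.
#' @return Named numeric vector of predicted expression values.
#' @export
predict.genet <- function(object, subset = c("all", "train", "val", "test"),
                          ...) {
  subset <- match.arg(subset)
  idx <- if (subset == "all") rep(TRUE, length(object$y)) else
    object$masks[[subset]]
  stats::setNames(object$fitted[idx], object$sample_ids[idx])
}

#' @export
fitted.genet <- function(object, ...) {
  stats::setNames(object$fitted, object$sample_ids)
}

#' @export
residuals.genet <- function(object, subset = c("all", "train", "val", "test"),
                            ...) {
  subset <- match.arg(subset)
  idx <- if (subset == "all") rep(TRUE, length(object$y)) else
    object$masks[[subset]]
  stats::setNames(object$y[idx] - object$fitted[idx], object$sample_ids[idx])
}

#' @export
coef.genet <- function(object, ...) {
  object$params
}

#' Diagnostic plots for a fitted model
#'
#' `which = 1`: predicted versus actual expression with the identity line;
#' `which = 2`: residuals against predicted values with a zero line. Points
#' are the test split by default.
#'
#' @param x A `"genet"` fit.
#' @param which Plots to draw (subset of `1:2`).
#' @param subset Split to plot (default `"test"`).
#' @param ... Passed to [plot()].
#' @return `x`, invisibly.
#' @export
plot.genet <- function(x, which = 1:2, subset = "test", ...) {
  idx <- if (subset == "all") rep(TRUE, length(x$y)) else x$masks[[subset]]
  yt <- x$y[idx]
  yp <- x$fitted[idx]
  if (1 %in% which) {
    plot(yt, yp, xlab = "actual expression", ylab = "predicted expression",
         main = sprintf("Predicted vs actual (%s)", subset), ...)
    graphics::abline(0, 1)
  }
  if (2 %in% which) {
    plot(yp, yt - yp, xlab = "predicted expression", ylab = "residual",
         main = sprintf("Residuals (%s)", subset), ...)
    graphics::abline(h = 0, lty = 2, col = 2)
  }
  invisible(x)
}
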