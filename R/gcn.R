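#' Discretize a continuous expression target into quantile classes
#'
#' The per-view GCNs are classifiers, so the continuous expression target is
#' binned into `n_classes` (approximately) equal-mass classes. Bin edges are
#' the interior quantiles of the *training* values only; validation and test
#' samples are mapped with those train-derived edges. A value equal to an
#' edge falls in the lower bin, so the mapping is monotone.
#'
#' @param y Numeric expression vector (all samples).
#' @param n_classes Number of classes c >= 1.
#' @param train_mask Logical (or integer index) mask of training samples.
#' @return Integer vector of labels in `0 .. n_classes - 1`, with the edge
#'   vector stored in `attr(, "cutpoints")`.
#' @export
discretize_expression <- function(y, n_classes, train_mask) {
  if (n_classes < 1) stop("n_classes must be >= 1")
  ytr <- y[train_mask]
  if (length(ytr) == 0L) stop("train_mask selects no samples")
  if (n_classes > length(unique(ytr))) {
    stop("n_classes (", n_classes, ") exceeds the number of distinct ",
         "training values (", length(unique(ytr)), "); use a smaller n_classes")
  }
  if (n_classes == 1L) {
    labels <- rep(0L, length(y))
    attr(labels, "cutpoints") <- numeric(0)
    return(labels)
  }
  cuts <- unname(stats::quantile(ytr, probs = seq_len(n_classes - 1L) / n_classes,
                                 type = 7))
  labels <- as.integer(rowSums(outer(y, cuts, ">")))
  attr(labels, "cutpoints") <- cuts
  labels
}

#' One graph convolution layer
#'
#' `activation(A^ %*% h %*% w + b)` — neighbor aggregation through the
#' normalized adjacency followed by a dense transform.
#'
#' @param h Input node features (n x d_in).
#' @param a_hat Normalized adjacency (n x n), e.g. from
#'   [normalize_adjacency()].
#' @param w,b Weight matrix (d_in x d_out) and bias vector (length d_out).
#' @param activation Function applied elementwise (default [relu]; use
#'   `identity` for a linear layer).
#' @return n x d_out matrix.
#' @export
graph_conv <- function(h, a_hat, w, b = numeric(ncol(w)), activation = relu) {
  if (ncol(h) != nrow(w)) {
    stop("dimension mismatch: features ", ncol(h), " vs weight rows ", nrow(w))
  }
  activation(sweep(a_hat %*% h %*% w, 2L, b, "+"))
}

# Glorot-initialized two-layer GCN parameters: n_bins -> hidden -> c
gcn_init <- function(d_in, hidden, n_classes) {
  list(w1 = glorot_init(d_in, hidden), b1 = numeric(hidden),
       w2 = glorot_init(hidden, n_classes), b2 = numeric(n_classes))
}

#' Two-layer GCN forward pass
#'
#' `H1 = ReLU(A^ H0 W1 + b1)` (with optional inverted dropout on `H1` during
#' training), `Z = A^ H1 W2 + b2`, `P = softmax(Z)` row-wise. The returned
#' probabilities lie on the simplex per sample. Deterministic given the
#' parameters and dropout mask.
#'
#' @param h0 Node feature matrix (n x n_bins).
#' @param a_hat Normalized adjacency (n x n).
#' @param params Parameter list (`w1`, `b1`, `w2`, `b2`) as from the
#'   trainers.
#' @param dropout_mask Optional 0/1 matrix the shape of `H1`; when supplied,
#'   `H1` is multiplied by `dropout_mask / keep_prob` (training mode).
#' @param keep_prob Keep probability matching `dropout_mask`.
#' @return List with `h1` (post-dropout hidden reps), `logits`, `prob`, and
#'   cached `ah0`, `ah1` products used by backprop.
#' @export
gcn_forward <- function(h0, a_hat, params, dropout_mask = NULL, keep_prob = 1) {
  if (nrow(h0) != nrow(a_hat)) {
    stop("dimension mismatch: ", nrow(h0), " samples vs ", nrow(a_hat),
         "-node adjacency")
  }
  ah0 <- a_hat %*% h0
  z1 <- sweep(ah0 %*% params$w1, 2L, params$b1, "+")
  h1 <- relu(z1)
  if (!is.null(dropout_mask)) h1 <- h1 * dropout_mask / keep_prob
  ah1 <- a_hat %*% h1
  logits <- sweep(ah1 %*% params$w2, 2L, params$b2, "+")
  list(h1 = h1, z1 = z1, logits = logits, prob = softmax_rows(logits),
       ah0 = ah0, ah1 = ah1)
}

# Masked cross-entropy loss (mean over mask rows) + L2 weight decay on the
# weight matrices. y_onehot: n x c. Returns list(loss, grads, fwd).
gcn_ce_loss_grad <- function(h0, a_hat, params, y_onehot, mask,
                             weight_decay = 0, dropout_mask = NULL,
                             keep_prob = 1) {
  fwd <- gcn_forward(h0, a_hat, params, dropout_mask, keep_prob)
  m <- sum(mask)
  p <- fwd$prob
  eps <- 1e-12
  loss <- -sum(y_onehot[mask, , drop = FALSE] *
                 log(p[mask, , drop = FALSE] + eps)) / m +
    weight_decay * 0.5 * (sum(params$w1^2) + sum(params$w2^2))
  dz2 <- matrix(0, nrow(p), ncol(p))
  dz2[mask, ] <- (p[mask, , drop = FALSE] - y_onehot[mask, , drop = FALSE]) / m
  grads <- gcn_backprop(dz2, fwd, a_hat, params, dropout_mask, keep_prob)
  grads$w1 <- grads$w1 + weight_decay * params$w1
  grads$w2 <- grads$w2 + weight_decay * params$w2
  list(loss = loss, grads = grads, fwd = fwd)
}

# Backpropagate a gradient dz2 (w.r.t. the logits) through the two-layer GCN.
# Shared by the cross-entropy stage and the end-to-end fusion loss.
gcn_backprop <- function(dz2, fwd, a_hat, params, dropout_mask = NULL,
                         keep_prob = 1) {
  gw2 <- crossprod(fwd$ah1, dz2)
  gb2 <- colSums(dz2)
  dh1 <- (a_hat %*% dz2) %*% t(params$w2)
  if (!is.null(dropout_mask)) dh1 <- dh1 * dropout_mask / keep_prob
  dz1 <- dh1
  dz1[fwd$z1 <= 0] <- 0
  gw1 <- crossprod(fwd$ah0, dz1)
  gb1 <- colSums(dz1)
  list(w1 = gw1, b1 = gb1, w2 = gw2, b2 = gb2)
}

#' Train one view's GCN classifier
#'
#' Full-batch Adam on the masked cross-entropy of the two-layer GCN, with
#' inverted dropout after the first layer (training only) and L2 weight
#' decay on the weight matrices. Transductive: the forward pass always runs
#' over the whole graph, the loss only over `masks$train`. All randomness
#' (initialisation, dropout) is driven by `seed`.
#'
#' @param h0 Feature matrix (n x n_bins) or a `feature_matrix`.
#' @param a_hat Normalized adjacency, or a `similarity_graph`.
#' @param labels Integer class labels in `0 .. n_classes - 1` (e.g. from
#'   [discretize_expression()]).
#' @param masks List with logical `train` mask (see [split_samples()]).
#' @param hidden_size Hidden layer width (default 128).
#' @param lr Adam learning rate (default 0.01).
#' @param epochs Training epochs (default 100).
#' @param dropout Dropout rate after layer 1 (default 0.5).
#' @param weight_decay L2 penalty on weights (default 5e-4).
#' @param seed Integer seed.
#' @return List with `params`, `prob` (evaluation-mode soft labels for all
#'   samples), `history` (per-epoch train loss), `n_classes`.
#' @export
train_view_gcn <- function(h0, a_hat, labels, masks, hidden_size = 128L,
                           lr = 0.01, epochs = 100L, dropout = 0.5,
                           weight_decay = 5e-4, seed = 1L) {
  if (inherits(h0, "feature_matrix")) h0 <- h0$values
  if (inherits(a_hat, "similarity_graph")) a_hat <- a_hat$norm_adjacency
  n_classes <- max(labels) + 1L
  y_onehot <- diag(n_classes)[labels + 1L, , drop = FALSE]
  keep <- 1 - dropout
  with_seed(seed, {
    params <- gcn_init(ncol(h0), hidden_size, n_classes)
    state <- adam_init(params)
    history <- numeric(epochs)
    for (e in seq_len(epochs)) {
      dm <- if (dropout > 0) {
        matrix(stats::rbinom(nrow(h0) * hidden_size, 1L, keep), nrow(h0))
      } else NULL
      lg <- gcn_ce_loss_grad(h0, a_hat, params, y_onehot, masks$train,
                             weight_decay, dm, keep)
      if (!is.finite(lg$loss)) {
        stop("GCN training diverged (loss is ", lg$loss, ") at epoch ", e,
             "; lower the learning rate")
      }
      history[e] <- lg$loss
      if (lr > 0) {
        st <- adam_step(params, lg$grads, state, lr)
        params <- st$params
        state <- st$state
      }
    }
    fwd <- gcn_forward(h0, a_hat, params)
    list(params = params, prob = fwd$prob, history = history,
         n_classes = n_classes)
  })
}
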