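#' Random train/validation/test split
#'
#' Randomized 70/15/15 split (by default) over `n` samples. Counts follow a
#' floor rule: `n_val = floor(f_val * n)`, `n_test = floor(f_test * n)`, and
#' every remainder sample goes to train, so the fractions hold exactly when
#' `n` is divisible by 20 and train never shrinks. Deterministic given
#' `seed`.
#'
#' @param n Number of samples (>= 3).
#' @param fractions Train/validation/test fractions summing to 1.
#' @param seed Integer seed for the permutation.
#' @return A list of disjoint logical masks `train`, `val`, `test` whose
#'   union covers all samples, plus `fractions` and `seed`.
#' @export
split_samples <- function(n, fractions = c(0.70, 0.15, 0.15), seed = 1L) {
  if (length(fractions) != 3L || abs(sum(fractions) - 1) > 1e-8) {
    stop("fractions must be three values summing to 1")
  }
  n_val <- floor(fractions[2L] * n)
  n_test <- floor(fractions[3L] * n)
  n_train <- n - n_val - n_test
  if (n < 3L || n_train < 1L || n_val < 1L || n_test < 1L) {
    stop("n = ", n, " is too small for a non-empty ",
         paste(fractions, collapse = "/"), " split")
  }
  perm <- with_seed(seed, sample.int(n))
  train <- val <- test <- logical(n)
  train[perm[seq_len(n_train)]] <- TRUE
  val[perm[n_train + seq_len(n_val)]] <- TRUE
  test[perm[n_train + n_val + seq_len(n_test)]] <- TRUE
  list(train = train, val = val, test = test, fractions = fractions,
       seed = seed)
}

#' Regression metrics report
#'
#' Mean squared error, its root, mean absolute error, the coefficient of
#' determination `R2 = 1 - SSres / SStot`, and the Pearson correlation.
#' `rmse` is `sqrt(mse)` exactly. When `y_true` is constant, `r2` and
#' `pearson_r` are undefined and returned as `NA` with `degenerate = TRUE`;
#' the error metrics are still computed.
#'
#' @param y_true,y_pred Equal-length numeric vectors (length >= 2).
#' @return A list with `mse`, `rmse`, `mae`, `r2`, `pearson_r`,
#'   `degenerate`, `n`.
#' @export
compute_metrics <- function(y_true, y_pred) {
  if (length(y_true) != length(y_pred)) {
    stop("y_true and y_pred must have equal length")
  }
  if (length(y_true) < 2L) stop("need at least 2 observations")
  res <- y_true - y_pred
  mse <- mean(res^2)
  sstot <- sum((y_true - mean(y_true))^2)
  degenerate <- sstot == 0
  list(mse = mse, rmse = sqrt(mse), mae = mean(abs(res)),
       r2 = if (degenerate) NA_real_ else 1 - sum(res^2) / sstot,
       pearson_r = if (degenerate || stats::sd(y_pred) == 0) NA_real_ else
         stats::cor(y_true, y_pred),
       degenerate = degenerate, n = length(y_true))
}

#' Grid search over learning rate and hidden size
#'
#' Sequentially trains one configuration per (lr, hidden_size) pair of the
#' grid — by default the 3 x 3 grid of learning rates
#' `{0.001, 0.01, 0.1}` and hidden sizes `{64, 128, 256}` — with a fixed
#' seed, and returns the configuration minimizing validation loss. Ties are
#' broken toward the smaller learning rate, then the smaller hidden size, so
#' the result does not depend on enumeration order. Configurations whose
#' training fails (e.g. divergence) are recorded with `NA` loss and skipped;
#' if every configuration fails, an error is raised.
#'
#' @param train_fn Function `(lr, hidden_size)` returning the validation
#'   loss (a single finite number) of a model trained with those settings.
#' @param lr_values,hidden_values Grid axes.
#' @return A list with `best` (list `lr`, `hidden_size`, `val_loss`) and
#'   `table` (one row per configuration, in enumeration order).
#' @export
grid_search <- function(train_fn, lr_values = c(0.001, 0.01, 0.1),
                        hidden_values = c(64L, 128L, 256L)) {
  if (length(lr_values) == 0L || length(hidden_values) == 0L) {
    stop("grid must be non-empty")
  }
  grid <- expand.grid(lr = lr_values, hidden_size = hidden_values,
                      KEEP.OUT.ATTRS = FALSE)
  grid$val_loss <- NA_real_
  grid$error <- NA_character_
  for (i in seq_len(nrow(grid))) {
    r <- tryCatch(train_fn(grid$lr[i], grid$hidden_size[i]),
                  error = function(e) e)
    if (inherits(r, "error")) {
      grid$error[i] <- conditionMessage(r)
    } else if (is.finite(r)) {
      grid$val_loss[i] <- r
    } else {
      grid$error[i] <- "non-finite validation loss"
    }
  }
  if (all(is.na(grid$val_loss))) {
    stop("every configuration in the grid failed to train")
  }
  ord <- order(grid$val_loss, grid$lr, grid$hidden_size, na.last = TRUE)
  b <- grid[ord[1L], ]
  list(best = list(lr = b$lr, hidden_size = as.integer(b$hidden_size),
                   val_loss = b$val_loss),
       table = grid)
}

#' Sweep the TSS window size
#'
#' Re-runs the whole pipeline (featurization, graph construction, training,
#' evaluation) for each TSS flank in `ranges` — by default the four window
#' sizes 200, 500, 1000 and 2000 bp — and tabulates the test metrics per
#' range. A failure at one range is recorded and the sweep continues.
#'
#' @param pipeline_fn Function `(tss_range)` returning a named list of
#'   numeric metrics (e.g. `list(mse = ..., r2 = ...)`).
#' @param ranges TSS flank sizes in bp.
#' @return Data frame with one row per range: `tss_range`, the metrics, and
#'   an `error` column (`NA` on success).
#' @export
tss_range_sweep <- function(pipeline_fn, ranges = c(200, 500, 1000, 2000)) {
  if (any(ranges <= 0)) stop("TSS ranges must be positive")
  rows <- lapply(ranges, function(r) {
    out <- tryCatch(pipeline_fn(r), error = function(e) e)
    if (inherits(out, "error")) {
      data.frame(tss_range = r, error = conditionMessage(out))
    } else {
      cbind(data.frame(tss_range = r),
            as.data.frame(out[vapply(out, is.numeric, TRUE)]),
            data.frame(error = NA_character_))
    }
  })
  cols <- unique(unlist(lapply(rows, names)))
  rows <- lapply(rows, function(d) {
    for (m in setdiff(cols, names(d))) d[[m]] <- NA_real_
    d[cols]
  })
  do.call(rbind, rows)
}
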