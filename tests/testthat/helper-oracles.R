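# Independent brute-force oracles. Each recomputes a quantity by the most
# literal possible method (per-base loops, per-entry formulas, per-node
# sums) and is kept free of the package's vectorized implementations.

# mean per-base signal per bin: walk every base of every bin
oracle_bin_signal <- function(peaks, window, bin_size) {
  n_bins <- ceiling((window$end - window$grid_start) / bin_size)
  out <- numeric(n_bins)
  for (b in seq_len(n_bins)) {
    lo <- window$grid_start + (b - 1) * bin_size
    acc <- 0
    for (base in seq(lo, min(lo + bin_size, window$end) - 1)) {
      if (base < 0) next
      if (nrow(peaks) > 0) {
        covering <- peaks$start <= base & peaks$end > base
        acc <- acc + sum(peaks$signal[covering])
      }
    }
    out[b] <- acc / bin_size
  }
  out
}

oracle_cosine <- function(x) {
  n <- nrow(x)
  s <- matrix(0, n, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      ni <- sqrt(sum(x[i, ]^2))
      nj <- sqrt(sum(x[j, ]^2))
      s[i, j] <- if (i == j) 1 else if (ni == 0 || nj == 0) 0 else
        sum(x[i, ] * x[j, ]) / (ni * nj)
    }
  }
  s
}

# per-entry D^-1/2 (A + I) D^-1/2
oracle_normalize <- function(a) {
  n <- nrow(a)
  at <- a + diag(n)
  deg <- sapply(seq_len(n), function(i) sum(at[i, ]))
  out <- matrix(0, n, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      out[i, j] <- at[i, j] / sqrt(deg[i] * deg[j])
    }
  }
  out
}

# smallest threshold keeping average degree >= k, by scanning all candidate
# thresholds descending
oracle_sparsify <- function(s, k) {
  n <- nrow(s)
  a <- pmax(s, 0)
  diag(a) <- 0
  vals <- sort(unique(a[a > 0]), decreasing = TRUE)
  for (t in vals) {
    kept <- a >= t
    diag(kept) <- FALSE
    if (sum(kept) / n >= k) {
      a[a < t] <- 0
      return(a)
    }
  }
  a
}

# two-layer GCN forward with explicit per-node neighbor sums
oracle_gcn_forward <- function(h0, a_hat, params) {
  n <- nrow(h0)
  agg1 <- matrix(0, n, ncol(h0))
  for (i in seq_len(n)) {
    for (j in seq_len(n)) agg1[i, ] <- agg1[i, ] + a_hat[i, j] * h0[j, ]
  }
  h1 <- pmax(agg1 %*% params$w1 + rep(1, n) %o% params$b1, 0)
  agg2 <- matrix(0, n, ncol(h1))
  for (i in seq_len(n)) {
    for (j in seq_len(n)) agg2[i, ] <- agg2[i, ] + a_hat[i, j] * h1[j, ]
  }
  z <- agg2 %*% params$w2 + rep(1, n) %o% params$b2
  p <- t(apply(z, 1, function(r) exp(r - max(r)) / sum(exp(r - max(r)))))
  list(h1 = h1, logits = z, prob = p)
}

# central finite-difference gradient of f at params (list of arrays)
finite_diff_grads <- function(f, params, eps = 1e-5) {
  g <- params
  for (nm in names(params)) {
    p <- params[[nm]]
    gp <- p
    for (i in seq_along(p)) {
      up <- params; up[[nm]][i] <- p[i] + eps
      dn <- params; dn[[nm]][i] <- p[i] - eps
      gp[i] <- (f(up) - f(dn)) / (2 * eps)
    }
    g[[nm]] <- gp
  }
  g
}
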