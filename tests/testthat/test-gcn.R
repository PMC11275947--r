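test_that("expression discretization uses train-quantile bins with tie-low", {
  y <- c(1, 2, 3, 4)
  lab <- discretize_expression(y, 2, rep(TRUE, 4))
  expect_equal(as.integer(lab), c(0L, 0L, 1L, 1L))
  # single class maps everything to 0
  expect_equal(as.integer(discretize_expression(y, 1, rep(TRUE, 4))),
               rep(0L, 4))
  # a value equal to a cutpoint goes to the lower bin
  y2 <- c(1, 2, 3)
  lab2 <- discretize_expression(y2, 3, rep(TRUE, 3))
  expect_equal(as.integer(lab2), c(0L, 1L, 2L))
  expect_error(discretize_expression(c(1, 1, 1, 2), 3, rep(TRUE, 4)),
               "smaller n_classes")
})

test_that("discretization is monotone and uses train-derived edges only", {
  set.seed(201)
  for (rep in 1:8) {
    y <- rnorm(60)
    train <- seq_len(60) <= 40
    lab <- discretize_expression(y, 4, train)
    o <- order(y)
    expect_true(all(diff(as.integer(lab)[o]) >= 0))
    expect_equal(attr(lab, "cutpoints"),
                 unname(quantile(y[train], c(0.25, 0.5, 0.75))))
    # val/test values outside the train range still map to end bins
    expect_true(all(lab >= 0 & lab <= 3))
  }
})

test_that("a single identity graph-conv layer propagates features unchanged", {
  h0 <- matrix(c(1, 2, 0.5, 3), 2)
  out <- graph_conv(h0, diag(2), diag(2))
  expect_equal(out, h0)
  # hand-computed aggregation: uniform 2-node graph averages the column
  a <- matrix(0.5, 2, 2)
  z <- graph_conv(matrix(c(1, 3), 2), a, matrix(1), activation = identity)
  expect_equal(z, matrix(c(2, 2), 2))
  expect_error(graph_conv(h0, diag(2), diag(3)), "dimension mismatch")
})

test_that("the two-layer forward pass matches a per-node brute-force oracle", {
  set.seed(202)
  for (rep in 1:5) {
    n <- 6
    h0 <- matrix(rnorm(n * 5), n)
    a <- matrix(rbinom(n^2, 1, 0.4) * runif(n^2), n)
    a <- (a + t(a)) / 2
    diag(a) <- 0
    a_hat <- normalize_adjacency(a)
    params <- with(list(), {
      set.seed(rep)
      list(w1 = matrix(rnorm(5 * 4), 5), b1 = rnorm(4),
           w2 = matrix(rnorm(4 * 3), 4), b2 = rnorm(3))
    })
    fwd <- gcn_forward(h0, a_hat, params)
    oracle <- oracle_gcn_forward(h0, a_hat, params)
    expect_equal(fwd$logits, oracle$logits, tolerance = 1e-9)
    expect_equal(unname(fwd$prob), unname(oracle$prob), tolerance = 1e-9)
    expect_equal(rowSums(fwd$prob), rep(1, n), tolerance = 1e-6)
  }
})

test_that("with an identity adjacency the GCN equals an MLP", {
  set.seed(203)
  n <- 10
  h0 <- matrix(rnorm(n * 6), n)
  params <- list(w1 = matrix(rnorm(6 * 8), 6), b1 = rnorm(8),
                 w2 = matrix(rnorm(8 * 3), 8), b2 = rnorm(3))
  fwd <- gcn_forward(h0, diag(n), params)
  h1 <- pmax(sweep(h0 %*% params$w1, 2, params$b1, "+"), 0)
  z <- sweep(h1 %*% params$w2, 2, params$b2, "+")
  p <- exp(z - apply(z, 1, max))
  p <- p / rowSums(p)
  expect_equal(fwd$logits, z, tolerance = 1e-12)
  expect_equal(fwd$prob, p, tolerance = 1e-12)
})

test_that("GCN training separates two planted clusters", {
  toy <- separable_toy()
  # cosine on the signed features separates the clusters (cross-cluster
  # similarities are negative and get clipped), giving an informative graph
  g <- build_similarity_graph(toy$x, avg_degree = 3, edge_scale = 1)
  fit <- train_view_gcn(toy$x, g$norm_adjacency, toy$labels, toy$masks,
                        hidden_size = 16L, lr = 0.01, epochs = 100L,
                        seed = 1)
  pred <- max.col(fit$prob) - 1L
  acc <- mean(pred[toy$masks$train] == toy$labels[toy$masks$train])
  expect_gte(acc, 0.9)
  # softmax rows stay on the simplex
  expect_equal(rowSums(fit$prob), rep(1, toy$n), tolerance = 1e-6)
  # training loss decreases overall (5% slack for dropout noise)
  h <- fit$history
  expect_lt(h[length(h)], h[1] * 1.05)
  expect_lt(min(h), h[1])
})

test_that("GCN training is seed-deterministic and frozen at lr = 0", {
  toy <- separable_toy(n_per = 10, seed = 7)
  g <- build_similarity_graph(toy$x, avg_degree = 2, edge_scale = 1)
  f1 <- train_view_gcn(toy$x, g$norm_adjacency, toy$labels, toy$masks,
                       hidden_size = 8L, epochs = 20L, seed = 5)
  f2 <- train_view_gcn(toy$x, g$norm_adjacency, toy$labels, toy$masks,
                       hidden_size = 8L, epochs = 20L, seed = 5)
  expect_identical(f1$params, f2$params)
  expect_identical(f1$prob, f2$prob)
  f0 <- train_view_gcn(toy$x, g$norm_adjacency, toy$labels, toy$masks,
                       hidden_size = 8L, lr = 0, epochs = 20L, seed = 5)
  init <- genet:::with_seed(5, genet:::gcn_init(ncol(toy$x), 8L, 2L))
  expect_equal(f0$params, init, tolerance = 1e-12)
})
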