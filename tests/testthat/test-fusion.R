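test_that("the cross-feature tensor is the outer product of view labels", {
  expect_equal(build_cross_feature_tensor(c(0, 1, 0), c(0, 0, 1)),
               outer(c(0, 1, 0), c(0, 0, 1)))
  t2 <- build_cross_feature_tensor(c(0.5, 0.5), c(0.2, 0.8))
  expect_equal(t2, rbind(c(0.1, 0.4), c(0.1, 0.4)))
  expect_error(build_cross_feature_tensor(c(1, 0), c(1, 0, 0)),
               "equal length")
})

test_that("tensor mass is conserved for simplex inputs", {
  set.seed(301)
  for (rep in 1:10) {
    c <- sample(2:6, 1)
    p <- rexp(c); p <- p / sum(p)
    q <- rexp(c); q <- q / sum(q)
    expect_equal(sum(build_cross_feature_tensor(p, q)), 1, tolerance = 1e-9)
  }
  # matrix form: every row of the flattened tensor sums to 1
  p <- matrix(rexp(12), 4); p <- p / rowSums(p)
  q <- matrix(rexp(12), 4); q <- q / rowSums(q)
  v <- build_cross_feature_tensor(p, q)
  expect_equal(rowSums(v), rep(1, 4), tolerance = 1e-9)
})

test_that("a uniform view makes tensor rows proportional to the other view", {
  q <- c(0.1, 0.6, 0.3)
  t <- build_cross_feature_tensor(rep(1 / 3, 3), q)
  for (i in 1:3) expect_equal(t[i, ], q / 3)
  t2 <- build_cross_feature_tensor(q, rep(1 / 3, 3))
  for (j in 1:3) expect_equal(t2[, j], q / 3)
})

test_that("flattening is row-major and invertible", {
  m <- rbind(c(1, 2), c(3, 4))
  expect_equal(flatten_tensor(m), c(1, 2, 3, 4))
  expect_equal(unflatten_tensor(flatten_tensor(m)), m)
  expect_equal(flatten_tensor(matrix(7)), 7)
  set.seed(302)
  m2 <- matrix(rnorm(25), 5)
  expect_equal(unflatten_tensor(flatten_tensor(m2)), m2)
  expect_error(unflatten_tensor(1:3), "perfect square")
  # the matrix (multi-sample) tensor layout matches per-sample flattening
  p <- matrix(rexp(6), 2); p <- p / rowSums(p)
  q <- matrix(rexp(6), 2); q <- q / rowSums(q)
  v <- build_cross_feature_tensor(p, q)
  expect_equal(v[1, ], flatten_tensor(build_cross_feature_tensor(p[1, ], q[1, ])))
})

test_that("the regression head computes w2'ReLU(W1 v + b1) + b2", {
  params <- list(w1 = matrix(0, 4, 3), b1 = rep(0, 3),
                 w2 = matrix(0, 3, 1), b2 = 1.5)
  expect_equal(fusion_forward(c(0.1, 0.4, 0.1, 0.4), params), 1.5)
  # identity-like W1 and a summing output layer add up the tensor mass
  params2 <- list(w1 = diag(4), b1 = rep(0, 4),
                  w2 = matrix(1, 4, 1), b2 = 0)
  expect_equal(fusion_forward(c(0.1, 0.4, 0.1, 0.4), params2), 1.0)
  # linear in v while pre-activations stay positive
  set.seed(303)
  params3 <- list(w1 = matrix(abs(rnorm(8)), 4), b1 = rep(0, 2),
                  w2 = matrix(rnorm(2), 2, 1), b2 = 0.3)
  v1 <- runif(4); v2 <- runif(4)
  expect_equal(fusion_forward(v1 + v2, params3) + params3$b2,
               fusion_forward(v1, params3) + fusion_forward(v2, params3),
               tolerance = 1e-9)
  expect_error(fusion_forward(1:5, params3), "does not match")
})

test_that("backprop through the whole fusion path matches finite differences", {
  set.seed(304)
  n <- 5; d <- 4; hid <- 3; cc <- 3
  x_tf <- matrix(rnorm(n * d), n)
  x_hm <- matrix(rnorm(n * d), n)
  a_tf <- normalize_adjacency(oracle_sparsify(oracle_cosine(abs(x_tf)), 1))
  a_hm <- normalize_adjacency(oracle_sparsify(oracle_cosine(abs(x_hm)), 1))
  y <- rnorm(n)
  mask <- c(TRUE, TRUE, TRUE, FALSE, TRUE)
  params <- list(
    tf = list(w1 = matrix(rnorm(d * hid), d), b1 = rnorm(hid),
              w2 = matrix(rnorm(hid * cc), hid), b2 = rnorm(cc)),
    hm = list(w1 = matrix(rnorm(d * hid), d), b1 = rnorm(hid),
              w2 = matrix(rnorm(hid * cc), hid), b2 = rnorm(cc)),
    head = list(w1 = matrix(rnorm(cc^2 * hid), cc^2), b1 = rnorm(hid),
                w2 = matrix(rnorm(hid), hid), b2 = rnorm(1)))
  bp <- genet_fusion_grad(x_tf, x_hm, a_tf, a_hm, params, y, mask)
  for (blk in c("tf", "hm", "head")) {
    fd <- finite_diff_grads(function(pblk) {
      p2 <- params
      p2[[blk]] <- pblk
      genet_fusion_grad(x_tf, x_hm, a_tf, a_hm, p2, y, mask)$loss
    }, params[[blk]])
    for (nm in names(fd)) {
      denom <- max(abs(fd[[nm]]), 1e-8)
      expect_lt(max(abs(fd[[nm]] - bp$grads[[blk]][[nm]])) / denom, 1e-4)
    }
  }
})

test_that("the fitted model is reproducible and exposes its S3 surface", {
  sim <- small_sim()
  f1 <- small_fit(sim)
  f2 <- small_fit(sim)
  expect_identical(f1$fitted, f2$fitted)
  expect_identical(coef(f1), coef(f2))
  n <- length(sim$expression$expression)
  expect_s3_class(f1, "genet")
  expect_length(fitted(f1), n)
  expect_equal(unname(residuals(f1)), sim$expression$expression - f1$fitted)
  expect_length(predict(f1, "test"), sum(f1$masks$test))
  expect_equal(f1$metrics$test$rmse^2, f1$metrics$test$mse, tolerance = 1e-12)
  expect_output(print(f1), "test: MSE")
  expect_output(summary(f1), "Metrics by split")
  pdf(NULL)
  on.exit(dev.off())
  expect_invisible(plot(f1))
})

test_that("misaligned views are rejected", {
  sim <- small_sim(seed = 12, n_genes = 6L, n_cell_lines = 3L)
  expect_error(genet_fit(sim$fm_tf$values[-1, ], sim$fm_hm$values,
                         sim$expression$expression, seed = 1),
               "row-aligned")
})
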