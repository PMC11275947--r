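# Shared dense-network primitives: Glorot initialisation, full-batch Adam,
# softmax/ReLU, and a small MLP trainer reused by the fusion head and the
# simple-NN baseline. Everything is seeded and deterministic.

relu <- function(x) {
  x[x < 0] <- 0
  x
}

# row-wise softmax with max-shift for stability
softmax_rows <- function(z) {
  z <- z - apply(z, 1L, max)
  e <- exp(z)
  e / rowSums(e)
}

# Glorot/Xavier uniform init for a d_in x d_out weight matrix
glorot_init <- function(d_in, d_out) {
  lim <- sqrt(6 / (d_in + d_out))
  matrix(stats::runif(d_in * d_out, -lim, lim), d_in, d_out)
}

# Adam state for a named list of parameter arrays
adam_init <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0),
       t = 0L)
}

# One Adam step; returns list(params, state). grads matches params by name.
adam_step <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1L
  t <- state$t
  for (nm in names(params)) {
    g <- grads[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g^2
    mhat <- state$m[[nm]] / (1 - beta1^t)
    vhat <- state$v[[nm]] / (1 - beta2^t)
    params[[nm]] <- params[[nm]] - lr * mhat / (sqrt(vhat) + eps)
  }
  list(params = params, state = state)
}

# evaluate an expression under a local, seeded RNG without disturbing the
# caller's RNG state
with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  force(code)
}

# z-score each column; zero-variance columns are left centred at 0
standardize_columns <- function(x) {
  mu <- colMeans(x)
  sdv <- apply(x, 2L, stats::sd)
  sdv[sdv == 0] <- 1
  sweep(sweep(x, 2L, mu), 2L, sdv, "/")
}

# ---- single-hidden-layer MLP regressor (ReLU hidden, linear output) -------

mlp_init <- function(d_in, hidden) {
  list(w1 = glorot_init(d_in, hidden), b1 = numeric(hidden),
       w2 = glorot_init(hidden, 1L), b2 = 0)
}

mlp_forward <- function(x, params) {
  h <- relu(sweep(x %*% params$w1, 2L, params$b1, "+"))
  yhat <- drop(h %*% params$w2) + params$b2
  list(h = h, yhat = yhat)
}

# gradients of mean((yhat - y)^2) over the rows of x
mlp_grad <- function(x, y, params, fwd = NULL) {
  n <- nrow(x)
  if (is.null(fwd)) fwd <- mlp_forward(x, params)
  dy <- matrix(2 * (fwd$yhat - y) / n, ncol = 1L)
  gw2 <- crossprod(fwd$h, dy)
  gb2 <- sum(dy)
  dh <- dy %*% t(params$w2)
  dh[fwd$h <= 0] <- 0
  gw1 <- crossprod(x, dh)
  gb1 <- colSums(dh)
  list(w1 = gw1, b1 = gb1, w2 = gw2, b2 = gb2)
}

# full-batch Adam training of the MLP on (x, y); deterministic given seed
mlp_train <- function(x, y, hidden = 64L, lr = 0.01, epochs = 200L, seed = 1L) {
  params <- with_seed(seed, mlp_init(ncol(x), hidden))
  state <- adam_init(params)
  for (e in seq_len(epochs)) {
    g <- mlp_grad(x, y, params)
    st <- adam_step(params, g, state, lr)
    params <- st$params
    state <- st$state
    if (!all(vapply(params, function(p) all(is.finite(p)), TRUE))) {
      stop("MLP training diverged (non-finite parameters) at epoch ", e)
    }
  }
  params
}
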