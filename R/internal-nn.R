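# Internal neural-network plumbing shared by the generator, the
# discriminator and the training loop. Tensors are plain R arrays with
# dim c(H, W, C, N); parameters live in flat named lists of arrays so the
# optimizer can walk them generically.

`%||%` <- function(a, b) if (is.null(a)) b else a

# Reshape (H,W,C,N) -> (H*W*N) x C matrix for per-channel statistics.
to_cmat <- function(x) {
  d <- dim(x)
  matrix(aperm(x, c(1L, 2L, 4L, 3L)), ncol = d[3])
}

from_cmat <- function(m, d) {
  aperm(array(m, c(d[1], d[2], d[4], d[3])), c(1L, 2L, 4L, 3L))
}

conv2d <- function(x, w, b = NULL, stride = 1L, pad = 0L) {
  conv2d_fwd_cpp(x, w, b %||% numeric(dim(w)[4]), as.integer(stride),
                 as.integer(pad), !is.null(b))
}

conv2d_grad <- function(x, w, gy, stride = 1L, pad = 0L, use_bias = FALSE) {
  conv2d_bwd_cpp(x, w, gy, as.integer(stride), as.integer(pad), use_bias)
}

dwconv2d <- function(x, w, stride = 1L, pad = 0L) {
  dwconv2d_fwd_cpp(x, w, as.integer(stride), as.integer(pad))
}

dwconv2d_grad <- function(x, w, gy, stride = 1L, pad = 0L) {
  dwconv2d_bwd_cpp(x, w, gy, as.integer(stride), as.integer(pad))
}

upsample_nn2 <- function(x) {
  d <- dim(x)
  x[rep(seq_len(d[1]), each = 2L), rep(seq_len(d[2]), each = 2L), , , drop = FALSE]
}

# Adjoint of nearest-neighbour x2 upsampling: sum gradients over 2x2 blocks.
upsample_nn2_grad <- function(g) {
  d <- dim(g)
  i1 <- seq(1L, d[1], by = 2L)
  j1 <- seq(1L, d[2], by = 2L)
  g[i1, j1, , , drop = FALSE] + g[i1 + 1L, j1, , , drop = FALSE] +
    g[i1, j1 + 1L, , , drop = FALSE] + g[i1 + 1L, j1 + 1L, , , drop = FALSE]
}

cat_channels <- function(a, b) {
  da <- dim(a)
  db <- dim(b)
  stopifnot(all(da[c(1, 2, 4)] == db[c(1, 2, 4)]))
  out <- array(0, c(da[1], da[2], da[3] + db[3], da[4]))
  out[, , seq_len(da[3]), ] <- a
  out[, , da[3] + seq_len(db[3]), ] <- b
  out
}

split_channels <- function(g, n_first) {
  d <- dim(g)
  list(first = g[, , seq_len(n_first), , drop = FALSE],
       second = g[, , (n_first + 1L):d[3], , drop = FALSE])
}

lrelu <- function(x, alpha = 0.2) ifelse(x > 0, x, alpha * x)
lrelu_grad <- function(x, g, alpha = 0.2) g * ifelse(x > 0, 1, alpha)
relu <- function(x) pmax(x, 0)
relu_grad <- function(x, g) g * (x > 0)
tanh_grad <- function(y, g) g * (1 - y^2)
sigmoid <- function(z) 1 / (1 + exp(-z))

# Batch normalization over (H, W, N) per channel. Returns the normalized
# tensor, a backward cache, and the updated running statistics.
bn_forward <- function(x, gamma, beta, run_mean, run_var, training,
                       eps = 1e-5, momentum = 0.1) {
  d <- dim(x)
  xm <- to_cmat(x)
  if (training) {
    mu <- colMeans(xm)
    v <- colMeans(xm^2) - mu^2
    run_mean <- (1 - momentum) * run_mean + momentum * mu
    run_var <- (1 - momentum) * run_var + momentum * v
  } else {
    mu <- run_mean
    v <- run_var
  }
  inv_std <- 1 / sqrt(v + eps)
  xhat <- sweep(sweep(xm, 2L, mu, "-"), 2L, inv_std, "*")
  y <- sweep(sweep(xhat, 2L, gamma, "*"), 2L, beta, "+")
  list(y = from_cmat(y, d),
       cache = list(xhat = xhat, inv_std = inv_std, gamma = gamma, d = d,
                    training = training),
       run_mean = run_mean, run_var = run_var)
}

bn_backward <- function(cache, gy) {
  d <- cache$d
  gm <- to_cmat(gy)
  g_gamma <- colSums(gm * cache$xhat)
  g_beta <- colSums(gm)
  if (cache$training) {
    n <- nrow(gm)
    t1 <- sweep(gm, 2L, colMeans(gm), "-")
    t2 <- sweep(cache$xhat, 2L, colMeans(gm * cache$xhat), "*")
    gx <- sweep(t1 - t2, 2L, cache$gamma * cache$inv_std, "*")
  } else {
    gx <- sweep(gm, 2L, cache$gamma * cache$inv_std, "*")
  }
  list(gx = from_cmat(gx, d), g_gamma = g_gamma, g_beta = g_beta)
}

# Inverted dropout; the same mask is reused in the backward pass.
dropout_forward <- function(x, rate) {
  keep <- 1 - rate
  mask <- array((stats::runif(length(x)) < keep) / keep, dim(x))
  list(y = x * mask, mask = mask)
}

# --- Adam ------------------------------------------------------------------

adam_init <- function(params) {
  # zero states shaped exactly like the parameters (attributes preserved)
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0),
       t = 0L)
}

adam_update <- function(params, grads, opt, lr, beta1 = 0.5, beta2 = 0.999,
                        eps = 1e-8) {
  opt$t <- opt$t + 1L
  bc1 <- 1 - beta1^opt$t
  bc2 <- 1 - beta2^opt$t
  for (nm in names(params)) {
    g <- grads[[nm]]
    if (is.null(g)) next
    opt$m[[nm]] <- beta1 * opt$m[[nm]] + (1 - beta1) * g
    opt$v[[nm]] <- beta2 * opt$v[[nm]] + (1 - beta2) * g^2
    params[[nm]] <- params[[nm]] -
      lr * (opt$m[[nm]] / bc1) / (sqrt(opt$v[[nm]] / bc2) + eps)
  }
  list(params = params, opt = opt)
}

init_weight <- function(dims, sd = 0.02) {
  array(stats::rnorm(prod(dims), sd = sd), dims)
}
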