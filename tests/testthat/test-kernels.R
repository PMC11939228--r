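# The C++ convolution kernels are the foundation of everything else, so
# they are checked against a direct triple-loop oracle and against
# central-difference gradients.

direct_conv <- function(x, w, stride, pad) {
  H <- dim(x)[1]; W <- dim(x)[2]; Cin <- dim(x)[3]; N <- dim(x)[4]
  kh <- dim(w)[1]; kw <- dim(w)[2]; Cout <- dim(w)[4]
  Ho <- (H + 2 * pad - kh) %/% stride + 1
  Wo <- (W + 2 * pad - kw) %/% stride + 1
  y <- array(0, c(Ho, Wo, Cout, N))
  for (n in 1:N) for (co in 1:Cout) for (ho in 1:Ho) for (wo in 1:Wo) {
    acc <- 0
    for (c in 1:Cin) for (i in 1:kh) for (j in 1:kw) {
      hs <- (ho - 1) * stride - pad + i
      ws <- (wo - 1) * stride - pad + j
      if (hs >= 1 && hs <= H && ws >= 1 && ws <= W)
        acc <- acc + w[i, j, c, co] * x[hs, ws, c, n]
    }
    y[ho, wo, co, n] <- acc
  }
  y
}

test_that("conv2d forward matches a direct-loop oracle across strides and pads", {
  set.seed(42)
  for (case in list(c(1, 1), c(2, 1), c(1, 0), c(2, 0))) {
    x <- array(rnorm(6 * 6 * 2 * 2), c(6, 6, 2, 2))
    w <- array(rnorm(3 * 3 * 2 * 4), c(3, 3, 2, 4))
    got <- ghostgan:::conv2d(x, w, stride = case[1], pad = case[2])
    expect_equal(got, direct_conv(x, w, case[1], case[2]), tolerance = 1e-12)
  }
  # even 4x4 kernel (discriminator geometry)
  x <- array(rnorm(8 * 8 * 1), c(8, 8, 1, 1))
  w <- array(rnorm(4 * 4 * 1 * 2), c(4, 4, 1, 2))
  expect_equal(ghostgan:::conv2d(x, w, stride = 2, pad = 1),
               direct_conv(x, w, 2, 1), tolerance = 1e-12)
})

test_that("conv2d backward agrees with central differences", {
  set.seed(1)
  x <- array(rnorm(5 * 5 * 2), c(5, 5, 2, 1))
  w <- array(rnorm(3 * 3 * 2 * 3), c(3, 3, 2, 3))
  y <- ghostgan:::conv2d(x, w, stride = 2, pad = 1)
  gr <- ghostgan:::conv2d_grad(x, w, 2 * y, stride = 2, pad = 1)
  f <- function(xx, ww) sum(ghostgan:::conv2d(xx, ww, stride = 2, pad = 1)^2)
  eps <- 1e-6
  num_x <- x
  for (i in seq_along(x)) {
    xp <- x; xp[i] <- xp[i] + eps
    xm <- x; xm[i] <- xm[i] - eps
    num_x[i] <- (f(xp, w) - f(xm, w)) / (2 * eps)
  }
  expect_equal(gr$gx, num_x, tolerance = 1e-5)
  num_w <- w
  for (i in seq_along(w)) {
    wp <- w; wp[i] <- wp[i] + eps
    wm <- w; wm[i] <- wm[i] - eps
    num_w[i] <- (f(x, wp) - f(x, wm)) / (2 * eps)
  }
  expect_equal(gr$gw, num_w, tolerance = 1e-5)
})

test_that("depthwise convolution derives output channel c*M+m from input channel c", {
  set.seed(2)
  x <- array(rnorm(6 * 6 * 3), c(6, 6, 3, 1))
  # delta kernels: each output should reproduce (a shift of) its own source
  w <- array(0, c(3, 3, 3, 2))
  w[2, 2, , 1] <- 1  # m = 1: identity
  w[1, 2, , 2] <- 1  # m = 2: shift by one row
  y <- ghostgan:::dwconv2d(x, w, stride = 1, pad = 1)
  expect_equal(dim(y)[3], 6)
  for (c in 1:3) {
    expect_equal(y[, , (c - 1) * 2 + 1, 1], x[, , c, 1])
    expect_equal(y[2:6, , (c - 1) * 2 + 2, 1], x[1:5, , c, 1])
  }
})

test_that("depthwise backward agrees with central differences", {
  set.seed(3)
  x <- array(rnorm(5 * 5 * 2), c(5, 5, 2, 1))
  w <- array(rnorm(3 * 3 * 2 * 2), c(3, 3, 2, 2))
  y <- ghostgan:::dwconv2d(x, w, stride = 1, pad = 1)
  gr <- ghostgan:::dwconv2d_grad(x, w, 2 * y, stride = 1, pad = 1)
  f <- function(xx, ww) sum(ghostgan:::dwconv2d(xx, ww, stride = 1, pad = 1)^2)
  eps <- 1e-6
  num_x <- x
  for (i in seq_along(x)) {
    xp <- x; xp[i] <- xp[i] + eps
    xm <- x; xm[i] <- xm[i] - eps
    num_x[i] <- (f(xp, w) - f(xm, w)) / (2 * eps)
  }
  expect_equal(gr$gx, num_x, tolerance = 1e-5)
  num_w <- w
  for (i in seq_along(w)) {
    wp <- w; wp[i] <- wp[i] + eps
    wm <- w; wm[i] <- wm[i] - eps
    num_w[i] <- (f(x, wp) - f(x, wm)) / (2 * eps)
  }
  expect_equal(gr$gw, num_w, tolerance = 1e-5)
})

test_that("batch normalization backward matches central differences", {
  set.seed(4)
  x <- array(rnorm(4 * 4 * 3 * 2), c(4, 4, 3, 2))
  gamma <- runif(3, 0.5, 1.5)
  beta <- rnorm(3)
  tgt <- array(rnorm(length(x)), dim(x))
  fwd <- function(xx) {
    ghostgan:::bn_forward(xx, gamma, beta, rep(0, 3), rep(1, 3), TRUE)$y
  }
  out <- ghostgan:::bn_forward(x, gamma, beta, rep(0, 3), rep(1, 3), TRUE)
  gb <- ghostgan:::bn_backward(out$cache, 2 * (out$y - tgt))
  f <- function(xx) sum((fwd(xx) - tgt)^2)
  eps <- 1e-5
  idx <- sample(length(x), 20)
  for (i in idx) {
    xp <- x; xp[i] <- xp[i] + eps
    xm <- x; xm[i] <- xm[i] - eps
    expect_equal(gb$gx[i], (f(xp) - f(xm)) / (2 * eps), tolerance = 1e-4)
  }
})
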