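test_that("binary cross-entropy matches closed forms", {
  expect_equal(bce_loss(1, 0.5), log(2), tolerance = 1e-9)
  expect_equal(bce_loss(c(0, 1), c(0.2, 0.8)), -log(0.8), tolerance = 1e-9)
  expect_lt(bce_loss(c(1, 0), c(1 - 1e-7, 1e-7)), 1e-6)
  expect_error(bce_loss(numeric(0), numeric(0)), "empty")
  expect_error(bce_loss(c(1, 0), 0.5), "mismatch")
  expect_error(bce_loss(2, 0.5), "\\[0, 1\\]")
  # non-negativity over random inputs, and logit form consistency
  withr::with_seed(1, {
    for (i in 1:20) {
      y <- round(runif(10))
      p <- runif(10)
      expect_gte(bce_loss(y, p), 0)
    }
    z <- rnorm(50, sd = 3)
    expect_equal(ghostgan:::bce_logits(1, z), bce_loss(rep(1, 50), ghostgan:::sigmoid(z)),
                 tolerance = 1e-6)
    expect_equal(ghostgan:::bce_logits(0, z), bce_loss(rep(0, 50), ghostgan:::sigmoid(z)),
                 tolerance = 1e-6)
  })
})

test_that("ssim is 1 on identical images, symmetric, and bounded", {
  p <- ssim_params(dynamic_range = 1)
  withr::with_seed(2, {
    x <- matrix(runif(32 * 32), 32, 32)
    y <- matrix(runif(32 * 32), 32, 32)
  })
  expect_identical(ssim(x, x, p), 1)
  expect_equal(ssim_loss(x, x, p), 0)
  expect_lt(abs(ssim(x, y, p) - ssim(y, x, p)), 1e-9)
  expect_lte(ssim(x, y, p), 1)
  expect_error(ssim(x, y[1:20, 1:20], p), "mismatch")
  expect_error(ssim(x[1:8, 1:8], y[1:8, 1:8], p), "window")
})

test_that("distinct constant images hit the zero-variance closed form", {
  p <- ssim_params(dynamic_range = 1)
  a <- matrix(0, 16, 16)
  b <- matrix(1, 16, 16)
  C1 <- (0.01 * 1)^2
  expect_equal(ssim(a, b, p), C1 / (1 + C1), tolerance = 1e-12)
})

test_that("ssim agrees with the scikit-image reference implementation", {
  p <- ssim_params(dynamic_range = 1)
  withr::with_seed(3, {
    for (i in 1:3) {
      x <- matrix(runif(64 * 64), 64, 64)
      y <- matrix(runif(64 * 64), 64, 64)
      expect_equal(ssim(x, y, p), skimage_ssim(x, y, 1), tolerance = 1e-6)
    }
  })
})

test_that("ssim loss grows with corruption and exceeds 1 for anti-correlated patterns", {
  p <- ssim_params(dynamic_range = 2)
  withr::with_seed(4, {
    x <- matrix(sin(seq(0, 8 * pi, length.out = 32)), 32, 32) * 0.5
    losses <- vapply(c(0.05, 0.2, 0.5), function(s) {
      ssim_loss(x, x + matrix(rnorm(1024, sd = s), 32, 32), p)
    }, numeric(1))
  })
  expect_true(all(diff(losses) > 0))
  # zero-window-mean pattern: negating it flips the structure term
  x <- 0.5 * outer(1:32, 1:32, function(i, j) (-1)^(i + j))
  l_anti <- ssim_loss(x, -x, p)
  expect_gt(l_anti, 1)
  expect_lte(l_anti, 2)
})

test_that("the analytic ssim gradient matches central differences", {
  p <- ssim_params(dynamic_range = 1)
  withr::with_seed(5, {
    x <- matrix(runif(14 * 14), 14, 14)
    y <- matrix(runif(14 * 14), 14, 14)
  })
  sg <- ghostgan:::ssim_grad_channel(x, y, p)
  expect_equal(sg$value, ssim(x, y, p))
  eps <- 1e-6
  num <- y
  for (i in seq_along(y)) {
    yp <- y; yp[i] <- yp[i] + eps
    ym <- y; ym[i] <- ym[i] - eps
    num[i] <- (ssim(x, yp, p) - ssim(x, ym, p)) / (2 * eps)
  }
  expect_equal(sg$grad, num, tolerance = 1e-6)
})

test_that("the combined loss is the stated weighted decomposition", {
  withr::with_seed(6, {
    gen <- array(runif(16 * 16 * 1 * 2, -1, 1), c(16, 16, 1, 2))
    real <- array(runif(16 * 16 * 1 * 2, -1, 1), c(16, 16, 1, 2))
    logits <- array(rnorm(3 * 3 * 1 * 2), c(3, 3, 1, 2))
  })
  w <- loss_weights(1, 1)
  rec <- combined_generator_loss(logits, gen, real, w)
  expect_equal(rec$l_combined, rec$l_bce + rec$l_ssim, tolerance = 1e-6)
  # zero logits give the ln 2 adversarial value; example arithmetic
  rec0 <- combined_generator_loss(array(0, dim(logits)), gen, real, w)
  expect_equal(rec0$l_bce, log(2), tolerance = 1e-9)
  w2 <- loss_weights(1, 0)
  rec2 <- combined_generator_loss(logits, gen, real, w2)
  expect_equal(rec2$l_combined, rec2$l_bce)
  expect_equal(rec2$l_ssim, 0)
  # stated example: 0.6931 + 0.25 under unit weights
  expect_equal(1 * 0.6931 + 1 * 0.25, 0.9431)
  expect_error(loss_weights(0, 0), "not both zero")
})

test_that("the discriminator loss has the right fixed points and symmetry", {
  z0 <- array(0, c(2, 2, 1, 1))
  expect_equal(discriminator_loss(z0, z0), log(2), tolerance = 1e-9)
  big <- array(30, c(2, 2, 1, 1))
  expect_lt(discriminator_loss(big, -big), 1e-6)
  withr::with_seed(7, {
    a <- array(rnorm(8), c(2, 2, 2, 1))
    b <- array(rnorm(8), c(2, 2, 2, 1))
  })
  expect_equal(discriminator_loss(a, b), discriminator_loss(-b, -a),
               tolerance = 1e-9)
})

test_that("the mean-squared-error hook behaves", {
  expect_equal(mse_loss(c(0, 2), c(1, 0)), 2.5)
  expect_equal(mse_loss(1:5, 1:5), 0)
  expect_error(mse_loss(1:3, 1:4), "mismatch")
})
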