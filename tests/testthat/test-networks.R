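test_that("generator depth is auto-reduced and geometry validated", {
  expect_equal(generator_spec(image_size = 64, depth = 6)$depth, 4)
  expect_equal(generator_spec(image_size = 256, depth = 6)$depth, 6)
  expect_equal(generator_spec(image_size = 32, depth = 6)$depth, 3)
  expect_error(generator_spec(image_size = 4, depth = 1), "image too small")
})

test_that("the generator maps masks to same-size images in [-1, 1] at several depths", {
  for (size in c(32, 64)) {
    spec <- generator_spec(base_width = 8, image_size = size)
    set.seed(1)
    g <- build_generator(spec)
    x <- array(runif(size * size * 3, -1, 1), c(size, size, 1, 3))
    y <- generator_forward(g, x)
    expect_identical(dim(y), c(as.integer(size), as.integer(size), 1L, 3L))
    expect_true(all(y >= -1 & y <= 1))
  }
  spec <- generator_spec(base_width = 8, image_size = 32)
  g <- build_generator(spec)
  expect_error(generator_forward(g, array(0, c(16, 16, 1, 1))), "expected")
})

test_that("generator forwards are deterministic without dropout, stochastic with it", {
  spec <- generator_spec(base_width = 8, image_size = 32)
  set.seed(2)
  g <- build_generator(spec)
  x <- array(runif(32 * 32 * 2, -1, 1), c(32, 32, 1, 2))
  expect_identical(generator_forward(g, x), generator_forward(g, x))
  a <- generate_batch(g, x, seed = 1)
  b <- generate_batch(g, x, seed = 1)
  c <- generate_batch(g, x, seed = 2)
  expect_identical(a, b)
  expect_gt(max(abs(a - c)), 1e-6)
})

test_that("the generator does not ignore its conditioning at initialization", {
  spec <- generator_spec(base_width = 8, image_size = 32)
  set.seed(3)
  g <- build_generator(spec)
  zeros <- array(-1, c(32, 32, 1, 1))
  ones <- array(1, c(32, 32, 1, 1))
  expect_gt(max(abs(generator_forward(g, zeros) - generator_forward(g, ones))),
            1e-4)
})

test_that("the ghost toggle shrinks only the encoder", {
  sg <- generator_spec(base_width = 16, image_size = 64, use_ghost_encoder = TRUE)
  ss <- generator_spec(base_width = 16, image_size = 64, use_ghost_encoder = FALSE)
  set.seed(4)
  g1 <- build_generator(sg)
  g2 <- build_generator(ss)
  expect_lt(count_params(g1), count_params(g2))
  expect_lt(count_params(g1, "^enc"), count_params(g2, "^enc"))
  expect_equal(count_params(g1, "^dec|^final"), count_params(g2, "^dec|^final"))
})

test_that("generated images denormalize to valid 8-bit output end to end", {
  pair <- make_phantom_pair(tiny_phantom_spec(size = 32, seed = 5), 0)
  spec <- generator_spec(base_width = 8, image_size = 32)
  set.seed(5)
  g <- build_generator(spec)
  x <- array(normalize_image(pair$mask), c(32, 32, 1, 1))
  img <- denormalize_image(generator_forward(g, x))
  expect_true(all(img >= 0 & img <= 255))
  expect_true(all(img == floor(img)))
})

test_that("a 3-layer discriminator on 256px pairs emits a 30x30 patch map", {
  spec <- discriminator_spec(in_channels = 2, base_width = 4, n_layers = 3)
  set.seed(6)
  d <- build_discriminator(spec)
  z <- discriminator_forward(d, array(0, c(256, 256, 2, 1)))
  expect_identical(dim(z), c(30L, 30L, 1L, 1L))
})

test_that("each patch logit sees a 70x70 receptive field", {
  spec <- discriminator_spec(in_channels = 2, base_width = 2, n_layers = 3)
  set.seed(7)
  d <- build_discriminator(spec)
  x <- array(rnorm(256 * 256 * 2), c(256, 256, 2, 1))
  fd <- ghostgan:::disc_forward_full(d, x, training = FALSE)
  gy <- array(0, dim(fd$out))
  gy[15, 15, 1, 1] <- 1  # a central logit
  gx <- ghostgan:::disc_backward(d, fd$cache, gy)$gx
  footprint <- abs(gx[, , 1, 1]) > 0
  rows <- range(which(rowSums(footprint) > 0))
  cols <- range(which(colSums(footprint) > 0))
  expect_equal(diff(rows) + 1, 70)
  expect_equal(diff(cols) + 1, 70)
})

test_that("generator backward matches numerical gradients through every layer type", {
  spec <- generator_spec(base_width = 4, depth = 3, image_size = 16,
                         dropout_rate = 0)
  set.seed(8)
  g <- build_generator(spec)
  x <- array(runif(16 * 16 * 2, -1, 1), c(16, 16, 1, 2))
  ff <- ghostgan:::gen_forward_full(g, x, training = TRUE, use_dropout = FALSE)
  tgt <- array(runif(length(ff$out), -1, 1), dim(ff$out))
  gb <- ghostgan:::gen_backward(g, ff$cache, 2 * (ff$out - tgt))
  loss_of <- function(params) {
    g2 <- g
    g2$params <- params
    o <- ghostgan:::gen_forward_full(g2, x, training = TRUE, use_dropout = FALSE)$out
    sum((o - tgt)^2)
  }
  eps <- 1e-5
  for (nm in names(g$params)) {
    idx <- sample(length(g$params[[nm]]), min(2, length(g$params[[nm]])))
    for (i in idx) {
      pp <- g$params; pp[[nm]][i] <- pp[[nm]][i] + eps
      pm <- g$params; pm[[nm]][i] <- pm[[nm]][i] - eps
      num <- (loss_of(pp) - loss_of(pm)) / (2 * eps)
      expect_equal(gb$grads[[nm]][i], num, tolerance = 1e-3,
                   label = paste("grad", nm))
    }
  }
})
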