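# Training-loop contracts on a 32px micro profile; longer smoke runs live
# in the acceptance suite.

micro_batch <- function(cfg, n = 4L, seed = 1L) {
  man <- tiny_phantom_manifest(n = n, size = cfg$image_size, seed = seed)
  pairs <- lapply(seq_len(n), function(i) ghostgan:::read_pair(man, i))
  ghostgan:::stack_batch(pairs, seq_len(n), cfg)
}

test_that("one training step moves generator parameters; lr 0 moves nothing", {
  cfg <- tiny_train_cfg(seed = 1)
  set.seed(cfg$seed)
  models <- ghostgan:::build_models(cfg)
  opts <- list(gen = ghostgan:::adam_init(models$gen$params),
               disc = ghostgan:::adam_init(models$disc$params))
  batch <- micro_batch(cfg)
  out <- train_step(batch, models, opts, cfg, step = 1)
  expect_false(identical(out$models$gen$params, models$gen$params))
  expect_s3_class(out$record, "loss_record")
  expect_equal(out$record$l_combined,
               out$record$l_bce + out$record$l_ssim, tolerance = 1e-9)

  cfg0 <- tiny_train_cfg(seed = 1, learning_rate = 0)
  out0 <- train_step(batch, models, opts, cfg0, step = 1)
  expect_identical(out0$models$gen$params, models$gen$params)
  expect_identical(out0$models$disc$params, models$disc$params)
})

test_that("identical seeds give identical loss histories", {
  man <- tiny_phantom_manifest(n = 6, size = 32, seed = 3)
  cfg <- tiny_train_cfg(seed = 5, steps = 10)
  a <- train_gan(man, cfg)
  b <- train_gan(man, cfg)
  expect_identical(a$history, b$history)
  expect_identical(a$gen$params, b$gen$params)
  expect_false(any(!is.finite(as.matrix(a$history[, -1]))))
  c <- train_gan(man, tiny_train_cfg(seed = 6, steps = 10))
  expect_false(identical(a$history$l_combined, c$history$l_combined))
})

test_that("checkpoints round-trip exactly and resume reproduces the next steps", {
  man <- tiny_phantom_manifest(n = 6, size = 32, seed = 4)
  ckdir <- tempfile("ck")
  cfg <- tiny_train_cfg(seed = 2, steps = 12, checkpoint_every = 8L,
                        checkpoint_dir = ckdir)
  full <- train_gan(man, cfg)
  ck_path <- file.path(ckdir, "ckpt_000008.rds")
  ck <- load_checkpoint(ck_path)
  expect_identical(ck$step, 8L)
  # parameter tensors round-trip bit-identically
  resumed <- train_gan(man, cfg, resume_from = ck_path)
  expect_equal(full$history, resumed$history, ignore_attr = TRUE)
  expect_identical(full$gen$params, resumed$gen$params)
  # sidecar records both specs and the seed
  side <- jsonlite::fromJSON(paste0(ck_path, ".json"))
  expect_equal(side$seed, 2)
  expect_equal(side$generator_spec$base_width, 8)
  expect_equal(side$discriminator_spec$n_layers, 2)
})

test_that("resuming under a mismatched generator spec is refused", {
  man <- tiny_phantom_manifest(n = 6, size = 32, seed = 4)
  ckdir <- tempfile("ck")
  cfg <- tiny_train_cfg(seed = 2, steps = 9, checkpoint_every = 8L,
                        checkpoint_dir = ckdir)
  train_gan(man, cfg)
  other <- tiny_train_cfg(seed = 2, steps = 12, base_width = 16L)
  expect_error(train_gan(man, other,
                         resume_from = file.path(ckdir, "ckpt_000008.rds")),
               "spec")
  expect_error(load_checkpoint(tempfile()), "not found")
})

test_that("an empty train split is a configuration error", {
  man <- tiny_phantom_manifest(n = 1, size = 32, seed = 9)
  man <- split_dataset(man, seed = 1)  # n = 1 puts everything in test
  expect_error(train_gan(man, tiny_train_cfg(steps = 2)), "empty train split")
})

test_that("the loss-mode comparison arms run and log the right terms", {
  man <- tiny_phantom_manifest(n = 6, size = 32, seed = 8)
  h_bce <- train_gan(man, tiny_train_cfg(seed = 3, steps = 3,
                                         loss_mode = "bce"))$history
  expect_true(all(h_bce$l_ssim == 0))
  expect_equal(h_bce$l_combined, h_bce$l_bce)
  h_mse <- train_gan(man, tiny_train_cfg(seed = 3, steps = 3,
                                         loss_mode = "mse"))$history
  expect_true(all(h_mse$l_ssim > 0))
  h_pix <- train_gan(man, tiny_train_cfg(seed = 3, steps = 3,
                                         bce_target = "pixel"))$history
  expect_true(all(is.finite(h_pix$l_combined)))
})

test_that("the ablation toggle trains a dense encoder with more parameters", {
  man <- tiny_phantom_manifest(n = 6, size = 32, seed = 2)
  g_ghost <- train_gan(man, tiny_train_cfg(seed = 1, steps = 2))$gen
  g_dense <- train_gan(man, tiny_train_cfg(seed = 1, steps = 2,
                                           ablation_no_ghost = TRUE))$gen
  expect_false(g_dense$spec$use_ghost_encoder)
  expect_lt(count_params(g_ghost), count_params(g_dense))
})
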