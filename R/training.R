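#' Training configuration
#'
#' Defaults follow the reference setup: batch size 64, learning rate 0.001,
#' Adam with `beta1 = 0.5`, 400 epochs at 256 x 256. That profile is
#' GPU-scale; for CPU work use [desk_profile()].
#'
#' @param batch_size Images per step.
#' @param learning_rate Adam learning rate of the generator.
#' @param disc_lr_factor Multiplier on `learning_rate` for the
#'   discriminator (two-time-scale updates keep the adversary from
#'   overpowering the generator in short runs).
#' @param beta1,beta2 Adam first/second-moment decay rates.
#' @param epochs Passes over the training split (ignored when `steps` is
#'   given).
#' @param steps Optional total step budget overriding `epochs`.
#' @param seed Integer seed; the only entropy source of a run.
#' @param image_size Square training resolution.
#' @param jitter_size Enlarged size before random cropping; default scales
#'   the canonical 256 -> 286 jitter to `image_size`.
#' @param base_width Generator base width.
#' @param depth Requested generator depth (auto-reduced for small images).
#' @param disc_base_width,disc_n_layers Discriminator width/depth.
#' @param ghost_ratio Ghost expansion ratio of the encoder.
#' @param ablation_no_ghost Build the encoder with dense convolutions
#'   instead of ghost blocks (the ablation arm).
#' @param dropout_rate Decoder dropout rate.
#' @param loss_mode `"combined"` (adversarial BCE + SSIM), `"bce"`
#'   (adversarial only) or `"mse"` (adversarial + mean-squared error) —
#'   the three arms of the loss-function comparison.
#' @param bce_target `"adversarial"` applies the BCE term to the
#'   discriminator's judgment of generated pairs (default); `"pixel"`
#'   applies it pixel-wise to the `[0, 1]`-rescaled images instead.
#' @param weights A [loss_weights()].
#' @param ssim An [ssim_params()] for the training loss (dynamic range 2).
#' @param checkpoint_every Steps between checkpoints (`NULL` disables).
#' @param checkpoint_dir Directory for checkpoints.
#' @param log_path Optional CSV path for the per-step loss history.
#' @param verbose Print progress every 50 steps.
#' @return A `train_config` list.
#' @export
train_config <- function(batch_size = 64L, learning_rate = 0.001, beta1 = 0.5,
                         beta2 = 0.999, disc_lr_factor = 0.1,
                         epochs = 400L, steps = NULL, seed = 0L,
                         image_size = 256L, jitter_size = NULL,
                         base_width = 64L, depth = 6L,
                         disc_base_width = NULL, disc_n_layers = 3L,
                         ghost_ratio = 2L, ablation_no_ghost = FALSE,
                         dropout_rate = 0.5,
                         loss_mode = c("combined", "bce", "mse"),
                         bce_target = c("adversarial", "pixel"),
                         weights = loss_weights(), ssim = ssim_params(),
                         checkpoint_every = NULL, checkpoint_dir = NULL,
                         log_path = NULL, verbose = FALSE) {
  loss_mode <- match.arg(loss_mode)
  bce_target <- match.arg(bce_target)
  if (batch_size < 1) stop("batch_size must be >= 1", call. = FALSE)
  if (learning_rate < 0) stop("learning_rate must be non-negative", call. = FALSE)
  if (beta1 < 0 || beta1 >= 1 || beta2 < 0 || beta2 >= 1)
    stop("beta1 and beta2 must lie in [0, 1)", call. = FALSE)
  structure(list(batch_size = as.integer(batch_size),
                 learning_rate = learning_rate, beta1 = beta1, beta2 = beta2,
                 disc_lr_factor = disc_lr_factor,
                 epochs = as.integer(epochs), steps = steps,
                 seed = as.integer(seed), image_size = as.integer(image_size),
                 jitter_size = as.integer(jitter_size %||%
                                            round(image_size * 286 / 256)),
                 base_width = as.integer(base_width), depth = as.integer(depth),
                 disc_base_width = as.integer(disc_base_width %||% base_width),
                 disc_n_layers = as.integer(disc_n_layers),
                 ghost_ratio = as.integer(ghost_ratio),
                 ablation_no_ghost = isTRUE(ablation_no_ghost),
                 dropout_rate = dropout_rate, loss_mode = loss_mode,
                 bce_target = bce_target, weights = weights, ssim = ssim,
                 checkpoint_every = checkpoint_every,
                 checkpoint_dir = checkpoint_dir, log_path = log_path,
                 verbose = isTRUE(verbose)),
            class = "train_config")
}

#' Desk-scale training profile
#'
#' A CPU-friendly configuration — 64 x 64 phantoms, batch 8, base width 16,
#' a 2-layer discriminator — used by the test suite and the worked
#' examples. Pass overrides as named arguments.
#'
#' @param ... Overrides forwarded to [train_config()].
#' @return A `train_config`.
#' @export
desk_profile <- function(...) {
  defaults <- list(image_size = 64L, batch_size = 8L, base_width = 16L,
                   disc_base_width = 16L, disc_n_layers = 2L, depth = 6L,
                   steps = 200L, epochs = 1000L)
  args <- utils::modifyList(defaults, list(...))
  do.call(train_config, args)
}

build_models <- function(cfg) {
  gspec <- generator_spec(in_channels = 1L, out_channels = 1L,
                          base_width = cfg$base_width, depth = cfg$depth,
                          image_size = cfg$image_size,
                          use_ghost_encoder = !cfg$ablation_no_ghost,
                          ghost_ratio = cfg$ghost_ratio,
                          dropout_rate = cfg$dropout_rate)
  dspec <- discriminator_spec(in_channels = 2L,
                              base_width = cfg$disc_base_width,
                              n_layers = cfg$disc_n_layers)
  list(gen = build_generator(gspec), disc = build_discriminator(dspec))
}

check_finite <- function(value, term, step) {
  if (!is.finite(value))
    stop(sprintf("non-finite %s at step %d", term, step), call. = FALSE)
  value
}

# Pixel-space BCE on [0,1]-rescaled images: loss and gradient wrt gen.
pixel_bce <- function(gen, real, eps = 1e-7) {
  p <- pmin(pmax((gen + 1) / 2, eps), 1 - eps)
  y <- (real + 1) / 2
  n <- length(p)
  loss <- -mean(y * log(p) + (1 - y) * log(1 - p))
  inner <- (gen + 1) / 2 > eps & (gen + 1) / 2 < 1 - eps
  grad <- ((p - y) / (p * (1 - p))) * inner * 0.5 / n
  list(loss = loss, grad = grad)
}

#' One adversarial training step
#'
#' Performs one discriminator update (BCE on real/fake patch logits) then
#' one generator update with the configured objective, both via Adam.
#' Models and optimizer states are returned updated (R copy semantics).
#'
#' @param batch List with `masks` and `scans`, tensors `c(H, W, 1, N)`
#'   normalized to `[-1, 1]`.
#' @param models List with `gen` and `disc`.
#' @param opts List with Adam states `gen` and `disc` (from `adam_init`;
#'   created by [train_gan()]).
#' @param cfg A [train_config()].
#' @param step Step index recorded in the returned `loss_record`.
#' @return List with `record` (a `loss_record`), `models`, `opts`.
#' @export
train_step <- function(batch, models, opts, cfg, step = 1L) {
  gen <- models$gen
  disc <- models$disc
  masks <- batch$masks
  scans <- batch$scans
  n_mask_ch <- dim(masks)[3]

  gf <- gen_forward_full(gen, masks, training = TRUE, use_dropout = TRUE)
  gen$state <- gf$state
  fake <- gf$out

  real_in <- cat_channels(masks, scans)
  fake_in <- cat_channels(masks, fake)

  # --- discriminator update ---
  dr <- disc_forward_full(disc, real_in, training = TRUE)
  disc$state <- dr$state
  df <- disc_forward_full(disc, fake_in, training = TRUE)
  disc$state <- df$state
  l_disc <- check_finite(discriminator_loss(dr$out, df$out), "l_disc", step)
  np <- length(dr$out)
  g_real <- array(0.5 * (sigmoid(dr$out) - 1) / np, dim(dr$out))
  g_fake <- array(0.5 * sigmoid(df$out) / np, dim(df$out))
  br <- disc_backward(disc, dr$cache, g_real)
  bf <- disc_backward(disc, df$cache, g_fake)
  d_grads <- br$grads
  for (nm in names(bf$grads)) d_grads[[nm]] <- d_grads[[nm]] + bf$grads[[nm]]
  upd <- adam_update(disc$params, d_grads, opts$disc,
                     cfg$learning_rate * (cfg$disc_lr_factor %||% 1),
                     cfg$beta1, cfg$beta2)
  disc$params <- upd$params
  opts$disc <- upd$opt

  # --- generator update (against the updated discriminator) ---
  w <- cfg$weights
  g_img <- array(0, dim(fake))
  if (cfg$bce_target == "adversarial") {
    df2 <- disc_forward_full(disc, fake_in, training = TRUE)
    disc$state <- df2$state
    l_bce <- check_finite(bce_logits(1, df2$out), "l_bce", step)
    if (w$w_bce > 0) {
      gz <- array(w$w_bce * (sigmoid(df2$out) - 1) / length(df2$out),
                  dim(df2$out))
      gi <- disc_backward(disc, df2$cache, gz)$gx
      g_img <- g_img + split_channels(gi, n_mask_ch)$second
    }
  } else {
    pb <- pixel_bce(fake, scans)
    l_bce <- check_finite(pb$loss, "l_bce", step)
    if (w$w_bce > 0) g_img <- g_img + w$w_bce * pb$grad
  }
  l_rec <- 0
  if (cfg$loss_mode == "combined" && w$w_ssim > 0) {
    sg <- ssim_loss_grad_batch(scans, fake, cfg$ssim)
    l_rec <- check_finite(sg$loss, "l_ssim", step)
    g_img <- g_img + w$w_ssim * sg$grad
  } else if (cfg$loss_mode == "mse" && w$w_ssim > 0) {
    l_rec <- check_finite(mse_loss(fake, scans), "l_mse", step)
    g_img <- g_img + w$w_ssim * 2 * (fake - scans) / length(fake)
  }
  gb <- gen_backward(gen, gf$cache, g_img)
  upd <- adam_update(gen$params, gb$grads, opts$gen, cfg$learning_rate,
                     cfg$beta1, cfg$beta2)
  gen$params <- upd$params
  opts$gen <- upd$opt

  rec <- loss_record(l_bce = l_bce, l_ssim = l_rec,
                     l_combined = w$w_bce * l_bce + w$w_ssim * l_rec,
                     l_disc = l_disc, step = as.integer(step))
  list(record = rec, models = list(gen = gen, disc = disc), opts = opts)
}

stack_batch <- function(pairs, idx, cfg) {
  n <- length(idx)
  s <- cfg$image_size
  masks <- array(0, c(s, s, 1L, n))
  scans <- array(0, c(s, s, 1L, n))
  for (k in seq_len(n)) {
    a <- augment_pair(pairs[[idx[k]]], s, cfg$jitter_size, random_crop = TRUE)
    masks[, , 1L, k] <- a$mask
    scans[, , 1L, k] <- a$scan
  }
  list(masks = masks, scans = scans)
}

#' Train the conditional GAN
#'
#' Alternating adversarial optimization over the train split of a
#' manifest: per step, one discriminator update then one generator update.
#' Training-time augmentation resamples the jitter-resize random crop
#' every epoch. Runs are fully determined by `cfg$seed` (single-threaded
#' CPU): identical seeds give identical loss histories.
#'
#' @param manifest A `dataset_manifest` with a non-empty train split (all
#'   entries are used if no split labels were assigned).
#' @param cfg A [train_config()].
#' @param resume_from Optional checkpoint path; training continues exactly
#'   where the checkpointed run left off.
#' @return List with `gen`, `disc`, `opts`, `history` (data.frame with
#'   columns step, l_bce, l_ssim, l_combined, l_disc), `cfg`.
#' @export
train_gan <- function(manifest, cfg, resume_from = NULL) {
  entries <- manifest$entries
  use <- if (any(entries$split != "none")) which(entries$split == "train")
         else seq_len(nrow(entries))
  if (length(use) == 0) stop("empty train split", call. = FALSE)
  pairs <- lapply(use, function(i) read_pair(manifest, i))
  n_train <- length(pairs)
  steps_per_epoch <- ceiling(n_train / cfg$batch_size)
  total_steps <- cfg$steps %||% (cfg$epochs * steps_per_epoch)

  if (is.null(resume_from)) {
    set.seed(cfg$seed)
    models <- build_models(cfg)
    opts <- list(gen = adam_init(models$gen$params),
                 disc = adam_init(models$disc$params))
    step <- 0L
    perm <- integer(0)
    pos <- 0L
    history <- list()
  } else {
    ck <- load_checkpoint(resume_from)
    expect <- build_models_specs(cfg)
    if (!identical(unclass(ck$gen$spec), unclass(expect$gen)))
      stop("checkpoint generator spec does not match the configuration",
           call. = FALSE)
    models <- list(gen = ck$gen, disc = ck$disc)
    opts <- ck$opts
    step <- ck$step
    perm <- ck$perm
    pos <- ck$pos
    history <- ck$history
    assign(".Random.seed", ck$rng, envir = globalenv())
  }

  while (step < total_steps) {
    if (pos >= length(perm)) {
      perm <- sample.int(n_train)
      pos <- 0L
    }
    idx <- perm[(pos + 1L):min(pos + cfg$batch_size, length(perm))]
    pos <- pos + length(idx)
    batch <- stack_batch(pairs, idx, cfg)
    step <- step + 1L
    out <- train_step(batch, models, opts, cfg, step)
    models <- out$models
    opts <- out$opts
    history[[length(history) + 1L]] <- out$record
    if (cfg$verbose && step %% 50L == 0L)
      message(sprintf("step %d/%d  l_combined=%.4f l_disc=%.4f", step,
                      total_steps, out$record$l_combined, out$record$l_disc))
    if (!is.null(cfg$checkpoint_every) && !is.null(cfg$checkpoint_dir) &&
        step %% cfg$checkpoint_every == 0L) {
      save_checkpoint(file.path(cfg$checkpoint_dir,
                                sprintf("ckpt_%06d.rds", step)),
                      models$gen, models$disc, opts, cfg, step, perm, pos,
                      history)
    }
  }

  hist_df <- history_to_df(history)
  if (!is.null(cfg$log_path))
    utils::write.csv(hist_df, cfg$log_path, row.names = FALSE)
  list(gen = models$gen, disc = models$disc, opts = opts, history = hist_df,
       cfg = cfg)
}

build_models_specs <- function(cfg) {
  list(gen = generator_spec(in_channels = 1L, out_channels = 1L,
                            base_width = cfg$base_width, depth = cfg$depth,
                            image_size = cfg$image_size,
                            use_ghost_encoder = !cfg$ablation_no_ghost,
                            ghost_ratio = cfg$ghost_ratio,
                            dropout_rate = cfg$dropout_rate))
}

history_to_df <- function(history) {
  do.call(rbind, lapply(history, function(r) {
    data.frame(step = r$step, l_bce = r$l_bce, l_ssim = r$l_ssim,
               l_combined = r$l_combined, l_disc = r$l_disc)
  }))
}

#' Save a training checkpoint
#'
#' Serializes models, optimizer states, the RNG state, the training
#' position and the loss history, plus a human-readable sidecar JSON
#' (`<path>.json`) recording both network specs and the seed.
#'
#' @param path Output `.rds` path.
#' @param gen,disc The two models.
#' @param opts Adam states.
#' @param cfg The [train_config()].
#' @param step Current step.
#' @param perm,pos Epoch permutation and position (for exact resumption).
#' @param history List of `loss_record`s so far.
#' @return `path`, invisibly.
#' @export
save_checkpoint <- function(path, gen, disc, opts, cfg, step,
                            perm = integer(0), pos = 0L, history = list()) {
  dir.create(dirname(path), showWarnings = FALSE, recursive = TRUE)
  saveRDS(list(gen = gen, disc = disc, opts = opts, cfg = cfg,
               step = as.integer(step), perm = perm, pos = as.integer(pos),
               history = history, rng = get(".Random.seed", envir = globalenv())),
          path)
  jsonlite::write_json(list(generator_spec = unclass(gen$spec),
                            discriminator_spec = unclass(disc$spec),
                            seed = cfg$seed, step = step),
                       paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}

#' Load a training checkpoint
#'
#' @param path Path written by [save_checkpoint()].
#' @return The checkpoint list (`gen`, `disc`, `opts`, `cfg`, `step`,
#'   `perm`, `pos`, `history`, `rng`).
#' @export
load_checkpoint <- function(path) {
  if (!file.exists(path)) stop("checkpoint not found: ", path, call. = FALSE)
  ck <- tryCatch(readRDS(path),
                 error = function(e) stop("corrupt checkpoint: ", path,
                                          call. = FALSE))
  needed <- c("gen", "disc", "opts", "step", "rng")
  if (!all(needed %in% names(ck)))
    stop("corrupt checkpoint (missing fields): ", path, call. = FALSE)
  ck
}
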