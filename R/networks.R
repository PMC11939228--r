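#' Generator specification
#'
#' The generator is a U-Net style encoder-decoder. The encoder is a stack
#' of stride-2 downsampling stages — ghost blocks when `use_ghost_encoder`
#' is `TRUE`, dense convolutions otherwise (the ablation toggle) — and the
#' decoder mirrors it with nearest-neighbour x2 upsampling, skip
#' connections concatenating the matching encoder activation, and a final
#' `tanh` so outputs live in `[-1, 1]` like the normalized inputs.
#' Dropout on the deepest decoder stages stays active at generation time
#' and plays the role of the conditional GAN's noise source.
#'
#' @param in_channels Channels of the conditioning mask.
#' @param out_channels Channels of the generated scan.
#' @param base_width Channels at the first encoder level; widths double per
#'   level, capped at `8 * base_width`.
#' @param depth Requested number of down/up levels; automatically reduced
#'   to `log2(image_size) - 2` for small images.
#' @param image_size Square input size in pixels; must be divisible by
#'   `2^depth`.
#' @param use_ghost_encoder Use ghost blocks in the encoder (`TRUE`) or
#'   dense convolutions (`FALSE`).
#' @param ghost_ratio Ghost expansion ratio `s` of the encoder blocks.
#' @param dropout_rate Dropout rate on the deepest (up to three) decoder
#'   stages.
#' @return A `generator_spec` list.
#' @export
generator_spec <- function(in_channels = 1L, out_channels = 1L,
                           base_width = 64L, depth = 6L, image_size = 256L,
                           use_ghost_encoder = TRUE, ghost_ratio = 2L,
                           dropout_rate = 0.5) {
  depth <- as.integer(min(depth, floor(log2(image_size)) - 2L))
  if (depth < 1) stop("depth must be >= 1 (image too small)", call. = FALSE)
  if (image_size %% 2^depth != 0)
    stop("image_size must be divisible by 2^depth", call. = FALSE)
  structure(list(in_channels = as.integer(in_channels),
                 out_channels = as.integer(out_channels),
                 base_width = as.integer(base_width),
                 depth = depth, image_size = as.integer(image_size),
                 use_ghost_encoder = isTRUE(use_ghost_encoder),
                 ghost_ratio = as.integer(ghost_ratio),
                 dropout_rate = dropout_rate),
            class = "generator_spec")
}

gen_widths <- function(spec) {
  pmin(spec$base_width * 2^(seq_len(spec$depth) - 1L), spec$base_width * 8L)
}

n_dropout_stages <- function(spec) min(3L, spec$depth - 1L)

# Ghost configurations of the encoder stages (also used for the dense
# variant: same in/out/kernel signature with ratio honoured or ignored).
encoder_ghost_configs <- function(spec) {
  w <- gen_widths(spec)
  ins <- c(spec$in_channels, w[-spec$depth])
  lapply(seq_len(spec$depth), function(i) {
    ghost_config(ins[i], w[i], ratio = spec$ghost_ratio, stride = 2L)
  })
}

#' Build a generator
#'
#' Parameters are drawn from `N(0, 0.02^2)` using the current RNG stream;
#' seed it (e.g. `set.seed`) for reproducible initialization.
#'
#' @param spec A [generator_spec()].
#' @return A `ghostgan_generator`: list with `spec`, flat named `params`,
#'   and batch-norm running statistics in `state`.
#' @export
build_generator <- function(spec) {
  w <- gen_widths(spec)
  d <- spec$depth
  cfgs <- encoder_ghost_configs(spec)
  params <- list()
  state <- list()
  for (i in seq_len(d)) {
    cfg <- cfgs[[i]]
    if (spec$use_ghost_encoder) {
      gp <- init_ghost_params(cfg)
      for (nm in names(gp)) params[[paste0("enc", i, ".", nm)]] <- gp[[nm]]
    } else {
      params[[paste0("enc", i, ".W")]] <- init_weight(c(3, 3, cfg$in_channels, w[i]))
    }
    if (i >= 2) {
      params[[paste0("enc", i, ".bn.gamma")]] <- rep(1, w[i])
      params[[paste0("enc", i, ".bn.beta")]] <- rep(0, w[i])
      state[[paste0("enc", i, ".bn.mean")]] <- rep(0, w[i])
      state[[paste0("enc", i, ".bn.var")]] <- rep(1, w[i])
    }
  }
  for (j in seq_len(d - 1L)) {
    cin <- w[d - j + 1L] + w[d - j]  # upsampled previous + skip
    cout <- w[d - j]
    params[[paste0("dec", j, ".W")]] <- init_weight(c(3, 3, cin, cout))
    params[[paste0("dec", j, ".bn.gamma")]] <- rep(1, cout)
    params[[paste0("dec", j, ".bn.beta")]] <- rep(0, cout)
    state[[paste0("dec", j, ".bn.mean")]] <- rep(0, cout)
    state[[paste0("dec", j, ".bn.var")]] <- rep(1, cout)
  }
  params[["final.W"]] <- init_weight(c(3, 3, w[1], spec$out_channels))
  params[["final.b"]] <- numeric(spec$out_channels)
  structure(list(spec = spec, params = params, state = state),
            class = "ghostgan_generator")
}

# Full forward pass with caches for backprop. Returns list(out, cache,
# state). `training` selects batch statistics for BN and updates the
# running averages; `use_dropout` activates decoder dropout (the noise
# source) independently of `training`.
gen_forward_full <- function(g, x, training = FALSE, use_dropout = training) {
  spec <- g$spec
  p <- g$params
  st <- g$state
  d <- spec$depth
  w <- gen_widths(spec)
  cfgs <- encoder_ghost_configs(spec)
  if (dim(x)[3] != spec$in_channels)
    stop("mask batch has wrong channel count", call. = FALSE)
  if (dim(x)[1] != spec$image_size || dim(x)[2] != spec$image_size)
    stop(sprintf("expected %dx%d input, got %dx%d", spec$image_size,
                 spec$image_size, dim(x)[1], dim(x)[2]), call. = FALSE)

  enc <- vector("list", d)
  cache <- list(enc = vector("list", d), dec = vector("list", d - 1L))
  h <- x
  for (i in seq_len(d)) {
    cc <- list(inp = h)
    if (spec$use_ghost_encoder) {
      cfg <- cfgs[[i]]
      pre <- paste0("enc", i, ".")
      gp <- list(primary.W = p[[paste0(pre, "primary.W")]],
                 cheap.W = p[[paste0(pre, "cheap.W")]])
      cc$intrinsic <- conv2d(h, gp$primary.W, stride = 2L, pad = 1L)
      z <- if (cfg$ratio == 1L) cc$intrinsic else
        cat_channels(cc$intrinsic,
                     dwconv2d(cc$intrinsic, gp$cheap.W, stride = 1L, pad = 1L))
    } else {
      z <- conv2d(h, p[[paste0("enc", i, ".W")]], stride = 2L, pad = 1L)
    }
    if (i >= 2) {
      bn <- bn_forward(z, p[[paste0("enc", i, ".bn.gamma")]],
                       p[[paste0("enc", i, ".bn.beta")]],
                       st[[paste0("enc", i, ".bn.mean")]],
                       st[[paste0("enc", i, ".bn.var")]], training)
      st[[paste0("enc", i, ".bn.mean")]] <- bn$run_mean
      st[[paste0("enc", i, ".bn.var")]] <- bn$run_var
      cc$bn <- bn$cache
      z <- bn$y
    }
    cc$pre_act <- z
    h <- lrelu(z)
    enc[[i]] <- h
    cache$enc[[i]] <- cc
  }

  n_drop <- n_dropout_stages(spec)
  for (j in seq_len(d - 1L)) {
    u <- upsample_nn2(h)
    ccin <- cat_channels(u, enc[[d - j]])
    cc <- list(ccin = ccin, n_up = dim(u)[3])
    z <- conv2d(ccin, p[[paste0("dec", j, ".W")]], stride = 1L, pad = 1L)
    bn <- bn_forward(z, p[[paste0("dec", j, ".bn.gamma")]],
                     p[[paste0("dec", j, ".bn.beta")]],
                     st[[paste0("dec", j, ".bn.mean")]],
                     st[[paste0("dec", j, ".bn.var")]], training)
    st[[paste0("dec", j, ".bn.mean")]] <- bn$run_mean
    st[[paste0("dec", j, ".bn.var")]] <- bn$run_var
    cc$bn <- bn$cache
    z <- bn$y
    if (use_dropout && j <= n_drop && spec$dropout_rate > 0) {
      dp <- dropout_forward(z, spec$dropout_rate)
      z <- dp$y
      cc$drop_mask <- dp$mask
    }
    cc$pre_act <- z
    h <- relu(z)
    cache$dec[[j]] <- cc
  }

  u <- upsample_nn2(h)
  cache$final_in <- u
  y <- tanh(conv2d(u, p[["final.W"]], p[["final.b"]], stride = 1L, pad = 1L))
  cache$out <- y
  list(out = y, cache = cache, state = st)
}

#' Generate images from a batch of masks
#'
#' @param g A `ghostgan_generator` from [build_generator()].
#' @param mask_batch Tensor `c(H, W, in_channels, N)` of masks normalized
#'   to `[-1, 1]`.
#' @param use_dropout Keep decoder dropout active (stochastic outputs);
#'   `FALSE` gives a deterministic pass.
#' @return Tensor `c(H, W, out_channels, N)` with values in `[-1, 1]`.
#' @export
generator_forward <- function(g, mask_batch, use_dropout = FALSE) {
  gen_forward_full(g, mask_batch, training = FALSE, use_dropout = use_dropout)$out
}

# Backward pass: g_out is dLoss/dOutput. Returns list(grads, gx).
gen_backward <- function(g, cache, g_out) {
  spec <- g$spec
  p <- g$params
  d <- spec$depth
  cfgs <- encoder_ghost_configs(spec)
  grads <- list()

  gz <- tanh_grad(cache$out, g_out)
  gr <- conv2d_grad(cache$final_in, p[["final.W"]], gz, stride = 1L, pad = 1L,
                    use_bias = TRUE)
  grads[["final.W"]] <- gr$gw
  grads[["final.b"]] <- gr$gb
  gh <- upsample_nn2_grad(gr$gx)

  ge <- vector("list", d)  # grads flowing into encoder activations
  for (j in rev(seq_len(d - 1L))) {
    cc <- cache$dec[[j]]
    gz <- relu_grad(cc$pre_act, gh)
    if (!is.null(cc$drop_mask)) gz <- gz * cc$drop_mask
    bnb <- bn_backward(cc$bn, gz)
    grads[[paste0("dec", j, ".bn.gamma")]] <- bnb$g_gamma
    grads[[paste0("dec", j, ".bn.beta")]] <- bnb$g_beta
    gr <- conv2d_grad(cc$ccin, p[[paste0("dec", j, ".W")]], bnb$gx,
                      stride = 1L, pad = 1L)
    grads[[paste0("dec", j, ".W")]] <- gr$gw
    parts <- split_channels(gr$gx, cc$n_up)
    skip_i <- d - j
    ge[[skip_i]] <- if (is.null(ge[[skip_i]])) parts$second else
      ge[[skip_i]] + parts$second
    gh <- upsample_nn2_grad(parts$first)
  }
  ge[[d]] <- if (is.null(ge[[d]])) gh else ge[[d]] + gh

  gx <- NULL
  for (i in rev(seq_len(d))) {
    cc <- cache$enc[[i]]
    gz <- lrelu_grad(cc$pre_act, ge[[i]])
    if (i >= 2) {
      bnb <- bn_backward(cc$bn, gz)
      grads[[paste0("enc", i, ".bn.gamma")]] <- bnb$g_gamma
      grads[[paste0("enc", i, ".bn.beta")]] <- bnb$g_beta
      gz <- bnb$gx
    }
    if (spec$use_ghost_encoder) {
      pre <- paste0("enc", i, ".")
      gp <- list(primary.W = p[[paste0(pre, "primary.W")]],
                 cheap.W = p[[paste0(pre, "cheap.W")]])
      gb <- ghost_backward(gz, cc$inp, cc$intrinsic, cfgs[[i]], gp)
      grads[[paste0(pre, "primary.W")]] <- gb$primary.W
      if (!is.null(gb$cheap.W)) grads[[paste0(pre, "cheap.W")]] <- gb$cheap.W
      gin <- gb$gx
    } else {
      gr <- conv2d_grad(cc$inp, p[[paste0("enc", i, ".W")]], gz,
                        stride = 2L, pad = 1L)
      grads[[paste0("enc", i, ".W")]] <- gr$gw
      gin <- gr$gx
    }
    if (i > 1) ge[[i - 1L]] <- if (is.null(ge[[i - 1L]])) gin else ge[[i - 1L]] + gin
    else gx <- gin
  }
  list(grads = grads, gx = gx)
}

#' Discriminator specification
#'
#' A conditional patch discriminator: the mask and the (real or generated)
#' scan are concatenated along channels, passed through `n_layers` stride-2
#' 4x4 convolution stages (widths doubling, capped at 8x), one stride-1
#' stage, and a final 1-channel stride-1 convolution emitting a grid of
#' patch logits. Sigmoid is applied only inside the loss.
#'
#' @param in_channels Mask channels + scan channels.
#' @param base_width Channels of the first stage.
#' @param n_layers Number of stride-2 stages.
#' @return A `discriminator_spec` list.
#' @export
discriminator_spec <- function(in_channels = 2L, base_width = 64L, n_layers = 3L) {
  if (n_layers < 1) stop("n_layers must be >= 1", call. = FALSE)
  structure(list(in_channels = as.integer(in_channels),
                 base_width = as.integer(base_width),
                 n_layers = as.integer(n_layers)),
            class = "discriminator_spec")
}

disc_widths <- function(spec) {
  c(pmin(spec$base_width * 2^(seq_len(spec$n_layers) - 1L), spec$base_width * 8L),
    min(spec$base_width * 2^spec$n_layers, spec$base_width * 8L))
}

#' Build a discriminator
#'
#' @param spec A [discriminator_spec()].
#' @return A `ghostgan_discriminator` with flat `params` and BN `state`.
#' @export
build_discriminator <- function(spec) {
  w <- disc_widths(spec)
  n <- spec$n_layers
  params <- list()
  state <- list()
  ins <- c(spec$in_channels, w[-length(w)])
  for (i in seq_len(n + 1L)) {
    nm <- paste0("d", i)
    params[[paste0(nm, ".W")]] <- init_weight(c(4, 4, ins[i], w[i]))
    if (i == 1L) {
      params[[paste0(nm, ".b")]] <- numeric(w[i])
    } else {
      params[[paste0(nm, ".bn.gamma")]] <- rep(1, w[i])
      params[[paste0(nm, ".bn.beta")]] <- rep(0, w[i])
      state[[paste0(nm, ".bn.mean")]] <- rep(0, w[i])
      state[[paste0(nm, ".bn.var")]] <- rep(1, w[i])
    }
  }
  params[["out.W"]] <- init_weight(c(4, 4, w[length(w)], 1))
  params[["out.b"]] <- numeric(1)
  structure(list(spec = spec, params = params, state = state),
            class = "ghostgan_discriminator")
}

disc_forward_full <- function(d, x, training = FALSE) {
  spec <- d$spec
  p <- d$params
  st <- d$state
  n <- spec$n_layers
  cache <- list(stages = vector("list", n + 1L))
  h <- x
  for (i in seq_len(n + 1L)) {
    nm <- paste0("d", i)
    stride <- if (i <= n) 2L else 1L
    cc <- list(inp = h, stride = stride)
    z <- conv2d(h, p[[paste0(nm, ".W")]],
                if (i == 1L) p[[paste0(nm, ".b")]] else NULL,
                stride = stride, pad = 1L)
    if (i > 1L) {
      bn <- bn_forward(z, p[[paste0(nm, ".bn.gamma")]], p[[paste0(nm, ".bn.beta")]],
                       st[[paste0(nm, ".bn.mean")]], st[[paste0(nm, ".bn.var")]],
                       training)
      st[[paste0(nm, ".bn.mean")]] <- bn$run_mean
      st[[paste0(nm, ".bn.var")]] <- bn$run_var
      cc$bn <- bn$cache
      z <- bn$y
    }
    cc$pre_act <- z
    h <- lrelu(z)
    cache$stages[[i]] <- cc
  }
  cache$out_in <- h
  logits <- conv2d(h, p[["out.W"]], p[["out.b"]], stride = 1L, pad = 1L)
  list(out = logits, cache = cache, state = st)
}

#' Discriminator forward pass
#'
#' @param d A `ghostgan_discriminator`.
#' @param x Tensor `c(H, W, in_channels, N)`: mask and scan concatenated
#'   along channels, normalized to `[-1, 1]`.
#' @return Patch logit tensor `c(H', W', 1, N)` (unbounded reals).
#' @export
discriminator_forward <- function(d, x) {
  disc_forward_full(d, x, training = FALSE)$out
}

# Backward; returns list(grads, gx) with gx the gradient wrt the input pair.
disc_backward <- function(d, cache, g_logits) {
  p <- d$params
  n <- d$spec$n_layers
  grads <- list()
  gr <- conv2d_grad(cache$out_in, p[["out.W"]], g_logits, stride = 1L, pad = 1L,
                    use_bias = TRUE)
  grads[["out.W"]] <- gr$gw
  grads[["out.b"]] <- gr$gb
  gh <- gr$gx
  for (i in rev(seq_len(n + 1L))) {
    nm <- paste0("d", i)
    cc <- cache$stages[[i]]
    gz <- lrelu_grad(cc$pre_act, gh)
    if (i > 1L) {
      bnb <- bn_backward(cc$bn, gz)
      grads[[paste0(nm, ".bn.gamma")]] <- bnb$g_gamma
      grads[[paste0(nm, ".bn.beta")]] <- bnb$g_beta
      gz <- bnb$gx
    }
    gr <- conv2d_grad(cc$inp, p[[paste0(nm, ".W")]], gz, stride = cc$stride,
                      pad = 1L, use_bias = (i == 1L))
    grads[[paste0(nm, ".W")]] <- gr$gw
    if (i == 1L) grads[[paste0(nm, ".b")]] <- gr$gb
    gh <- gr$gx
  }
  list(grads = grads, gx = gh)
}

#' Count learnable parameters of a model
#'
#' @param model A `ghostgan_generator` or `ghostgan_discriminator`.
#' @param pattern Optional regular expression restricting to matching
#'   parameter names (e.g. `"^enc"` for the encoder).
#' @return Total number of learnable scalars.
#' @export
count_params <- function(model, pattern = NULL) {
  p <- model$params
  if (!is.null(pattern)) p <- p[grepl(pattern, names(p))]
  sum(vapply(p, length, integer(1)))
}
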