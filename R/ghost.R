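#' Ghost block configuration
#'
#' A ghost block replaces a standard convolution by (1) a primary
#' convolution producing only `m = out_channels / ratio` "intrinsic" feature
#' maps, (2) cheap depthwise linear operations deriving `(ratio - 1)` ghost
#' maps from each intrinsic map, and (3) concatenation of intrinsic maps
#' (passed through unchanged, the identity mapping) with the ghost maps.
#' The result has `out_channels` channels at roughly `1/ratio` of the
#' parameter cost of a dense convolution.
#'
#' @param in_channels,out_channels Channel counts; `out_channels` must be
#'   divisible by `ratio`.
#' @param ratio Ghost expansion ratio `s >= 1`; `s = 1` degenerates to a
#'   standard convolution (no cheap branch).
#' @param primary_kernel,cheap_kernel Odd kernel sizes of the primary and
#'   depthwise cheap convolutions.
#' @param stride Stride of the primary convolution.
#' @param use_bias Whether the convolutions carry bias terms.
#' @return A `ghost_config` list.
#' @export
#' @examples
#' cfg <- ghost_config(16, 32, ratio = 2)
#' ghost_param_count(cfg)
#' standard_conv_param_count(16, 32, 3)
ghost_config <- function(in_channels, out_channels, ratio = 2L,
                         primary_kernel = 3L, cheap_kernel = 3L,
                         stride = 1L, use_bias = FALSE) {
  if (in_channels < 1 || out_channels < 1) stop("channel counts must be positive", call. = FALSE)
  if (ratio < 1) stop("ratio must be >= 1", call. = FALSE)
  if (out_channels %% ratio != 0)
    stop("out_channels must be divisible by ratio", call. = FALSE)
  for (k in c(primary_kernel, cheap_kernel))
    if (k < 1 || k %% 2 == 0) stop("kernels must be odd and positive", call. = FALSE)
  structure(list(in_channels = as.integer(in_channels),
                 out_channels = as.integer(out_channels),
                 ratio = as.integer(ratio),
                 primary_kernel = as.integer(primary_kernel),
                 cheap_kernel = as.integer(cheap_kernel),
                 stride = as.integer(stride),
                 use_bias = isTRUE(use_bias)),
            class = "ghost_config")
}

#' Initialize ghost-block parameters
#'
#' @param cfg A [ghost_config()].
#' @param sd Standard deviation of the Gaussian weight initialization.
#' @return Named list with `primary.W` (and `primary.b` if biased) and, for
#'   `ratio > 1`, `cheap.W` (and `cheap.b`).
#' @export
init_ghost_params <- function(cfg, sd = 0.02) {
  m <- cfg$out_channels %/% cfg$ratio
  p <- list(primary.W = init_weight(c(cfg$primary_kernel, cfg$primary_kernel,
                                      cfg$in_channels, m), sd))
  if (cfg$use_bias) p$primary.b <- numeric(m)
  if (cfg$ratio > 1) {
    p$cheap.W <- init_weight(c(cfg$cheap_kernel, cfg$cheap_kernel,
                               m, cfg$ratio - 1L), sd)
    if (cfg$use_bias) p$cheap.b <- numeric(m * (cfg$ratio - 1L))
  }
  p
}

#' Forward pass of a ghost block
#'
#' Computes the intrinsic maps with the primary convolution, derives ghost
#' maps with the depthwise cheap convolution, and concatenates
#' `[intrinsic, ghost]` (intrinsic first — the identity mapping) along the
#' channel axis. Padding is "same" (`(k - 1) / 2`).
#'
#' @param x Input tensor, dim `c(H, W, in_channels, N)`.
#' @param cfg A [ghost_config()].
#' @param params Parameters from [init_ghost_params()].
#' @return Tensor with `out_channels` channels.
#' @export
ghost_forward <- function(x, cfg, params) {
  if (dim(x)[3] != cfg$in_channels)
    stop(sprintf("input has %d channels, config expects %d",
                 dim(x)[3], cfg$in_channels), call. = FALSE)
  intrinsic <- conv2d(x, params$primary.W, params$primary.b,
                      stride = cfg$stride, pad = (cfg$primary_kernel - 1L) %/% 2L)
  if (cfg$ratio == 1L) return(intrinsic)
  ghost <- dwconv2d(intrinsic, params$cheap.W, stride = 1L,
                    pad = (cfg$cheap_kernel - 1L) %/% 2L)
  if (!is.null(params$cheap.b)) {
    d <- dim(ghost)
    ghost <- ghost + aperm(array(params$cheap.b, c(d[3], d[1], d[2], d[4])),
                           c(2L, 3L, 1L, 4L))
  }
  cat_channels(intrinsic, ghost)
}

# Backward pass; cache = list(x, intrinsic). Returns grads named as in
# init_ghost_params plus gx.
ghost_backward <- function(gy, x, intrinsic, cfg, params) {
  m <- cfg$out_channels %/% cfg$ratio
  pp <- (cfg$primary_kernel - 1L) %/% 2L
  if (cfg$ratio == 1L) {
    gr <- conv2d_grad(x, params$primary.W, gy, stride = cfg$stride, pad = pp,
                      use_bias = cfg$use_bias)
    out <- list(gx = gr$gx, primary.W = gr$gw)
    if (cfg$use_bias) out$primary.b <- gr$gb
    return(out)
  }
  parts <- split_channels(gy, m)
  g_int <- parts$first
  g_ghost <- parts$second
  cp <- (cfg$cheap_kernel - 1L) %/% 2L
  gc <- dwconv2d_grad(intrinsic, params$cheap.W, g_ghost, stride = 1L, pad = cp)
  g_int <- g_int + gc$gx
  gr <- conv2d_grad(x, params$primary.W, g_int, stride = cfg$stride, pad = pp,
                    use_bias = cfg$use_bias)
  out <- list(gx = gr$gx, primary.W = gr$gw, cheap.W = gc$gw)
  if (cfg$use_bias) {
    out$primary.b <- gr$gb
    out$cheap.b <- colSums(to_cmat(g_ghost))
  }
  out
}

#' Parameter count of a ghost block
#'
#' Closed form: with `m = out/s` intrinsic channels,
#' `m * in * k_p^2 + m * (s - 1) * k_c^2`, plus `m + m * (s - 1) = out`
#' bias terms when biased.
#'
#' @param cfg A [ghost_config()].
#' @return Integer parameter count.
#' @export
ghost_param_count <- function(cfg) {
  m <- cfg$out_channels %/% cfg$ratio
  n <- m * cfg$in_channels * cfg$primary_kernel^2 +
    m * (cfg$ratio - 1L) * cfg$cheap_kernel^2
  if (cfg$use_bias) n <- n + cfg$out_channels
  n
}

#' Parameter count of a standard convolution
#'
#' @param in_channels,out_channels Channel counts.
#' @param kernel Kernel size.
#' @param use_bias Whether a per-output-channel bias is counted.
#' @return `in * out * k^2` (+ `out` if biased).
#' @export
standard_conv_param_count <- function(in_channels, out_channels, kernel,
                                      use_bias = FALSE) {
  n <- in_channels * out_channels * kernel^2
  if (use_bias) n <- n + out_channels
  n
}

#' Parameter-cost comparison of ghost versus standard convolutions
#'
#' For each configuration, tallies the parameters of the ghost block and of
#' a dense convolution with the same `(in, out, primary_kernel)` signature,
#' and reports the compression ratio `standard / ghost`.
#'
#' @param cfgs A list of [ghost_config()] objects (or a single one).
#' @return A `cost_report`: list with `per_layer` (data.frame),
#'   `standard_params`, `ghost_params`, `compression_ratio`.
#' @export
compression_report <- function(cfgs) {
  if (inherits(cfgs, "ghost_config")) cfgs <- list(cfgs)
  if (length(cfgs) == 0) stop("need at least one configuration", call. = FALSE)
  per <- do.call(rbind, lapply(seq_along(cfgs), function(i) {
    cfg <- cfgs[[i]]
    std <- standard_conv_param_count(cfg$in_channels, cfg$out_channels,
                                     cfg$primary_kernel, cfg$use_bias)
    gh <- ghost_param_count(cfg)
    data.frame(layer = i, in_channels = cfg$in_channels,
               out_channels = cfg$out_channels, ratio = cfg$ratio,
               standard_params = std, ghost_params = gh,
               compression = std / gh)
  }))
  structure(list(per_layer = per,
                 standard_params = sum(per$standard_params),
                 ghost_params = sum(per$ghost_params),
                 compression_ratio = sum(per$standard_params) / sum(per$ghost_params)),
            class = "cost_report")
}

#' @export
print.cost_report <- function(x, ...) {
  cat("Parameter cost report\n")
  print(x$per_layer, row.names = FALSE)
  cat(sprintf("total: standard %d, ghost %d, compression %.3f\n",
              x$standard_params, x$ghost_params, x$compression_ratio))
  invisible(x)
}
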