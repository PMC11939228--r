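# Loss functions of the hybrid generator objective: adversarial binary
# cross-entropy plus a structural-similarity (SSIM) term,
#   L_combined = w_bce * L_BCE + w_ssim * (1 - SSIM).
# SSIM follows the canonical formulation: Gaussian 11x11 window
# (sigma = 1.5), K1 = 0.01, K2 = 0.03, uncentred window covariances, map
# averaged over all fully-interior window positions ("valid" filtering).

#' SSIM parameters
#'
#' @param window Odd window size in pixels (Gaussian weighted).
#' @param sigma Standard deviation of the Gaussian window.
#' @param K1,K2 Stabilization constants; `C1 = (K1 L)^2`, `C2 = (K2 L)^2`.
#' @param dynamic_range Value range `L` of the images: 2 for `[-1, 1]`
#'   tensors (the training default), 255 for 8-bit images.
#' @return An `ssim_params` list with precomputed `C1`, `C2`.
#' @export
ssim_params <- function(window = 11L, sigma = 1.5, K1 = 0.01, K2 = 0.03,
                        dynamic_range = 2) {
  if (window %% 2 == 0 || window < 3) stop("window must be odd and >= 3", call. = FALSE)
  if (K1 <= 0 || K2 <= 0 || dynamic_range <= 0)
    stop("K1, K2 and dynamic_range must be positive", call. = FALSE)
  structure(list(window = as.integer(window), sigma = sigma, K1 = K1, K2 = K2,
                 dynamic_range = dynamic_range,
                 C1 = (K1 * dynamic_range)^2, C2 = (K2 * dynamic_range)^2),
            class = "ssim_params")
}

#' Loss weights of the combined objective
#'
#' @param w_bce Weight of the adversarial BCE term.
#' @param w_ssim Weight of the SSIM term.
#' @return A `loss_weights` list.
#' @export
loss_weights <- function(w_bce = 1, w_ssim = 1) {
  if (w_bce < 0 || w_ssim < 0 || (w_bce == 0 && w_ssim == 0))
    stop("weights must be non-negative and not both zero", call. = FALSE)
  structure(list(w_bce = w_bce, w_ssim = w_ssim), class = "loss_weights")
}

#' Binary cross-entropy
#'
#' `-(1/N) * sum(y * log(p) + (1 - y) * log(1 - p))` with predictions
#' clipped to `[eps, 1 - eps]`.
#'
#' @param y_true Targets in `[0, 1]`.
#' @param y_pred Predicted probabilities.
#' @param eps Clipping constant (default `1e-7`).
#' @return Non-negative scalar.
#' @export
#' @examples
#' bce_loss(1, 0.5)  # log(2)
bce_loss <- function(y_true, y_pred, eps = 1e-7) {
  if (length(y_true) == 0) stop("empty input", call. = FALSE)
  if (length(y_true) != length(y_pred)) stop("shape mismatch", call. = FALSE)
  if (any(y_true < 0) || any(y_true > 1))
    stop("y_true must lie in [0, 1]", call. = FALSE)
  p <- pmin(pmax(y_pred, eps), 1 - eps)
  -mean(y_true * log(p) + (1 - y_true) * log(1 - p))
}

# Numerically stable BCE on logits with a constant target (0 or 1).
bce_logits <- function(target, z) {
  mean(pmax(z, 0) - z * target + log1p(exp(-abs(z))))
}

#' Mean squared error
#'
#' Comparison hook for re-running the loss-function study (adversarial BCE
#' alone, BCE + MSE, BCE + SSIM) on phantom data.
#'
#' @param x,y Equal-shape numeric arrays.
#' @return Mean of squared differences.
#' @export
mse_loss <- function(x, y) {
  if (length(x) != length(y)) stop("shape mismatch", call. = FALSE)
  mean((x - y)^2)
}

# Normalized 1D Gaussian window, radius (window-1)/2.
gauss_kernel1d <- function(window = 11L, sigma = 1.5) {
  r <- (window - 1L) %/% 2L
  g <- exp(-((-r):r)^2 / (2 * sigma^2))
  g / sum(g)
}

# Banded matrix realizing valid 1D filtering: (n - k + 1) x n.
band_mat <- function(n, g) {
  k <- length(g)
  no <- n - k + 1L
  m <- matrix(0, no, n)
  for (i in seq_len(no)) m[i, i:(i + k - 1L)] <- g
  m
}

# Local SSIM statistics on one 2D channel. Returns the SSIM map plus the
# intermediates needed for the analytic gradient.
ssim_stats <- function(x, y, p) {
  g <- gauss_kernel1d(p$window, p$sigma)
  Tr <- band_mat(nrow(x), g)
  Tc <- band_mat(ncol(x), g)
  f <- function(m) Tr %*% m %*% t(Tc)
  ux <- f(x); uy <- f(y)
  vx <- f(x * x) - ux^2
  vy <- f(y * y) - uy^2
  vxy <- f(x * y) - ux * uy
  A1 <- 2 * ux * uy + p$C1
  A2 <- 2 * vxy + p$C2
  B1 <- ux^2 + uy^2 + p$C1
  B2 <- vx + vy + p$C2
  list(S = (A1 * A2) / (B1 * B2), ux = ux, uy = uy, A1 = A1, A2 = A2,
       B1 = B1, B2 = B2, Tr = Tr, Tc = Tc)
}

ssim_channel <- function(x, y, p) mean(ssim_stats(x, y, p)$S)

#' Structural Similarity Index (SSIM)
#'
#' Mean local SSIM over a Gaussian sliding window restricted to fully
#' interior positions. Multi-channel inputs are scored as the mean of the
#' per-channel SSIM. `ssim(x, x)` is exactly 1.
#'
#' @param x,y Equal-shape matrices or `c(H, W, C)` arrays.
#' @param p An [ssim_params()]; remember to set `dynamic_range` to the
#'   actual value range of the images.
#' @return Scalar in `[-1, 1]`.
#' @export
ssim <- function(x, y, p = ssim_params()) {
  if (!all(dim(x) == dim(y))) stop("shape mismatch", call. = FALSE)
  if (any(dim(x)[1:2] < p$window))
    stop("image smaller than the SSIM window", call. = FALSE)
  if (length(dim(x)) == 2L) return(ssim_channel(x, y, p))
  mean(vapply(seq_len(dim(x)[3]),
              function(c) ssim_channel(x[, , c], y[, , c], p), numeric(1)))
}

#' SSIM loss
#'
#' `1 - ssim(x, y, p)`; 0 for identical images, at most 2.
#'
#' @inheritParams ssim
#' @return Scalar in `[0, 2]`.
#' @export
ssim_loss <- function(x, y, p = ssim_params()) 1 - ssim(x, y, p)

# Mean SSIM of one channel together with its analytic gradient wrt y.
# Every local statistic is a Gaussian-filtered function of the pixels, so
# the chain rule turns into adjoint ("scatter-back") filtering with the
# same window.
ssim_grad_channel <- function(x, y, p) {
  s <- ssim_stats(x, y, p)
  S <- s$S
  dmu <- 2 * (s$ux * s$A2) / (s$B1 * s$B2) - S * 2 * s$uy / s$B1
  dvy <- -S / s$B2
  dvxy <- 2 * s$A1 / (s$B1 * s$B2)
  adj <- function(m) t(s$Tr) %*% m %*% s$Tc
  n_pos <- length(S)
  grad <- (adj(dmu) + 2 * y * adj(dvy) - 2 * adj(dvy * s$uy) +
             x * adj(dvxy) - adj(dvxy * s$ux)) / n_pos
  list(value = mean(S), grad = grad)
}

# Batch SSIM loss and gradient wrt the generated tensor (H, W, C, N);
# loss = mean over images/channels of (1 - SSIM).
ssim_loss_grad_batch <- function(real, gen, p) {
  d <- dim(gen)
  grad <- array(0, d)
  total <- 0
  nc <- d[3] * d[4]
  for (n in seq_len(d[4])) {
    for (c in seq_len(d[3])) {
      sg <- ssim_grad_channel(real[, , c, n], gen[, , c, n], p)
      total <- total + (1 - sg$value)
      grad[, , c, n] <- -sg$grad / nc
    }
  }
  list(loss = total / nc, grad = grad)
}

#' Combined generator loss
#'
#' The adversarial term scores the discriminator's patch judgments of
#' (mask, generated) pairs against the "real" target
#' (`bce(1, sigmoid(logits))`); the perceptual term is the mean SSIM loss
#' between generated and ground-truth scans. The combined value is
#' `w_bce * l_bce + w_ssim * l_ssim`.
#'
#' @param d_fake_logits Discriminator patch logits on generated pairs.
#' @param gen_images,real_images Generated and ground-truth tensors
#'   `c(H, W, C, N)` in `[-1, 1]`.
#' @param w A [loss_weights()].
#' @param p An [ssim_params()] (dynamic range 2 for normalized tensors).
#' @param step Optional step index recorded in the result.
#' @return A `loss_record`: list with `l_bce`, `l_ssim`, `l_combined`,
#'   `l_disc` (`NA` here), `step`.
#' @export
combined_generator_loss <- function(d_fake_logits, gen_images, real_images,
                                    w = loss_weights(), p = ssim_params(),
                                    step = NA_integer_) {
  if (!all(dim(gen_images) == dim(real_images)))
    stop("generated/real shape mismatch", call. = FALSE)
  l_bce <- bce_logits(1, d_fake_logits)
  l_ssim <- if (w$w_ssim > 0) {
    d <- dim(gen_images)
    mean(vapply(seq_len(d[4]), function(n) {
      mean(vapply(seq_len(d[3]), function(c) {
        1 - ssim_channel(real_images[, , c, n], gen_images[, , c, n], p)
      }, numeric(1)))
    }, numeric(1)))
  } else 0
  loss_record(l_bce = l_bce, l_ssim = l_ssim,
              l_combined = w$w_bce * l_bce + w$w_ssim * l_ssim,
              l_disc = NA_real_, step = step)
}

loss_record <- function(l_bce, l_ssim, l_combined, l_disc, step) {
  structure(list(l_bce = l_bce, l_ssim = l_ssim, l_combined = l_combined,
                 l_disc = l_disc, step = step), class = "loss_record")
}

#' Discriminator loss
#'
#' Mean of the BCE of real-pair logits against 1 and fake-pair logits
#' against 0: `0.5 * (bce(1, sigmoid(real)) + bce(0, sigmoid(fake)))`.
#'
#' @param d_real_logits,d_fake_logits Equal-shape patch logit tensors.
#' @return Non-negative scalar (`log(2)` for uninformative zero logits).
#' @export
discriminator_loss <- function(d_real_logits, d_fake_logits) {
  if (length(d_real_logits) != length(d_fake_logits))
    stop("shape mismatch", call. = FALSE)
  0.5 * (bce_logits(1, d_real_logits) + bce_logits(0, d_fake_logits))
}
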