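#' Generate scans from a batch of masks
#'
#' Runs the generator on normalized masks with decoder dropout active (the
#' model's noise source), seeded for reproducibility: the same
#' `(weights, masks, seed)` give bit-identical images, different seeds give
#' distinct ones.
#'
#' @param gen A `ghostgan_generator`.
#' @param masks Tensor `c(H, W, in_channels, N)` in `[-1, 1]`.
#' @param seed Integer seed for the dropout noise.
#' @param out_dir Optional directory; when given, images are denormalized
#'   and written as 8-bit PNGs `gen_00001.png`, ...
#' @return Tensor `c(H, W, out_channels, N)` in `[-1, 1]`.
#' @export
generate_batch <- function(gen, masks, seed = 0L, out_dir = NULL) {
  imgs <- withr::with_seed(as.integer(seed),
                           generator_forward(gen, masks, use_dropout = TRUE))
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    for (n in seq_len(dim(imgs)[4])) {
      png::writePNG(denormalize_image(imgs[, , 1, n]) / 255,
                    file.path(out_dir, sprintf("gen_%05d.png", n)))
    }
  }
  imgs
}

#' Evaluate generated images against ground truth with SSIM
#'
#' For every pair in the chosen split, generates a scan from the mask,
#' denormalizes it to 8-bit, and computes the SSIM against the
#' ground-truth scan with dynamic range 255 (scores saved-image quality,
#' matching how generated PNGs would be compared). Reports the per-image
#' scores, their mean, and the parameter-cost report of the generator.
#'
#' @param gen A `ghostgan_generator`.
#' @param manifest A `dataset_manifest`.
#' @param split Which split to score (`"test"`, `"val"`, `"train"`, or
#'   `"all"`).
#' @param p An [ssim_params()]; default window 11 with dynamic range 255.
#' @param seed Seed for the generation noise.
#' @return An `eval_report`: list with `mean_ssim`, `per_image_ssim`,
#'   `n_images`, `cost`, `config_digest`.
#' @export
evaluate_ssim <- function(gen, manifest, split = "test",
                          p = ssim_params(dynamic_range = 255), seed = 0L) {
  idx <- if (split == "all") seq_len(nrow(manifest$entries))
         else which(manifest$entries$split == split)
  if (length(idx) == 0) stop("split '", split, "' is empty", call. = FALSE)
  s <- gen$spec$image_size
  scores <- numeric(length(idx))
  for (k in seq_along(idx)) {
    pair <- read_pair(manifest, idx[k])
    pair <- resize_pair(pair, s)
    mask <- array(normalize_image(pair$mask), c(s, s, 1L, 1L))
    img <- generate_batch(gen, mask, seed = seed + k)
    scores[k] <- ssim(denormalize_image(img[, , 1, 1]), pair$scan, p)
  }
  cost <- model_cost(gen$spec)
  structure(list(mean_ssim = mean(scores), per_image_ssim = scores,
                 n_images = length(scores), cost = cost,
                 config_digest = spec_digest(gen$spec)),
            class = "eval_report")
}

spec_digest <- function(spec) {
  paste(vapply(unclass(spec), function(v) paste(format(v), collapse = ","),
               character(1)), collapse = "|")
}

#' Serialize an evaluation report to JSON
#'
#' @param report An `eval_report` from [evaluate_ssim()].
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_eval_report <- function(report, path) {
  x <- unclass(report)
  x$cost <- list(per_layer = x$cost$per_layer,
                 standard_params = x$cost$standard_params,
                 ghost_params = x$cost$ghost_params,
                 compression_ratio = x$cost$compression_ratio,
                 total_params = x$cost$total_params,
                 param_memory_bytes = x$cost$param_memory_bytes)
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read back an evaluation report
#'
#' @param path JSON path written by [write_eval_report()].
#' @return The `eval_report` list.
#' @export
read_eval_report <- function(path) {
  x <- jsonlite::fromJSON(path)
  x$cost <- structure(x$cost, class = "cost_report")
  structure(x, class = "eval_report")
}

#' Parameter-cost accounting for a generator configuration
#'
#' Compares the ghost-encoder generator against a dense-convolution
#' encoder at identical widths, using the closed-form counts of the ghost
#' module, and estimates parameter memory at 4 bytes per float32
#' parameter. The decoder (and any discriminator) is unaffected by the
#' encoder toggle.
#'
#' @param gen_spec A [generator_spec()].
#' @param disc_spec Optional [discriminator_spec()] whose (toggle-invariant)
#'   cost is included in the totals.
#' @return A `cost_report` with encoder comparison, totals for both
#'   encoder variants, and memory estimates.
#' @export
model_cost <- function(gen_spec, disc_spec = NULL) {
  cfgs <- encoder_ghost_configs(gen_spec)
  rep <- compression_report(cfgs)
  w <- gen_widths(gen_spec)
  d <- gen_spec$depth
  decoder <- sum(vapply(seq_len(d - 1L), function(j) {
    cin <- w[d - j + 1L] + w[d - j]
    standard_conv_param_count(cin, w[d - j], 3L) + 2L * w[d - j]  # + BN
  }, numeric(1))) + standard_conv_param_count(w[1], gen_spec$out_channels, 3L,
                                              use_bias = TRUE)
  bn_enc <- sum(2L * w[-1])  # encoder BN scale/shift (stages 2..d)
  disc <- if (is.null(disc_spec)) 0 else {
    dw <- disc_widths(disc_spec)
    ins <- c(disc_spec$in_channels, dw[-length(dw)])
    sum(ins * dw * 16) + dw[1] + sum(2L * dw[-1]) +
      standard_conv_param_count(dw[length(dw)], 1L, 4L, use_bias = TRUE)
  }
  ghost_total <- rep$ghost_params + bn_enc + decoder
  standard_total <- rep$standard_params + bn_enc + decoder
  total <- if (gen_spec$use_ghost_encoder) ghost_total else standard_total
  structure(list(per_layer = rep$per_layer,
                 standard_params = rep$standard_params,
                 ghost_params = rep$ghost_params,
                 compression_ratio = rep$compression_ratio,
                 generator_params_ghost = ghost_total,
                 generator_params_standard = standard_total,
                 discriminator_params = disc,
                 total_params = total + disc,
                 param_memory_bytes = 4 * (total + disc)),
            class = "cost_report")
}
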