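# Preprocessing pipeline: resize to a jitter size, paired random crop back
# to the base size, [-1, 1] normalization, and seeded train/val/test
# splitting. Mirrors the standard conditional-translation augmentation:
# 256 -> 286 -> random 256 crop.

# Bilinear square resize of a plain matrix via EBImage.
imresize_bilinear <- function(m, size) {
  if (nrow(m) == size && ncol(m) == size) return(m)
  out <- EBImage::imageData(EBImage::resize(EBImage::Image(m), w = size, h = size,
                                            filter = "bilinear"))
  matrix(out, size, size)
}

imresize_nearest <- function(m, size) {
  if (nrow(m) == size && ncol(m) == size) return(m)
  out <- EBImage::imageData(EBImage::resize(EBImage::Image(m), w = size, h = size,
                                            filter = "none"))
  matrix(out, size, size)
}

#' Preprocessing configuration
#'
#' @param base_size Final (cropped) square size in pixels.
#' @param jitter_size Enlarged size before the random crop; must be at
#'   least `base_size`.
#' @param split_ratios Length-3 numeric summing to 1: train, val, test.
#' @param seed Integer seed driving crops and splits.
#' @return A `preprocess_config` list.
#' @export
preprocess_config <- function(base_size = 256L, jitter_size = 286L,
                              split_ratios = c(0.8, 0.1, 0.1), seed = 0L) {
  if (jitter_size < base_size) stop("jitter_size must be >= base_size", call. = FALSE)
  if (length(split_ratios) != 3 || any(split_ratios < 0) || any(split_ratios > 1) ||
      abs(sum(split_ratios) - 1) > 1e-9)
    stop("split_ratios must be three values in [0,1] summing to 1", call. = FALSE)
  structure(list(base_size = as.integer(base_size),
                 jitter_size = as.integer(jitter_size),
                 normalize_low = -1, normalize_high = 1,
                 split_ratios = split_ratios, seed = as.integer(seed)),
            class = "preprocess_config")
}

#' Resize a mask/scan pair to the jitter size
#'
#' The scan is resized with bilinear interpolation; the mask with
#' nearest-neighbour sampling and then re-thresholded at 127 so it stays
#' strictly binary. When `jitter_size` equals the current size the pair is
#' returned unchanged.
#'
#' @param pair An `image_pair` (see [make_phantom_pair()]).
#' @param jitter_size Target square size in pixels.
#' @return The resized `image_pair`.
#' @export
resize_pair <- function(pair, jitter_size) {
  if (jitter_size < 1) stop("jitter_size must be positive", call. = FALSE)
  jitter_size <- as.integer(jitter_size)
  if (nrow(pair$mask) == jitter_size && ncol(pair$mask) == jitter_size) return(pair)
  mask <- imresize_nearest(pair$mask, jitter_size)
  mask <- ifelse(mask > 127, 255, 0)
  scan <- pmin(pmax(imresize_bilinear(pair$scan, jitter_size), 0), 255)
  structure(list(mask = mask, scan = scan, id = pair$id), class = "image_pair")
}

#' Paired random crop
#'
#' Draws one offset uniformly from the admissible window and applies the
#' same crop to both mask and scan, preserving their spatial
#' correspondence. Coordinates are 0-based, row-major, origin top-left.
#'
#' @param pair An `image_pair`, at least `base_size` in both dimensions.
#' @param base_size Crop size in pixels.
#' @param offset Optional fixed `c(row, col)` 0-based offset; when `NULL`
#'   (default) the offset is drawn from the current RNG stream.
#' @return The cropped `image_pair` with an `offset` attribute.
#' @export
paired_random_crop <- function(pair, base_size, offset = NULL) {
  H <- nrow(pair$mask)
  W <- ncol(pair$mask)
  if (H < base_size || W < base_size)
    stop("pair smaller than base_size", call. = FALSE)
  max_r <- H - base_size
  max_c <- W - base_size
  if (is.null(offset)) {
    offset <- c(if (max_r > 0) sample.int(max_r + 1L, 1L) - 1L else 0L,
                if (max_c > 0) sample.int(max_c + 1L, 1L) - 1L else 0L)
  }
  if (any(offset < 0) || offset[1] > max_r || offset[2] > max_c)
    stop("offset outside admissible window", call. = FALSE)
  rows <- offset[1] + seq_len(base_size)
  cols <- offset[2] + seq_len(base_size)
  out <- structure(list(mask = pair$mask[rows, cols],
                        scan = pair$scan[rows, cols], id = pair$id),
                   class = "image_pair")
  attr(out, "offset") <- as.integer(offset)
  out
}

#' Normalize an 8-bit image to [-1, 1]
#'
#' Affine map `x -> x / 127.5 - 1`, so 0 maps to -1 and 255 to +1.
#'
#' @param image Numeric matrix/array with values in `[0, 255]`.
#' @return Numeric array of the same shape in `[-1, 1]`.
#' @export
normalize_image <- function(image) {
  if (any(image < 0) || any(image > 255))
    stop("pixel values must lie in [0, 255]", call. = FALSE)
  image / 127.5 - 1
}

#' Map a [-1, 1] image back to 8-bit integers
#'
#' Inverse of [normalize_image()]: `x -> round_half_up((x + 1) * 127.5)`,
#' clipped to `[0, 255]`. Values outside `[-1, 1]` by more than `tol` are an
#' error; smaller overshoots are clipped.
#'
#' @param image Numeric matrix/array with values in `[-1, 1]`.
#' @param tol Tolerance for out-of-range values (default `1e-3`).
#' @return Integer-valued array in `[0, 255]`.
#' @export
denormalize_image <- function(image, tol = 1e-3) {
  if (any(image < -1 - tol) || any(image > 1 + tol))
    stop("values outside [-1, 1] beyond tolerance", call. = FALSE)
  x <- pmin(pmax(image, -1), 1)
  pmin(pmax(floor((x + 1) * 127.5 + 0.5), 0), 255)
}

#' Assign train/val/test splits to a manifest
#'
#' Entries are shuffled by a seeded permutation; the first
#' `floor(r_train * n)` go to train, the next `floor(r_val * n)` to val,
#' and the remainder to test. The partition is disjoint and exhaustive and
#' is a pure function of `(manifest, ratios, seed)`.
#'
#' @param manifest A `dataset_manifest`.
#' @param ratios Length-3 numeric summing to 1 (train, val, test).
#' @param seed Integer seed for the permutation.
#' @return The manifest with `split` labels and updated counts.
#' @export
split_dataset <- function(manifest, ratios = c(0.8, 0.1, 0.1), seed = 0L) {
  n <- nrow(manifest$entries)
  if (n < 1) stop("manifest is empty", call. = FALSE)
  if (length(ratios) != 3 || abs(sum(ratios) - 1) > 1e-9)
    stop("ratios must sum to 1", call. = FALSE)
  counts <- split_counts(n, ratios)
  perm <- withr::with_seed(as.integer(seed), sample.int(n))
  labels <- rep(c("train", "val", "test"), times = counts)
  entries <- manifest$entries
  entries$split[perm] <- labels
  out <- new_manifest(entries, manifest$seed, manifest$dir)
  if (!is.null(manifest$dir) && dir.exists(manifest$dir %||% ""))
    write_manifest(out, file.path(manifest$dir, "manifest.jsonl"))
  out
}

# Floor/remainder allocation: train and val floored, test absorbs the rest.
split_counts <- function(n, ratios) {
  n_train <- floor(ratios[1] * n)
  n_val <- floor(ratios[2] * n)
  c(train = n_train, val = n_val, test = n - n_train - n_val)
}

# Full training-time augmentation for one pair: jitter-resize, paired
# random crop, normalization. Used by the training loop.
augment_pair <- function(pair, base_size, jitter_size, random_crop = TRUE) {
  pair <- resize_pair(pair, jitter_size)
  pair <- paired_random_crop(pair, base_size,
                             offset = if (random_crop) NULL else c(0L, 0L))
  list(mask = normalize_image(pair$mask), scan = normalize_image(pair$scan))
}
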