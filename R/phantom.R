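#' Specification for synthetic tumor phantoms
#'
#' A phantom is a paired (mask, scan) image: the mask is a binary union of
#' random ellipses standing in for tumor outlines, and the scan is a smooth
#' background with the masked region raised to `tumor_intensity`, plus
#' Gaussian pixel noise. Phantoms structurally emulate paired 2D brain-tumor
#' segmentation data (grayscale scan + binary mask at a fixed square size)
#' so that the whole conditional-GAN pipeline can be exercised without any
#' external dataset.
#'
#' @param image_size Pixels per side (square images). Must be >= 16.
#' @param tumor_count_range Integer interval `c(lo, hi)` for the number of
#'   ellipses per phantom.
#' @param tumor_radius_range Interval in pixels for ellipse semi-axes.
#' @param tumor_intensity Scan intensity inside the mask, in `[0, 255]`.
#' @param background_model `"concentric_gradient"` (radially decaying
#'   intensity from the image centre) or `"smooth_noise"` (low-frequency
#'   random field).
#' @param noise_sigma Standard deviation of additive Gaussian pixel noise,
#'   in 8-bit intensity units.
#' @param seed Integer seed; together with the pair index it fully
#'   determines each phantom.
#' @return A `phantom_spec` list.
#' @export
#' @examples
#' spec <- phantom_spec(image_size = 64, seed = 1)
#' pair <- make_phantom_pair(spec, 1)
#' range(pair$mask)
phantom_spec <- function(image_size = 256L,
                         tumor_count_range = c(1L, 2L),
                         tumor_radius_range = c(8, 40),
                         tumor_intensity = 220,
                         background_model = c("concentric_gradient", "smooth_noise"),
                         noise_sigma = 8,
                         seed = 0L) {
  background_model <- match.arg(background_model)
  if (image_size < 16) stop("image_size must be at least 16", call. = FALSE)
  if (any(tumor_count_range < 0) || tumor_count_range[2] < tumor_count_range[1])
    stop("tumor_count_range must be a non-negative increasing interval", call. = FALSE)
  if (any(tumor_radius_range <= 0) || any(tumor_radius_range > image_size / 2))
    stop("tumor_radius_range must be positive and at most image_size/2", call. = FALSE)
  if (noise_sigma < 0) stop("noise_sigma must be non-negative", call. = FALSE)
  if (tumor_intensity < 0 || tumor_intensity > 255)
    stop("tumor_intensity must lie in [0, 255]", call. = FALSE)
  structure(list(image_size = as.integer(image_size),
                 tumor_count_range = as.integer(tumor_count_range),
                 tumor_radius_range = tumor_radius_range,
                 tumor_intensity = tumor_intensity,
                 background_model = background_model,
                 noise_sigma = noise_sigma,
                 seed = as.integer(seed)),
            class = "phantom_spec")
}

phantom_background <- function(spec) {
  n <- spec$image_size
  if (spec$background_model == "concentric_gradient") {
    ctr <- (n + 1) / 2
    r <- sqrt(outer((seq_len(n) - ctr)^2, (seq_len(n) - ctr)^2, "+"))
    # 120 at the centre fading to 40 at the corner
    120 - 80 * r / max(r)
  } else {
    # low-frequency field: coarse Gaussian grid, bilinear upsampling
    coarse <- matrix(stats::rnorm(64), 8, 8)
    up <- imresize_bilinear(coarse, n)
    lo <- min(up); hi <- max(up)
    if (hi > lo) up <- (up - lo) / (hi - lo)
    40 + 80 * up
  }
}

#' Generate one paired (mask, scan) phantom
#'
#' A pure function of `(spec$seed, index)`: the per-pair random stream is
#' seeded with `spec$seed + index`, so pairs are independent of generation
#' order and bit-reproducible.
#'
#' @param spec A [phantom_spec()].
#' @param index Non-negative integer pair index.
#' @return An `image_pair`: list with `mask` (integer matrix, values 0/255),
#'   `scan` (integer matrix in `[0, 255]`) and `id`.
#' @export
make_phantom_pair <- function(spec, index) {
  if (!inherits(spec, "phantom_spec")) stop("spec must be a phantom_spec", call. = FALSE)
  if (index < 0) stop("index must be non-negative", call. = FALSE)
  withr::with_seed(spec$seed + as.integer(index), {
    n <- spec$image_size
    mask <- matrix(0, n, n)
    k <- if (spec$tumor_count_range[1] == spec$tumor_count_range[2]) {
      spec$tumor_count_range[1]
    } else {
      sample(spec$tumor_count_range[1]:spec$tumor_count_range[2], 1L)
    }
    rr <- spec$tumor_radius_range
    if (k > 0) {
      xs <- matrix(seq_len(n), n, n)
      ys <- t(xs)
      for (i in seq_len(k)) {
        cx <- stats::runif(1, 0.25 * n, 0.75 * n)
        cy <- stats::runif(1, 0.25 * n, 0.75 * n)
        a <- stats::runif(1, rr[1], rr[2])
        b <- stats::runif(1, rr[1], rr[2])
        th <- stats::runif(1, 0, pi)
        dx <- xs - cx
        dy <- ys - cy
        u <- dx * cos(th) + dy * sin(th)
        v <- -dx * sin(th) + dy * cos(th)
        mask[(u / a)^2 + (v / b)^2 <= 1] <- 255
      }
    }
    bg <- phantom_background(spec)
    scan <- bg
    scan[mask > 0] <- spec$tumor_intensity
    if (spec$noise_sigma > 0) {
      scan <- scan + matrix(stats::rnorm(n * n, sd = spec$noise_sigma), n, n)
    }
    scan <- pmin(pmax(round(scan), 0), 255)
    structure(list(mask = mask, scan = scan,
                   id = sprintf("phantom_%05d", as.integer(index))),
              class = "image_pair")
  })
}

#' Generate a paired phantom dataset on disk
#'
#' Writes `n` mask/scan pairs as 8-bit grayscale PNGs plus a JSON-lines
#' manifest (`manifest.jsonl`). The first manifest line is a metadata record
#' with the seed and counts; each following line describes one pair
#' (`id`, `mask`, `scan`, `split`). Entries are ordered by index and all
#' pairs start unsplit (`split = "none"`); use [split_dataset()] to assign
#' train/val/test labels.
#'
#' @param n Number of pairs (>= 1).
#' @param spec A [phantom_spec()].
#' @param out_dir Output directory, created if missing.
#' @return A `dataset_manifest`: list with `entries` (data.frame), `seed`,
#'   `counts`, `dir`.
#' @export
make_phantom_dataset <- function(n, spec, out_dir) {
  if (n < 1) stop("n must be at least 1", call. = FALSE)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  entries <- data.frame(id = character(n), mask = character(n),
                        scan = character(n), split = rep("none", n),
                        stringsAsFactors = FALSE)
  for (i in seq_len(n)) {
    pair <- make_phantom_pair(spec, i - 1L)
    mask_file <- sprintf("%s_mask.png", pair$id)
    scan_file <- sprintf("%s_scan.png", pair$id)
    png::writePNG(pair$mask / 255, file.path(out_dir, mask_file))
    png::writePNG(pair$scan / 255, file.path(out_dir, scan_file))
    entries[i, ] <- list(pair$id, mask_file, scan_file, "none")
  }
  manifest <- new_manifest(entries, spec$seed, out_dir)
  write_manifest(manifest, file.path(out_dir, "manifest.jsonl"))
  manifest
}

new_manifest <- function(entries, seed, dir) {
  if (anyDuplicated(entries$mask) || anyDuplicated(entries$scan))
    stop("manifest paths must be unique", call. = FALSE)
  counts <- table(factor(entries$split, levels = c("train", "val", "test", "none")))
  structure(list(entries = entries, seed = as.integer(seed),
                 counts = as.list(counts), dir = dir),
            class = "dataset_manifest")
}

#' Write a dataset manifest as JSON lines
#'
#' @param manifest A `dataset_manifest`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_manifest <- function(manifest, path) {
  meta <- jsonlite::toJSON(list(type = "meta", seed = manifest$seed,
                                n = nrow(manifest$entries)), auto_unbox = TRUE)
  lines <- vapply(seq_len(nrow(manifest$entries)), function(i) {
    e <- manifest$entries[i, ]
    as.character(jsonlite::toJSON(list(id = e$id, mask = e$mask, scan = e$scan,
                                       split = e$split), auto_unbox = TRUE))
  }, character(1))
  writeLines(c(as.character(meta), lines), path)
  invisible(path)
}

#' Read a JSON-lines dataset manifest
#'
#' @param path Path to a `manifest.jsonl` written by [write_manifest()].
#' @return A `dataset_manifest`.
#' @export
read_manifest <- function(path) {
  if (!file.exists(path)) stop("manifest not found: ", path, call. = FALSE)
  lines <- readLines(path)
  meta <- jsonlite::fromJSON(lines[1])
  rows <- lapply(lines[-1], jsonlite::fromJSON)
  entries <- do.call(rbind, lapply(rows, function(r) {
    data.frame(id = r$id, mask = r$mask, scan = r$scan, split = r$split,
               stringsAsFactors = FALSE)
  }))
  new_manifest(entries, meta$seed, dirname(path))
}

# Load one pair of a manifest from disk as 8-bit matrices.
read_pair <- function(manifest, i) {
  e <- manifest$entries[i, ]
  mask <- round(png::readPNG(file.path(manifest$dir, e$mask)) * 255)
  scan <- round(png::readPNG(file.path(manifest$dir, e$scan)) * 255)
  if (length(dim(mask)) == 3L) mask <- mask[, , 1]
  if (length(dim(scan)) == 3L) scan <- scan[, , 1]
  structure(list(mask = mask, scan = scan, id = e$id), class = "image_pair")
}
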