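# Shared fixtures: tiny phantom datasets and CPU-cheap training profiles.

tiny_phantom_spec <- function(size = 32L, seed = 7L, ...) {
  phantom_spec(image_size = size, tumor_radius_range = c(3, 8), seed = seed, ...)
}

tiny_phantom_manifest <- function(n = 8L, size = 32L, seed = 7L,
                                  dir = tempfile("ph")) {
  make_phantom_dataset(n, tiny_phantom_spec(size = size, seed = seed), dir)
}

# 32 px, narrow nets: a training step costs a fraction of a second.
tiny_train_cfg <- function(...) {
  args <- utils::modifyList(list(image_size = 32L, base_width = 8L,
                                 disc_base_width = 8L, batch_size = 4L,
                                 disc_n_layers = 2L), list(...))
  do.call(desk_profile, args)
}

# Independent SSIM oracle: scikit-image's structural_similarity via the
# command-line python of the environment (Gaussian weights, sigma 1.5,
# population covariances — the canonical formulation this package follows).
# Pairs are written row-stacked to CSV and scored in one python call.
skimage_ssim_batch <- function(xs, ys, data_range = 1) {
  dir <- tempfile("ssim_oracle")
  dir.create(dir)
  utils::write.table(do.call(rbind, xs), file.path(dir, "x.csv"),
                     row.names = FALSE, col.names = FALSE, sep = ",")
  utils::write.table(do.call(rbind, ys), file.path(dir, "y.csv"),
                     row.names = FALSE, col.names = FALSE, sep = ",")
  script <- paste0(
    "import numpy as np\n",
    "from skimage.metrics import structural_similarity as s\n",
    sprintf("x = np.loadtxt(r'%s', delimiter=',')\n", file.path(dir, "x.csv")),
    sprintf("y = np.loadtxt(r'%s', delimiter=',')\n", file.path(dir, "y.csv")),
    sprintf("k = %d\n", length(xs)),
    "h = x.shape[0] // k\n",
    "for i in range(k):\n",
    sprintf(paste0("    print(s(x[i*h:(i+1)*h], y[i*h:(i+1)*h], ",
                   "gaussian_weights=True, sigma=1.5, ",
                   "use_sample_covariance=False, data_range=%.17g))\n"),
            data_range))
  py <- file.path(dir, "oracle.py")
  writeLines(script, py)
  as.numeric(system2("python", py, stdout = TRUE))
}

skimage_ssim <- function(x, y, data_range = 1) {
  skimage_ssim_batch(list(x), list(y), data_range)
}
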