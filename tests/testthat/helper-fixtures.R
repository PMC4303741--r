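# Shared fixtures, built once per session and cached.

.fixtures <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fixtures)) {
    assign(key, force(expr), envir = .fixtures)
  }
  get(key, envir = .fixtures)
}

# fast registration preset for module tests and the pipeline fixtures
fast_reg <- function() reg_config(levels = 2, budget = 100, max_samples = 2000)

# high-precision preset for pose-recovery checks
precision_reg <- function() reg_config(max_samples = 24000)

# a small phantom grid with the same physical extent as the default
# (32 x 32 x 24 voxels at 6 mm), for cheap pipeline-level tests
small_spec <- function(seed = 1L, ...) {
  phantom_spec(grid_shape = c(32, 32, 24), spacing = c(6, 6, 6),
               seed = seed, ...)
}

default_atlases <- function() {
  cached("atlases_default", generate_atlas_set(phantom_spec(seed = 1), n = 6,
                                               seed = 4242L))
}

small_atlases <- function() {
  cached("atlases_small", generate_atlas_set(small_spec(seed = 1), n = 6,
                                             seed = 4242L))
}

# noise- and bias-free spec: intensities equal class means exactly
clean_spec <- function(seed = 1L, ...) {
  phantom_spec(class_noise_sd = 0,
               bias_field = list(amplitude = 0,
                                 coef = c(x = 0, y = 0, z = 0,
                                          x2 = 0, y2 = 0, z2 = 0)),
               seed = seed, ...)
}

# crop the top `drop` slices off a volume (and its geometry)
crop_top <- function(vol, drop) {
  d <- dim(vol$data)
  out <- vol
  out$data <- vol$data[, , seq_len(d[3] - drop), drop = FALSE]
  out
}

# exhaustive 1-D kNN oracle with the package's neighbour semantics:
# all samples within the k-th smallest distance, majority vote, ties by
# smaller mean neighbour distance, then lowest class index
brute_knn_1d <- function(train, cls, k, q) {
  out <- integer(length(q))
  for (i in seq_along(q)) {
    dd <- abs(train - q[i])
    kth <- sort(dd, partial = k)[k]
    nb <- dd <= kth
    counts <- vapply(1:3, function(c) sum(nb & cls == c), numeric(1))
    top <- which(counts == max(counts))
    if (length(top) > 1) {
      md <- vapply(top, function(c) mean(dd[nb & cls == c]), numeric(1))
      top <- top[md <= min(md) + 1e-12]
    }
    out[i] <- top[1]
  }
  out
}

# write one phantom examination as a DICOM directory; returns the dir
write_exam <- function(ph, dir) {
  write_dicom_series(ph$image, ph$header, file.path(dir, "series1"))
  dir
}
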