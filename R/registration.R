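#' Registration configuration
#'
#' Hyperparameters of the mutual-information registration engine. The
#' defaults (32 histogram bins, 3 resolution levels, 200 optimizer
#' iterations per level) are tuned for desk-scale head volumes at around
#' 3 mm resolution.
#'
#' @param levels Number of resolution levels; level `l` downsamples by
#'   `2^(levels - l)` (block mean).
#' @param bins Joint-histogram bins (>= 2).
#' @param budget Nelder-Mead iterations per level.
#' @param max_samples Cap on the number of (deterministically strided)
#'   fixed-image samples entering the metric at each level.
#' @param estimate_scale Include per-axis log-scale parameters in the
#'   affine model (rotation + translation only when `FALSE`).
#' @param cap_mm Displacement cap for non-rigid control points, mm.
#' @param grid_spacing_mm Non-rigid control-point spacing, mm.
#' @param nonrigid_steps Coordinate-descent step sizes (mm), one sweep per
#'   step.
#' @param nonrigid_min_gain Minimum MI improvement (nats) for a control
#'   point move to be accepted; filters the noise-level fluctuations of
#'   the sampled metric so identical images yield an exactly zero field.
#' @param seed Integer seed (the engine itself is deterministic; the seed
#'   is recorded for provenance and future samplers).
#' @return A list of class `reg_config`.
#' @export
reg_config <- function(levels = 3, bins = 32, budget = 200,
                       max_samples = 6000, estimate_scale = TRUE,
                       cap_mm = 10, grid_spacing_mm = 48,
                       nonrigid_steps = c(3, 1.5), nonrigid_min_gain = 0.005,
                       seed = 42L) {
  assert_that(bins >= 2, "bins must be >= 2")
  structure(list(levels = levels, bins = bins, budget = budget,
                 max_samples = max_samples, estimate_scale = estimate_scale,
                 cap_mm = cap_mm, grid_spacing_mm = grid_spacing_mm,
                 nonrigid_steps = nonrigid_steps,
                 nonrigid_min_gain = nonrigid_min_gain,
                 seed = as.integer(seed)),
            class = "reg_config")
}

#' Affine transform in physical (LPS) coordinates
#'
#' Maps a fixed-space point `x` to moving space as
#' `matrix %*% (x - center) + center + translation`; this is the
#' resampling convention, so applying the transform pulls moving-image
#' intensities onto the fixed grid.
#'
#' @param matrix 3x3 invertible matrix.
#' @param translation Length-3 translation, mm.
#' @param center Length-3 rotation center, mm.
#' @return An object of class `affine_transform`.
#' @export
affine_transform <- function(matrix = diag(3), translation = c(0, 0, 0),
                             center = c(0, 0, 0)) {
  matrix <- as.matrix(matrix)
  assert_that(all(dim(matrix) == c(3, 3)) && abs(det(matrix)) > 1e-12,
              "matrix must be 3x3 and invertible")
  structure(list(matrix = matrix, translation = as.numeric(translation),
                 center = as.numeric(center)),
            class = "affine_transform")
}

#' @export
print.affine_transform <- function(x, ...) {
  cat("<affine_transform>\n")
  print(round(x$matrix, 5))
  cat("translation:", paste(round(x$translation, 3), collapse = ", "),
      " center:", paste(round(x$center, 3), collapse = ", "), "\n")
  invisible(x)
}

# Apply an affine transform to physical points (n x 3).
affine_points <- function(tf, xyz) {
  sweep(sweep(xyz, 2, tf$center) %*% t(tf$matrix), 2,
        tf$center + tf$translation, "+")
}

#' Invert an affine transform
#' @param tf An [affine_transform()].
#' @return The inverse [affine_transform()].
#' @export
invert_affine <- function(tf) {
  Minv <- solve(tf$matrix)
  affine_transform(Minv, -as.numeric(Minv %*% tf$translation), tf$center)
}

# --- mutual information ---------------------------------------------------

bin_index <- function(v, lo, hi, bins) {
  if (hi <= lo) return(rep(1L, length(v)))
  i <- floor((v - lo) / (hi - lo) * bins) + 1
  pmin.int(pmax.int(as.integer(i), 1L), bins)
}

# MI (nats) from two paired sample vectors with fixed bin ranges.
mi_samples <- function(fa, fb, bins, range_a = range(fa), range_b = range(fb)) {
  ia <- bin_index(fa, range_a[1], range_a[2], bins)
  ib <- bin_index(fb, range_b[1], range_b[2], bins)
  joint <- tabulate(ia + bins * (ib - 1L), bins * bins) / length(ia)
  pj <- joint[joint > 0]
  pa <- rowSums(matrix(joint, bins, bins)); pa <- pa[pa > 0]
  pb <- colSums(matrix(joint, bins, bins)); pb <- pb[pb > 0]
  -sum(pa * log(pa)) - sum(pb * log(pb)) + sum(pj * log(pj))
}

entropy_samples <- function(fa, bins, range_a = range(fa)) {
  ia <- bin_index(fa, range_a[1], range_a[2], bins)
  p <- tabulate(ia, bins) / length(ia)
  p <- p[p > 0]
  -sum(p * log(p))
}

#' Mutual information between two volumes
#'
#' Histogram-based MI, `H(a) + H(b) - H(a, b)` in nats, computed from the
#' joint intensity histogram over the shared grid. `mi(x, x)` equals the
#' marginal entropy of `x` exactly, and MI is symmetric and non-negative.
#'
#' @param a,b [image_volume()] objects on the same grid.
#' @param bins Number of histogram bins per axis (>= 2).
#' @return MI in nats.
#' @export
mutual_information <- function(a, b, bins = 32) {
  assert_that(bins >= 2, "bins must be >= 2")
  assert_that(all(dim(a$data) == dim(b$data)),
              "volumes must share a grid (resample one first); empty overlap")
  mi_samples(as.numeric(a$data), as.numeric(b$data), bins)
}

#' Shannon entropy of a volume's intensity histogram
#' @inheritParams mutual_information
#' @param x An [image_volume()].
#' @return Entropy in nats.
#' @export
volume_entropy <- function(x, bins = 32) {
  entropy_samples(as.numeric(x$data), bins)
}

# --- resolution pyramid ---------------------------------------------------

# Block-mean downsampling by integer factor, with matching geometry.
downsample_volume <- function(vol, factor) {
  if (factor <= 1) return(vol)
  d <- dim(vol$data)
  d2 <- pmax(d %/% factor, 1)
  a <- vol$data[seq_len(d2[1] * factor), seq_len(d2[2] * factor),
                seq_len(d2[3] * factor), drop = FALSE]
  dim(a) <- c(factor, d2[1], factor, d2[2], factor, d2[3])
  a <- aperm(a, c(1, 3, 5, 2, 4, 6))
  dim(a) <- c(factor^3, prod(d2))
  out <- array(colMeans(a), dim = d2)
  new_origin <- as.numeric(vox_to_phys(vol, matrix(rep((factor - 1) / 2, 3), 1)))
  image_volume(out, vol$spacing * factor, new_origin, vol$direction)
}

# Strided sample of fixed-image positions: physical coords + values.
# Positions are jittered off-grid by up to half a voxel (deterministic,
# seeded) and the fixed values interpolated there, so that an on-grid
# solution has no interpolation advantage over off-grid candidates — the
# usual grid-alignment local maximum of histogram MI.
sample_fixed <- function(vol, max_samples, jitter_seed = 42L) {
  n <- length(vol$data)
  stride <- max(1L, ceiling(n / max_samples))
  idx <- seq(1L, n, by = stride)
  ijk <- voxel_grid(vol)[idx, , drop = FALSE]
  d <- dim(vol$data)
  off <- withr::with_seed(jitter_seed,
                          matrix(stats::runif(length(idx) * 3, -0.5, 0.5),
                                 ncol = 3))
  v <- ijk + off
  v <- pmin(pmax(v, 0), matrix(d - 1, nrow(v), 3, byrow = TRUE))
  list(xyz = vox_to_phys(vol, v),
       values = interp_trilinear(vol$data, v))
}

# MI of moving resampled at mapped points vs fixed samples; points mapping
# outside the moving domain are dropped from both marginals. The fixed
# values are pre-binned once per level (fx$bin); the moving intensities
# enter the joint histogram with soft linear binning (each value split
# between its two nearest bins), so the metric is a smooth function of
# the transform parameters rather than jumping at bin crossings.
mi_mapped <- function(moving, fx, mapped_xyz, bins, range_m) {
  v <- phys_to_vox(moving, mapped_xyz)
  d <- dim(moving$data)
  inside <- v[, 1] >= 0 & v[, 1] <= d[1] - 1 &
            v[, 2] >= 0 & v[, 2] <= d[2] - 1 &
            v[, 3] >= 0 & v[, 3] <= d[3] - 1
  if (sum(inside) < 32) return(-Inf)
  mv <- interp_trilinear_inside(moving$data, v[inside, , drop = FALSE])
  ia <- fx$bin[inside]
  # fractional bin coordinate: bin centres at 1..bins
  cc <- (mv - range_m[1]) / max(range_m[2] - range_m[1], .Machine$double.eps) *
    bins + 0.5
  k0 <- pmin.int(pmax.int(as.integer(floor(cc)), 1L), bins)
  k1 <- pmin.int(k0 + 1L, bins)
  w1 <- pmin(pmax(cc - k0, 0), 1)
  key <- c(ia + bins * (k0 - 1L), ia + bins * (k1 - 1L))
  w <- c(1 - w1, w1)
  acc <- rowsum(w, key)
  joint <- numeric(bins * bins)
  joint[as.integer(rownames(acc))] <- acc
  joint <- joint / length(ia)
  pj <- joint[joint > 0]
  pa <- rowSums(matrix(joint, bins, bins)); pa <- pa[pa > 0]
  pb <- colSums(matrix(joint, bins, bins)); pb <- pb[pb > 0]
  mi <- -sum(pa * log(pa)) - sum(pb * log(pb)) + sum(pj * log(pj))
  attr(mi, "n_inside") <- sum(inside)
  mi
}

# attach pre-binned fixed values
prebin_fixed <- function(fx, bins) {
  fx$bin <- bin_index(fx$values, min(fx$values), max(fx$values), bins)
  fx
}

params_to_affine <- function(par, center, estimate_scale) {
  R <- rotation_matrix(par[1:3])
  S <- if (estimate_scale) diag(exp(par[7:9])) else diag(3)
  affine_transform(R %*% S, par[4:6], center)
}

center_of_mass <- function(vol) {
  w <- as.numeric(vol$data)
  w <- pmax(w - min(w), 0)
  if (sum(w) == 0) return(grid_center(vol))
  xyz <- vox_to_phys(vol, voxel_grid(vol))
  colSums(xyz * w) / sum(w)
}

#' Affine registration by mutual-information maximization
#'
#' Multi-resolution Nelder-Mead search over rotations, translations and
#' (optionally) per-axis log scales, maximizing the histogram MI between
#' the fixed image and the transformed moving image. Initialization is
#' identity rotation with a center-of-mass translation. The returned
#' transform maps fixed-space points into moving space (resampling
#' convention), and its final MI is never below the MI of the
#' initialization: if the search fails to improve, the initial transform
#' is returned with `improved = FALSE`.
#'
#' @param moving,fixed [image_volume()] objects.
#' @param config A [reg_config()].
#' @return A list of class `affine_registration`: `transform`
#'   ([affine_transform()]), `mi_initial`, `mi_final`, `improved`.
#' @export
affine_register <- function(moving, fixed, config = reg_config()) {
  factors <- 2^((config$levels:1) - 1)
  center <- grid_center(fixed)
  t0 <- center_of_mass(moving) - center_of_mass(fixed)
  npar <- if (config$estimate_scale) 9 else 6
  par <- c(0, 0, 0, t0, rep(0, npar - 6))
  range_m <- range(moving$data)
  level_mi <- function(mov_l, fx, par) {
    tf <- params_to_affine(par, center, config$estimate_scale)
    mi_mapped(mov_l, fx, affine_points(tf, fx$xyz), config$bins, range_m)
  }
  for (f in factors) {
    mov_l <- downsample_volume(moving, f)
    fix_l <- downsample_volume(fixed, f)
    fx <- prebin_fixed(sample_fixed(fix_l, config$max_samples, config$seed),
                       config$bins)
    # optimize in scaled offset space, starting each level at zero offset:
    # Nelder-Mead sizes its initial simplex from the starting point, so a
    # zero start gives every parameter the same initial step (~3 degrees,
    # ~2 mm, ~2% log-scale). After convergence the search is restarted
    # once from the optimum with a fresh full-size simplex, which escapes
    # the shallow local plateaus of the sampled histogram metric.
    coarse <- c(rep(30, 3), rep(20, 3), rep(0.2, npar - 6))[seq_len(npar)]
    fine <- c(rep(4, 3), rep(2.5, 3), rep(0.03, npar - 6))[seq_len(npar)]
    polish <- c(rep(1, 3), rep(0.6, 3), rep(0.008, npar - 6))[seq_len(npar)]
    finest <- f == factors[length(factors)]
    # the finest level does the precision work: double budget + a final
    # small-simplex polish round
    maxit <- if (finest) 2 * config$budget else config$budget
    rounds <- if (finest) list(coarse, fine, polish) else list(coarse, fine)
    for (parscale in rounds) {
      obj <- function(dp) {
        mi <- level_mi(mov_l, fx, par + dp * parscale)
        if (is.nan(mi)) stop("registration diverged: non-finite objective")
        if (!is.finite(mi)) return(1e6)  # empty overlap: steer away
        -mi
      }
      opt <- stats::optim(rep(0, npar), obj, method = "Nelder-Mead",
                          control = list(maxit = maxit, reltol = 1e-9))
      par <- par + opt$par * parscale
    }
  }
  fx_full <- prebin_fixed(sample_fixed(fixed, config$max_samples, config$seed),
                          config$bins)
  mi_init <- level_mi(moving, fx_full, c(0, 0, 0, t0, rep(0, npar - 6)))
  mi_final <- level_mi(moving, fx_full, par)
  if (!is.finite(mi_final)) stop("registration diverged: non-finite final MI")
  if (mi_final >= mi_init) {
    tf <- params_to_affine(par, center, config$estimate_scale)
    improved <- TRUE
  } else {
    tf <- params_to_affine(c(0, 0, 0, t0, rep(0, npar - 6)), center,
                           config$estimate_scale)
    mi_final <- mi_init
    improved <- FALSE
  }
  structure(list(transform = tf, mi_initial = mi_init, mi_final = mi_final,
                 improved = improved),
            class = "affine_registration")
}

# --- non-rigid refinement -------------------------------------------------

#' Coarse control-grid deformation field
#'
#' A lattice of control-point displacements (mm) over the fixed-image
#' domain, interpolated trilinearly between knots and composed with an
#' affine pre-alignment: a fixed-space point `x` maps to
#' `affine(x) + d(x)`.
#'
#' @keywords internal
deformation_field <- function(affine, knot_origin, knot_spacing, dims,
                              direction = diag(3), disp = NULL, cap = 10) {
  if (is.null(disp)) disp <- array(0, dim = c(dims, 3))
  structure(list(affine = affine, knot_origin = knot_origin,
                 knot_spacing = knot_spacing, dims = dims,
                 direction = direction, disp = disp, cap = cap),
            class = "deformation_field")
}

# displacement at physical points (n x 3); knots live on the fixed-image
# axes, so points are first rotated into that frame
field_displacement <- function(df, xyz) {
  u <- sweep(sweep(xyz, 2, df$knot_origin) %*% df$direction, 2,
             df$knot_spacing, "/")
  u <- pmin(pmax(u, 0), matrix(df$dims - 1, nrow(u), 3, byrow = TRUE))
  cbind(interp_trilinear(array(df$disp[, , , 1], df$dims), u),
        interp_trilinear(array(df$disp[, , , 2], df$dims), u),
        interp_trilinear(array(df$disp[, , , 3], df$dims), u))
}

deform_points <- function(df, xyz) {
  affine_points(df$affine, xyz) + field_displacement(df, xyz)
}

#' Non-rigid registration refining an affine pre-alignment
#'
#' Greedy coordinate descent on a coarse control-point lattice: each sweep
#' tries, for every control point and axis, a displacement step in both
#' directions and keeps it when the mutual information improves.
#' Displacement magnitudes are capped at `config$cap_mm`. The search runs
#' on a downsampled grid, matching the coarse scale of the lattice. With
#' `moving == fixed` no step improves MI, so the field stays exactly zero.
#'
#' @param moving,fixed [image_volume()] objects.
#' @param init [affine_transform()] pre-alignment (from
#'   [affine_register()]).
#' @param config A [reg_config()].
#' @return A list of class `nonrigid_registration`: `field`
#'   (`deformation_field`), `mi_initial` (affine-only MI), `mi_final`.
#' @export
nonrigid_register <- function(moving, fixed, init, config = reg_config()) {
  assert_that(inherits(init, "affine_transform"),
              "init must be an affine_transform (run affine_register first)")
  f <- 2^(max(config$levels - 2, 0))
  fix_l <- downsample_volume(fixed, f)
  fx <- prebin_fixed(sample_fixed(fix_l, config$max_samples, config$seed),
                     config$bins)
  range_m <- range(moving$data)

  d <- dim(fixed$data)
  extent <- (d - 1) * fixed$spacing
  dims <- pmax(2L, as.integer(ceiling(extent / config$grid_spacing_mm)) + 1L)
  knot_spacing <- extent / (dims - 1)
  corner <- as.numeric(vox_to_phys(fixed, matrix(0, 1, 3)))
  df <- deformation_field(init, corner, knot_spacing, dims,
                          direction = fixed$direction, cap = config$cap_mm)
  # knot-lattice coordinates of the metric samples (fixed voxel frame)
  vox_xyz <- phys_to_vox(fixed, fx$xyz)
  knot_u <- sweep(sweep(vox_xyz, 2, fixed$spacing, "*"), 2, knot_spacing, "/")
  knot_u <- pmin(pmax(knot_u, 0), matrix(dims - 1, nrow(knot_u), 3, byrow = TRUE))

  eval_mi <- function(disp) {
    dx <- cbind(interp_trilinear(array(disp[, , , 1], dims), knot_u),
                interp_trilinear(array(disp[, , , 2], dims), knot_u),
                interp_trilinear(array(disp[, , , 3], dims), knot_u))
    mi_mapped(moving, fx, affine_points(init, fx$xyz) + dx, config$bins,
              range_m)
  }

  mi_initial <- eval_mi(df$disp)
  best <- as.numeric(mi_initial)
  # a move must not shrink the metric overlap: MI can spuriously rise as
  # samples are pushed outside the moving domain
  n_floor <- attr(mi_initial, "n_inside")
  # control points whose support holds no foreground sample stay at zero:
  # in pure background the metric only fluctuates with noise and corner
  # knots would otherwise drift
  fg_thr <- min(fx$values) + 0.1 * diff(range(fx$values))
  active <- array(FALSE, dim = dims)
  for (ci in seq_len(dims[1])) for (cj in seq_len(dims[2]))
    for (ck in seq_len(dims[3])) {
      supp <- abs(knot_u[, 1] - (ci - 1)) < 1 &
              abs(knot_u[, 2] - (cj - 1)) < 1 &
              abs(knot_u[, 3] - (ck - 1)) < 1
      active[ci, cj, ck] <- any(fx$values[supp] > fg_thr)
    }
  disp <- df$disp
  # metric fluctuations grow as samples shrink; scale the acceptance
  # threshold accordingly (reference sampling: 6000 positions)
  eps <- config$nonrigid_min_gain * max(1, sqrt(6000 / length(fx$values)))
  for (step in config$nonrigid_steps) {
    for (ci in seq_len(dims[1])) for (cj in seq_len(dims[2]))
      for (ck in seq_len(dims[3])) for (ax in 1:3) {
        if (!active[ci, cj, ck]) next
        cur <- disp[ci, cj, ck, ax]
        for (delta in c(step, -step)) {
          cand <- cur + delta
          newvec <- disp[ci, cj, ck, ]; newvec[ax] <- cand
          if (sqrt(sum(newvec^2)) > config$cap_mm) next
          disp[ci, cj, ck, ax] <- cand
          mi <- eval_mi(disp)
          if (as.numeric(mi) > best + eps &&
              attr(mi, "n_inside") >= n_floor) {
            best <- as.numeric(mi); cur <- cand
          } else {
            disp[ci, cj, ck, ax] <- cur
          }
        }
      }
  }
  df$disp <- disp
  structure(list(field = df, mi_initial = mi_initial, mi_final = best),
            class = "nonrigid_registration")
}

#' Resample a volume through a transform
#'
#' Pulls `volume` onto the `target` grid through an [affine_transform()] or
#' a `deformation_field`: each target voxel's physical position is mapped
#' into the source volume and interpolated. Intensity images use linear
#' interpolation; label volumes and binary masks must use
#' nearest-neighbour (linear interpolation of labels is rejected), so
#' resampled labels only ever take input label values. Voxels mapping
#' outside the source domain get `fill` (default 0 / background).
#'
#' @param volume Source [image_volume()] or [label_volume()].
#' @param transform [affine_transform()] or `deformation_field` mapping
#'   target space to source space.
#' @param target [image_volume()] (or compatible) supplying the output
#'   grid.
#' @param interpolation `"linear"` or `"nearest"`.
#' @param fill Fill value outside the source domain.
#' @return Volume of the same class as `volume` on the target grid.
#' @export
apply_transform <- function(volume, transform, target,
                            interpolation = c("linear", "nearest"),
                            fill = 0) {
  interpolation <- match.arg(interpolation)
  is_labels <- inherits(volume, "label_volume")
  if (is_labels && interpolation == "linear") {
    stop("label volumes must be resampled with nearest-neighbour interpolation",
         call. = FALSE)
  }
  xyz <- vox_to_phys(target, voxel_grid(target))
  src_xyz <- if (inherits(transform, "deformation_field")) {
    deform_points(transform, xyz)
  } else if (inherits(transform, "affine_transform")) {
    affine_points(transform, xyz)
  } else stop("transform must be an affine_transform or deformation_field")
  v <- phys_to_vox(volume, src_xyz)
  vals <- if (interpolation == "linear") {
    interp_trilinear(volume$data, v, fill = fill)
  } else {
    interp_nearest(volume$data, v, fill = fill)
  }
  out <- array(vals, dim = dim(target$data))
  if (is_labels) {
    label_volume(out, target$spacing, target$origin, target$direction)
  } else {
    image_volume(out, target$spacing, target$origin, target$direction)
  }
}

#' Serialize / restore transforms as plain text (YAML)
#' @param transform [affine_transform()] or `deformation_field`.
#' @param path File path.
#' @return `path`; `read_transform()` returns the transform.
#' @export
write_transform <- function(transform, path) {
  if (inherits(transform, "affine_transform")) {
    obj <- list(type = "affine", matrix = as.numeric(transform$matrix),
                translation = transform$translation, center = transform$center)
  } else {
    obj <- list(type = "deformation", affine = list(
      matrix = as.numeric(transform$affine$matrix),
      translation = transform$affine$translation,
      center = transform$affine$center),
      knot_origin = transform$knot_origin,
      knot_spacing = transform$knot_spacing,
      dims = transform$dims, direction = as.numeric(transform$direction),
      disp = as.numeric(transform$disp), cap = transform$cap)
  }
  yaml::write_yaml(obj, path, precision = 15)
  invisible(path)
}

#' @rdname write_transform
#' @export
read_transform <- function(path) {
  obj <- yaml::read_yaml(path)
  if (obj$type == "affine") {
    affine_transform(matrix(obj$matrix, 3, 3), obj$translation, obj$center)
  } else {
    af <- affine_transform(matrix(obj$affine$matrix, 3, 3),
                           obj$affine$translation, obj$affine$center)
    deformation_field(af, obj$knot_origin, obj$knot_spacing,
                      as.integer(obj$dims),
                      direction = matrix(obj$direction, 3, 3),
                      disp = array(obj$disp, dim = c(obj$dims, 3)),
                      cap = obj$cap)
  }
}
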