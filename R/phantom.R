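#' Synthetic head phantom specification
#'
#' Describes a schematic head built from nested ellipsoids — white matter
#' inside grey matter inside CSF inside skull, with a face lobe attached
#' anteriorly — so every tissue volume has an analytic ground truth.
#' Together with per-tissue mean intensities, Gaussian noise, a smooth
#' multiplicative bias field, an affine pose perturbation and a full
#' acquisition/identity header profile, this is everything needed to
#' emulate one heterogeneous clinical MR examination.
#'
#' The defaults define the reference test conditions of the package:
#' a 64 x 64 x 48 grid at 3 mm isotropic spacing, tissue noise SD equal to
#' 5% of the smallest between-tissue mean separation, and a quadratic bias
#' field of +/-10% amplitude.
#'
#' @param grid_shape 3 positive integers, voxels.
#' @param spacing 3 positive reals, mm.
#' @param tissue_geometry Named list of ellipsoid semi-axes (mm):
#'   `skull`, `csf`, `gm`, `wm` (each length 3, strictly nested), and
#'   `face = list(center =, semi =)` for the anterior face lobe.
#' @param class_means Named per-tissue mean intensities (arbitrary units)
#'   for `background`, `face`, `skull`, `csf`, `gm`, `wm`.
#' @param class_noise_sd Per-tissue Gaussian noise SD; a single number is
#'   recycled. The default is 5% of the minimum CSF/GM/WM mean separation.
#' @param bias_field List `(amplitude, coef)`: the multiplicative field is
#'   `1 + amplitude * q(x)` with `q` a quadratic in normalized coordinates
#'   scaled to `[-1, 1]` over the grid.
#' @param pose List `(rotation, translation, scale)`: rotation in degrees
#'   about the three axes, translation in mm, isotropic or per-axis scale.
#' @param header_profile A [header_record()] (identity part ignored here),
#'   or NULL for a 3T gradient-echo T1w profile.
#' @param identity_profile Named list merged into the header identity.
#' @param seed Integer random seed; identical spec + seed reproduces the
#'   phantom bit-for-bit.
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(grid_shape = c(64, 64, 48),
                         spacing = c(3, 3, 3),
                         tissue_geometry = default_tissue_geometry(),
                         class_means = c(background = 5, face = 55, skull = 20,
                                         csf = 30, gm = 65, wm = 100),
                         class_noise_sd = NULL,
                         bias_field = list(amplitude = 0.10,
                                           coef = c(x = 0.6, y = 0.3, z = 0.4,
                                                    x2 = 1, y2 = -0.7, z2 = 0.5)),
                         pose = list(rotation = c(0, 0, 0),
                                     translation = c(0, 0, 0),
                                     scale = c(1, 1, 1)),
                         header_profile = NULL,
                         identity_profile = list(),
                         seed = 1L) {
  assert_that(length(grid_shape) == 3 && all(grid_shape >= 2),
              "grid_shape must be 3 integers >= 2")
  assert_that(length(spacing) == 3 && all(spacing > 0), "spacing must be > 0")
  if (is.null(class_noise_sd)) {
    sep <- min(diff(sort(class_means[c("csf", "gm", "wm")])))
    class_noise_sd <- 0.05 * sep
  }
  if (length(class_noise_sd) == 1) {
    class_noise_sd <- stats::setNames(rep(class_noise_sd, length(class_means)),
                                      names(class_means))
  }
  assert_that(all(class_noise_sd >= 0), "class_noise_sd must be >= 0")
  if (length(pose$scale) == 1) pose$scale <- rep(pose$scale, 3)
  if (is.null(header_profile)) {
    header_profile <- header_record(
      scanning_sequence = "GR", repetition_time = 7.9, echo_time = 3.1,
      inversion_time = 450, flip_angle = 12,
      pixel_spacing = spacing[1:2], slice_thickness = spacing[3],
      matrix_size = grid_shape[1:2], n_slices = grid_shape[3],
      field_strength = 3, manufacturer = "GE MEDICAL SYSTEMS",
      model = "Discovery MR750", series_number = 2L,
      series_description = "T1 3D",
      private_tags = list(list(group = 0x0019, element = 0x1010,
                               payload = "VENDOR NOTE Doe^Jane H0000001")))
  }
  id_defaults <- list(patient_name = "Doe^Jane", patient_id = "H0000001",
                      birth_date = "19560315", study_date = "20100607",
                      sex = "F", accession = "ACC0000001",
                      institution = "Example University Hospital",
                      referring_physician = "Ref^Doctor",
                      operators = "Tech^One")
  identity_profile <- utils::modifyList(id_defaults, identity_profile)
  spec <- structure(list(grid_shape = as.integer(grid_shape),
                         spacing = as.numeric(spacing),
                         tissue_geometry = tissue_geometry,
                         class_means = class_means,
                         class_noise_sd = class_noise_sd,
                         bias_field = bias_field,
                         pose = pose,
                         header_profile = header_profile,
                         identity_profile = identity_profile,
                         seed = as.integer(seed)),
                    class = "phantom_spec")
  validate_geometry(spec)
  spec
}

#' @rdname phantom_spec
#' @export
default_tissue_geometry <- function() {
  # inner shells are offset posteriorly/superiorly: real heads are not
  # rotationally symmetric, and the offsets give intensity-based
  # registration an unambiguous rotation signal
  list(skull = c(62, 72, 54),
       csf = c(55, 64, 47), csf_center = c(0, 1, 1),
       gm = c(49, 58, 41), gm_center = c(0, 3, 3),
       wm = c(38, 46, 30), wm_center = c(0, 6, 6),
       face = list(center = c(0, -72, -12), semi = c(26, 16, 24)))
}

# numeric containment check: every sampled point of the inner ellipsoid
# surface must lie inside the outer ellipsoid
contained_in <- function(inner_c, inner_s, outer_c, outer_s, n = 400) {
  pts <- withr::with_seed(1L, {
    u <- matrix(stats::rnorm(3 * n), ncol = 3)
    u / sqrt(rowSums(u^2))
  })
  surf <- sweep(sweep(pts, 2, inner_s, "*"), 2, inner_c, "+")
  all(inside_ellipsoid(surf, outer_c, outer_s))
}

validate_geometry <- function(spec) {
  g <- spec$tissue_geometry
  cc <- g$csf_center %||% c(0, 0, 0)
  gc <- g$gm_center %||% c(0, 0, 0)
  wc <- g$wm_center %||% c(0, 0, 0)
  nested <- contained_in(wc, g$wm, gc, g$gm) &&
    contained_in(gc, g$gm, cc, g$csf) &&
    contained_in(cc, g$csf, c(0, 0, 0), g$skull)
  assert_that(nested,
              "tissue ellipsoids cannot be nested: each shell must contain the next (skull > csf > gm > wm)")
  invisible(spec)
}

# Rotation matrix from degrees about x, y, z (applied z %*% y %*% x).
rotation_matrix <- function(deg) {
  r <- deg * pi / 180
  cx <- cos(r[1]); sx <- sin(r[1])
  cy <- cos(r[2]); sy <- sin(r[2])
  cz <- cos(r[3]); sz <- sin(r[3])
  Rx <- matrix(c(1, 0, 0, 0, cx, sx, 0, -sx, cx), 3)
  Ry <- matrix(c(cy, 0, -sy, 0, 1, 0, sy, 0, cy), 3)
  Rz <- matrix(c(cz, sz, 0, -sz, cz, 0, 0, 0, 1), 3)
  Rz %*% Ry %*% Rx
}

inside_ellipsoid <- function(u, center, semi) {
  ((u[, 1] - center[1]) / semi[1])^2 +
    ((u[, 2] - center[2]) / semi[2])^2 +
    ((u[, 3] - center[3]) / semi[3])^2 <= 1
}

# Inverse-posed voxel-centre coordinates: membership of the canonical
# ellipsoids is tested here, so ground truth is exact under any pose.
posed_coords <- function(spec) {
  vol0 <- phantom_geometry(spec)
  xyz <- vox_to_phys(vol0, voxel_grid(vol0))  # centred grid, head at origin
  R <- rotation_matrix(spec$pose$rotation)
  A <- R %*% diag(spec$pose$scale)
  sweep(xyz, 2, spec$pose$translation) %*% t(solve(A))
}

# Full 6-class map in {0 bg, 4 face, 5 skull, 1 CSF, 2 GM, 3 WM}.
phantom_class_map <- function(spec) {
  u <- posed_coords(spec)
  g <- spec$tissue_geometry
  cls <- integer(nrow(u))
  in_skull <- inside_ellipsoid(u, c(0, 0, 0), g$skull)
  cls[inside_ellipsoid(u, g$face$center, g$face$semi) & !in_skull] <- 4L
  cls[in_skull] <- 5L
  cls[inside_ellipsoid(u, g$csf_center %||% c(0, 0, 0), g$csf)] <- 1L
  cls[inside_ellipsoid(u, g$gm_center %||% c(0, 0, 0), g$gm)] <- 2L
  cls[inside_ellipsoid(u, g$wm_center %||% c(0, 0, 0), g$wm)] <- 3L
  array(cls, dim = spec$grid_shape)
}

# Face-exclusion region for the defacing atlas mask: the face ellipsoid
# dilated by a safety margin (defacing masks are generous — a tight mask
# leaves boundary voxels behind under voxelization and registration
# error), guarded on the inside by the ellipsoid midway through the skull
# shell so the excluded region stays well clear of CSF and brain.
face_exclusion_region <- function(spec, margin = 6) {
  u <- posed_coords(spec)
  g <- spec$tissue_geometry
  guard <- (g$skull + g$csf) / 2
  excl <- inside_ellipsoid(u, g$face$center, g$face$semi + margin) &
    !inside_ellipsoid(u, c(0, 0, 0), guard)
  array(excl, dim = spec$grid_shape)
}

# Empty volume with the spec geometry, grid centred on the origin.
phantom_geometry <- function(spec) {
  origin <- -(spec$grid_shape - 1) / 2 * spec$spacing
  image_volume(array(0, dim = spec$grid_shape), spec$spacing, origin)
}

# Multiplicative bias field over the grid, normalized to peak |q| = 1.
phantom_bias_field <- function(spec) {
  vol0 <- phantom_geometry(spec)
  xyz <- vox_to_phys(vol0, voxel_grid(vol0))
  half <- (spec$grid_shape - 1) / 2 * spec$spacing
  nx <- xyz[, 1] / half[1]; ny <- xyz[, 2] / half[2]; nz <- xyz[, 3] / half[3]
  cf <- spec$bias_field$coef
  q <- cf["x"] * nx + cf["y"] * ny + cf["z"] * nz +
    cf["x2"] * nx^2 + cf["y2"] * ny^2 + cf["z2"] * nz^2
  if (max(abs(q)) > 0) q <- q / max(abs(q))
  array(1 + spec$bias_field$amplitude * q, dim = spec$grid_shape)
}

#' Generate a synthetic head phantom
#'
#' Builds the posed ground-truth tissue partition, draws per-tissue
#' Gaussian intensities, and applies the multiplicative bias field. All
#' randomness flows through `spec$seed`: the same spec reproduces the same
#' arrays bit-for-bit.
#'
#' @param spec A [phantom_spec()].
#' @return A list:
#' \describe{
#'   \item{image}{[image_volume()] of intensities.}
#'   \item{labels}{[label_volume()] ground-truth CSF/GM/WM partition
#'     (face and skull map to background).}
#'   \item{header}{[header_record()] carrying the acquisition and identity
#'     profiles.}
#'   \item{class_map}{integer array over \{0 bg, 1 CSF, 2 GM, 3 WM,
#'     4 face, 5 skull\} — the full ground truth.}
#'   \item{bias}{the multiplicative bias field array.}
#' }
#' @export
generate_phantom <- function(spec) {
  cls <- phantom_class_map(spec)
  means <- spec$class_means[c("background", "csf", "gm", "wm", "face", "skull")]
  sds <- spec$class_noise_sd[c("background", "csf", "gm", "wm", "face", "skull")]
  vol0 <- phantom_geometry(spec)
  intensity <- withr::with_seed(spec$seed, {
    mu <- means[cls + 1L]
    if (all(sds == 0)) mu else mu + stats::rnorm(length(cls), 0, sds[cls + 1L])
  })
  bias <- phantom_bias_field(spec)
  data <- array(pmax(as.numeric(intensity), 0) * as.numeric(bias),
                dim = spec$grid_shape)
  labels <- cls
  labels[labels > 3L] <- 0L
  header <- spec$header_profile
  header$identity <- utils::modifyList(header$identity, spec$identity_profile)
  header$pixel_spacing <- spec$spacing[1:2]
  header$slice_thickness <- spec$spacing[3]
  header$spacing_between_slices <- spec$spacing[3]
  header$matrix_size <- spec$grid_shape[1:2]
  header$n_slices <- spec$grid_shape[3]
  list(image = image_volume(data, spec$spacing, vol0$origin),
       labels = label_volume(labels, spec$spacing, vol0$origin),
       header = header,
       class_map = cls,
       bias = bias)
}

#' Analytic ground-truth tissue volumes of a phantom spec, in ml
#'
#' Exact ellipsoid-shell volumes `4/3 pi abc`, scaled by the pose's scale
#' factors (rotations and translations preserve volume).
#'
#' @param spec A [phantom_spec()].
#' @return Named numeric: `csf_ml`, `gm_ml`, `wm_ml`, `brain_ml`, `icv_ml`.
#' @export
phantom_true_volumes <- function(spec) {
  g <- spec$tissue_geometry
  ell <- function(semi) 4 / 3 * pi * prod(semi)
  s <- prod(spec$pose$scale)
  wm <- ell(g$wm) * s
  gm <- ell(g$gm) * s - wm
  csf <- ell(g$csf) * s - wm - gm
  c(csf_ml = csf / 1000, gm_ml = gm / 1000, wm_ml = wm / 1000,
    brain_ml = (gm + wm) / 1000, icv_ml = (csf + gm + wm) / 1000)
}

#' Generate a jittered atlas set
#'
#' Emulates the expert-annotated reference atlases of an atlas-based
#' segmentation method: `n` phantoms with independent pose and intensity
#' jitter, each carrying its intensity image, CSF/GM/WM label partition,
#' and masks derived from the ground truth — intracranial
#' (CSF + GM + WM), cerebrum (GM + WM), and the face-exclusion mask
#' (1 = keep, 0 = face region).
#'
#' @param spec Base [phantom_spec()].
#' @param n Number of atlases (default 6).
#' @param jitter List of half-ranges: `rotation` (deg), `translation` (mm),
#'   `scale` (fraction), `intensity` (fraction of class means). `NULL`
#'   disables jitter.
#' @param seed Integer seed driving all jitter draws.
#' @return An object of class `atlas_set`: `list(atlases, count)` where
#'   each atlas is `list(intensity, labels, intracranial, cerebrum,
#'   face_keep)`.
#' @export
generate_atlas_set <- function(spec, n = 6,
                               jitter = list(rotation = 5, translation = 4,
                                             scale = 0.03, intensity = 0.03),
                               seed = spec$seed + 1000L) {
  assert_that(n >= 1, "n must be >= 1")
  if (is.null(jitter)) jitter <- list(rotation = 0, translation = 0,
                                      scale = 0, intensity = 0)
  draws <- withr::with_seed(seed, {
    lapply(seq_len(n), function(i) list(
      rotation = stats::runif(3, -1, 1) * jitter$rotation,
      translation = stats::runif(3, -1, 1) * jitter$translation,
      scale = 1 + stats::runif(3, -1, 1) * jitter$scale,
      gain = 1 + stats::runif(1, -1, 1) * jitter$intensity))
  })
  atlases <- lapply(seq_len(n), function(i) {
    sp <- spec
    sp$pose <- draws[[i]][c("rotation", "translation", "scale")]
    sp$class_means <- spec$class_means * draws[[i]]$gain
    sp$seed <- derive_seed(seed, i)
    ph <- generate_phantom(sp)
    geom <- ph$labels[c("spacing", "origin", "direction")]
    mk <- function(mask) {
      v <- image_volume(array(as.numeric(mask), dim = dim(ph$labels$data)),
                        geom$spacing, geom$origin, geom$direction)
      v
    }
    list(intensity = ph$image,
         labels = ph$labels,
         intracranial = mk(ph$labels$data > 0L),
         cerebrum = mk(ph$labels$data >= 2L),
         face_keep = mk(!face_exclusion_region(sp)))
  })
  structure(list(atlases = atlases, count = n), class = "atlas_set")
}

#' @export
print.atlas_set <- function(x, ...) {
  cat(sprintf("<atlas_set> %d atlases, grid %s\n", x$count,
              paste(dim(x$atlases[[1]]$intensity$data), collapse = "x")))
  invisible(x)
}

#' Save / load an atlas set as NIfTI files
#'
#' One subdirectory per atlas holding `intensity.nii.gz`, `labels.nii.gz`
#' and the three masks, plus a `meta.json` with the count.
#'
#' @param atlases An `atlas_set`.
#' @param dir Directory.
#' @return `dir` (write) or an `atlas_set` (read).
#' @export
write_atlas_set <- function(atlases, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (i in seq_len(atlases$count)) {
    ad <- file.path(dir, sprintf("atlas_%02d", i))
    dir.create(ad, showWarnings = FALSE)
    a <- atlases$atlases[[i]]
    write_volume(a$intensity, file.path(ad, "intensity.nii.gz"))
    write_volume(a$labels, file.path(ad, "labels.nii.gz"))
    write_volume(a$intracranial, file.path(ad, "intracranial.nii.gz"))
    write_volume(a$cerebrum, file.path(ad, "cerebrum.nii.gz"))
    write_volume(a$face_keep, file.path(ad, "face_keep.nii.gz"))
  }
  jsonlite::write_json(list(count = atlases$count), file.path(dir, "meta.json"),
                       auto_unbox = TRUE)
  invisible(dir)
}

#' @rdname write_atlas_set
#' @export
read_atlas_set <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "meta.json"))
  atlases <- lapply(seq_len(meta$count), function(i) {
    ad <- file.path(dir, sprintf("atlas_%02d", i))
    list(intensity = read_volume(file.path(ad, "intensity.nii.gz")),
         labels = read_volume(file.path(ad, "labels.nii.gz"), labels = TRUE),
         intracranial = read_volume(file.path(ad, "intracranial.nii.gz")),
         cerebrum = read_volume(file.path(ad, "cerebrum.nii.gz")),
         face_keep = read_volume(file.path(ad, "face_keep.nii.gz")))
  })
  structure(list(atlases = atlases, count = meta$count), class = "atlas_set")
}
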