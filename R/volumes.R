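#' Oriented 3D image volume
#'
#' The basic image container of the package: a 3D scalar array with voxel
#' spacing (mm), origin (mm) and an orthonormal direction matrix, all in the
#' DICOM patient coordinate system (LPS). Voxel indices are 0-based and a
#' voxel's coordinates refer to its center. The physical position of voxel
#' `(i, j, k)` is `origin + direction %*% (c(i, j, k) * spacing)`.
#'
#' @param data 3D numeric array. The first index runs along the image
#'   column direction (fastest varying in a DICOM pixel stream), the second
#'   along rows, the third across slices.
#' @param spacing Numeric length 3, voxel spacing in mm (> 0).
#' @param origin Numeric length 3, physical position of voxel (0,0,0) in mm.
#' @param direction 3x3 orthonormal matrix of axis direction cosines.
#' @return An object of class `image_volume`.
#' @export
image_volume <- function(data, spacing, origin = c(0, 0, 0), direction = diag(3)) {
  assert_that(is.array(data) && length(dim(data)) == 3, "data must be a 3D array")
  spacing <- as.numeric(spacing)
  assert_that(length(spacing) == 3 && all(spacing > 0), "spacing must be 3 positive reals")
  origin <- as.numeric(origin)
  assert_that(length(origin) == 3, "origin must be length 3")
  direction <- as.matrix(direction)
  assert_that(all(dim(direction) == c(3, 3)), "direction must be 3x3")
  assert_that(abs(abs(det(direction)) - 1) < 1e-6 &&
                max(abs(crossprod(direction) - diag(3))) < 1e-6,
              "direction must be orthonormal (|det| = 1)")
  structure(list(data = data, spacing = spacing, origin = origin,
                 direction = direction),
            class = "image_volume")
}

#' Tissue label volume
#'
#' An [image_volume()] whose voxels carry integer tissue labels:
#' background = 0, CSF = 1, GM = 2, WM = 3.
#'
#' @inheritParams image_volume
#' @return An object of class `c("label_volume", "image_volume")`.
#' @export
label_volume <- function(data, spacing, origin = c(0, 0, 0), direction = diag(3)) {
  storage.mode(data) <- "integer"
  assert_that(all(data %in% 0:3), "labels must be in {0 = background, 1 = CSF, 2 = GM, 3 = WM}")
  vol <- image_volume(data, spacing, origin, direction)
  class(vol) <- c("label_volume", class(vol))
  vol
}

#' @export
print.image_volume <- function(x, ...) {
  cat(sprintf("<%s> %s voxels, spacing %s mm, origin (%s)\n",
              class(x)[1], paste(dim(x$data), collapse = "x"),
              paste(format(x$spacing, digits = 4), collapse = "x"),
              paste(format(x$origin, digits = 4), collapse = ", ")))
  invisible(x)
}

# Label codes used throughout
TISSUE_LEVELS <- c(background = 0L, CSF = 1L, GM = 2L, WM = 3L)

same_grid <- function(a, b, tol = 1e-4) {
  all(dim(a$data) == dim(b$data)) &&
    max(abs(a$spacing - b$spacing)) < tol &&
    max(abs(a$origin - b$origin)) < tol &&
    max(abs(a$direction - b$direction)) < tol
}

# 0-based voxel index grid (n x 3) for a volume, optionally strided.
voxel_grid <- function(vol) {
  d <- dim(vol$data)
  cbind(rep(seq_len(d[1]) - 1, times = d[2] * d[3]),
        rep(rep(seq_len(d[2]) - 1, each = d[1]), times = d[3]),
        rep(seq_len(d[3]) - 1, each = d[1] * d[2]))
}

# voxel (0-based, n x 3) -> physical mm (n x 3)
vox_to_phys <- function(vol, ijk) {
  ijk <- matrix(as.numeric(ijk), ncol = 3)
  sweep(ijk %*% t(vol$direction %*% diag(vol$spacing)), 2, vol$origin, "+")
}

# physical mm (n x 3) -> voxel (0-based real, n x 3)
phys_to_vox <- function(vol, xyz) {
  xyz <- matrix(as.numeric(xyz), ncol = 3)
  sweep(sweep(xyz, 2, vol$origin, "-") %*% vol$direction, 2, vol$spacing, "/")
}

# Physical coordinates of the grid center (mm).
grid_center <- function(vol) {
  as.numeric(vox_to_phys(vol, matrix((dim(vol$data) - 1) / 2, 1)))
}

# Trilinear interpolation of arr at real 0-based voxel coordinates v (n x 3).
# Points outside the grid get `fill`.
interp_trilinear <- function(arr, v, fill = 0) {
  d <- dim(arr)
  inside <- v[, 1] >= 0 & v[, 1] <= d[1] - 1 &
            v[, 2] >= 0 & v[, 2] <= d[2] - 1 &
            v[, 3] >= 0 & v[, 3] <= d[3] - 1
  out <- rep(fill, nrow(v))
  if (!any(inside)) return(out)
  v <- v[inside, , drop = FALSE]
  i0 <- pmin(floor(v[, 1]), d[1] - 2); fx <- v[, 1] - i0
  j0 <- pmin(floor(v[, 2]), d[2] - 2); fy <- v[, 2] - j0
  k0 <- pmin(floor(v[, 3]), d[3] - 2); fz <- v[, 3] - k0
  # degenerate single-voxel axes
  if (d[1] == 1) { i0 <- rep(0, nrow(v)); fx <- rep(0, nrow(v)) }
  if (d[2] == 1) { j0 <- rep(0, nrow(v)); fy <- rep(0, nrow(v)) }
  if (d[3] == 1) { k0 <- rep(0, nrow(v)); fz <- rep(0, nrow(v)) }
  base <- 1 + i0 + d[1] * (j0 + d[2] * k0)
  sx <- 1; sy <- d[1]; sz <- d[1] * d[2]
  if (d[1] == 1) sx <- 0
  if (d[2] == 1) sy <- 0
  if (d[3] == 1) sz <- 0
  val <-
    arr[base]                * (1 - fx) * (1 - fy) * (1 - fz) +
    arr[base + sx]           * fx       * (1 - fy) * (1 - fz) +
    arr[base + sy]           * (1 - fx) * fy       * (1 - fz) +
    arr[base + sx + sy]      * fx       * fy       * (1 - fz) +
    arr[base + sz]           * (1 - fx) * (1 - fy) * fz +
    arr[base + sx + sz]      * fx       * (1 - fy) * fz +
    arr[base + sy + sz]      * (1 - fx) * fy       * fz +
    arr[base + sx + sy + sz] * fx       * fy       * fz
  out[inside] <- val
  out
}

# Trilinear interpolation assuming every point is already inside the grid
# (hot path of the registration metric: bounds were checked by the caller).
interp_trilinear_inside <- function(arr, v) {
  d <- dim(arr)
  i0 <- pmin.int(floor(v[, 1]), d[1] - 2); fx <- v[, 1] - i0
  j0 <- pmin.int(floor(v[, 2]), d[2] - 2); fy <- v[, 2] - j0
  k0 <- pmin.int(floor(v[, 3]), d[3] - 2); fz <- v[, 3] - k0
  base <- 1 + i0 + d[1] * (j0 + d[2] * k0)
  sx <- 1; sy <- d[1]; sz <- d[1] * d[2]
  gx <- 1 - fx; gy <- 1 - fy; gz <- 1 - fz
  (arr[base] * gx + arr[base + sx] * fx) * gy * gz +
    (arr[base + sy] * gx + arr[base + sx + sy] * fx) * fy * gz +
    (arr[base + sz] * gx + arr[base + sx + sz] * fx) * gy * fz +
    (arr[base + sy + sz] * gx + arr[base + sx + sy + sz] * fx) * fy * fz
}

# Nearest-neighbour interpolation at real 0-based voxel coordinates (n x 3).
interp_nearest <- function(arr, v, fill = 0) {
  d <- dim(arr)
  r <- round(v)
  inside <- r[, 1] >= 0 & r[, 1] <= d[1] - 1 &
            r[, 2] >= 0 & r[, 2] <= d[2] - 1 &
            r[, 3] >= 0 & r[, 3] <= d[3] - 1
  out <- rep(fill, nrow(v))
  idx <- 1 + r[inside, 1] + d[1] * (r[inside, 2] + d[2] * r[inside, 3])
  out[inside] <- arr[idx]
  out
}

#' Voxel volume in cubic millimetres
#'
#' The product of the three voxel spacings, the conversion factor between
#' voxel counts and tissue volumes.
#'
#' @param x An [image_volume()], a [header_record()], or a numeric length-3
#'   spacing vector.
#' @return Voxel volume in mm^3.
#' @export
voxel_volume <- function(x) UseMethod("voxel_volume")

#' @export
voxel_volume.image_volume <- function(x) prod(x$spacing)

#' @export
voxel_volume.numeric <- function(x) {
  assert_that(length(x) == 3 && all(is.finite(x)) && all(x > 0),
              "spacing must be 3 positive finite numbers")
  prod(x)
}

#' @export
voxel_volume.header_record <- function(x) {
  ps <- x$pixel_spacing
  dz <- x$spacing_between_slices %||% NA_real_
  if (!is_scalar_number(dz)) dz <- x$slice_thickness
  assert_that(length(ps) == 2 && all(is.finite(ps)) && all(ps > 0) &&
                is_scalar_number(dz) && dz > 0,
              "header has missing or invalid spacing")
  prod(ps) * dz
}

# --- NIfTI I/O ------------------------------------------------------------

LPS_TO_RAS <- diag(c(-1, -1, 1))

#' Write a volume to NIfTI-1
#'
#' Internally the package works in DICOM LPS patient coordinates; on export
#' the affine is converted to the NIfTI RAS convention (x and y axes
#' negated), so files line up with standard neuroimaging viewers.
#'
#' @param vol An [image_volume()] or [label_volume()].
#' @param path Output path (`.nii` or `.nii.gz`).
#' @return `path`, invisibly.
#' @export
write_volume <- function(vol, path) {
  aff <- rbind(cbind(LPS_TO_RAS %*% (vol$direction %*% diag(vol$spacing)),
                     as.numeric(LPS_TO_RAS %*% vol$origin)),
               c(0, 0, 0, 1))
  img <- RNifti::asNifti(vol$data)
  img <- RNifti::`pixdim<-`(img, vol$spacing)
  img <- RNifti::`sform<-`(img, structure(aff, code = 2L))
  img <- RNifti::`qform<-`(img, structure(aff, code = 2L))
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Read a NIfTI-1 volume
#'
#' Converts the NIfTI RAS affine back into the package's LPS convention.
#'
#' @param path NIfTI file path.
#' @param labels If `TRUE`, return a [label_volume()].
#' @return An [image_volume()] or [label_volume()].
#' @export
read_volume <- function(path, labels = FALSE) {
  img <- RNifti::readNifti(path)
  xf <- RNifti::xform(img)
  M <- LPS_TO_RAS %*% xf[1:3, 1:3]
  spacing <- sqrt(colSums(M^2))
  direction <- sweep(M, 2, spacing, "/")
  origin <- as.numeric(LPS_TO_RAS %*% xf[1:3, 4])
  data <- array(as.numeric(img), dim = dim(img))
  if (labels) {
    label_volume(array(as.integer(round(data)), dim = dim(data)),
                 spacing, origin, direction)
  } else {
    image_volume(data, spacing, origin, direction)
  }
}
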