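#' DICOM series header record
#'
#' Typed acquisition and identity metadata for one MR series. Times are in
#' ms (`inversion_time = 0` means no inversion pulse), spacings in mm, field
#' strength in tesla. Identity elements live in the `identity` sub-list so
#' the scrubbing policy can cover them as a unit; vendor private elements
#' are kept as a list of `(group, element, payload)` until removed.
#'
#' @param scanning_sequence One of `"SE"`, `"GR"`, `"IR"`, `"EP"`, `"unknown"`.
#' @param repetition_time,echo_time,inversion_time,flip_angle Acquisition
#'   parameters (ms, ms, ms, degrees). `NA` marks an absent element.
#' @param pixel_spacing In-plane spacing, mm, length 2 `(dx, dy)`.
#' @param slice_thickness,spacing_between_slices Slice geometry, mm.
#' @param matrix_size In-plane matrix `(columns, rows)`.
#' @param n_slices Number of slices.
#' @param field_strength Magnetic field strength, tesla.
#' @param manufacturer,model Scanner vendor and model strings.
#' @param contrast_agent Contrast bolus agent string; empty means none.
#' @param series_number,series_description Series bookkeeping.
#' @param diffusion_b_value Diffusion b-value, s/mm^2 (`NA` = absent).
#' @param n_temporal_positions Number of temporal positions (1 for
#'   structural scans).
#' @param identity Named list of identifying elements: `patient_name`,
#'   `patient_id`, `birth_date`, `study_date` (dates as `"YYYYMMDD"`),
#'   `sex`, `accession`, `institution`, `referring_physician`, `operators`,
#'   `other` (free-form character vector).
#' @param private_tags List of `list(group =, element =, payload =)` with
#'   odd `group` numbers.
#' @return An object of class `header_record`.
#' @export
header_record <- function(scanning_sequence = "unknown",
                          repetition_time = NA_real_,
                          echo_time = NA_real_,
                          inversion_time = 0,
                          flip_angle = NA_real_,
                          pixel_spacing = c(1, 1),
                          slice_thickness = 1,
                          spacing_between_slices = NULL,
                          matrix_size = c(1L, 1L),
                          n_slices = 1L,
                          field_strength = NA_real_,
                          manufacturer = "",
                          model = "",
                          contrast_agent = "",
                          series_number = 1L,
                          series_description = "",
                          diffusion_b_value = NA_real_,
                          n_temporal_positions = 1L,
                          identity = list(),
                          private_tags = list()) {
  id_defaults <- list(patient_name = "", patient_id = "", birth_date = "",
                      study_date = "", sex = "", accession = "",
                      institution = "", referring_physician = "",
                      operators = "", other = character())
  identity <- utils::modifyList(id_defaults, identity)
  h <- structure(list(
    scanning_sequence = scanning_sequence,
    repetition_time = repetition_time,
    echo_time = echo_time,
    inversion_time = inversion_time,
    flip_angle = flip_angle,
    pixel_spacing = as.numeric(pixel_spacing),
    slice_thickness = slice_thickness,
    spacing_between_slices = spacing_between_slices,
    matrix_size = as.integer(matrix_size),
    n_slices = as.integer(n_slices),
    field_strength = field_strength,
    manufacturer = manufacturer,
    model = model,
    contrast_agent = contrast_agent,
    series_number = as.integer(series_number),
    series_description = series_description,
    diffusion_b_value = diffusion_b_value,
    n_temporal_positions = as.integer(n_temporal_positions),
    identity = identity,
    private_tags = private_tags
  ), class = "header_record")
  validate_header(h)
  h
}

validate_header <- function(h) {
  ok_time <- function(x) is.na(x) || x >= 0
  assert_that(ok_time(h$repetition_time) && ok_time(h$echo_time),
              "repetition_time and echo_time must be >= 0 or NA")
  assert_that(all(h$matrix_size >= 1) && h$n_slices >= 1,
              "matrix and n_slices must be >= 1")
  assert_that(length(h$pixel_spacing) == 2 && all(h$pixel_spacing > 0),
              "pixel_spacing must be 2 positive reals")
  invisible(h)
}

#' @export
print.header_record <- function(x, ...) {
  cat(sprintf("<header_record> %s series %d: TR %s TE %s TI %s flip %s, %dx%dx%d\n",
              x$scanning_sequence, x$series_number,
              format(x$repetition_time), format(x$echo_time),
              format(x$inversion_time), format(x$flip_angle),
              x$matrix_size[1], x$matrix_size[2], x$n_slices))
  invisible(x)
}

# --- low-level DICOM codec (explicit VR little endian, classic single-frame) ----

DCM_LONG_VRS <- c("OB", "OW", "OF", "SQ", "UT", "UN")
UID_TRANSFER_SYNTAX_ELE <- "1.2.840.10008.1.2.1"
UID_MR_STORAGE <- "1.2.840.10008.5.1.4.1.1.4"

int_to_raw_le <- function(x, width) {
  out <- raw(width * length(x))
  for (i in seq_along(x)) {
    v <- as.double(x[i])
    for (b in seq_len(width)) {
      out[(i - 1) * width + b] <- as.raw(v %% 256)
      v <- v %/% 256
    }
  }
  out
}

dcm_pad_string <- function(s, pad = as.raw(0x20)) {
  r <- charToRaw(s)
  if (length(r) %% 2 == 1) r <- c(r, pad)
  r
}

dcm_format_ds <- function(x) {
  paste(vapply(x, function(v) {
    s <- format(v, digits = 10, scientific = FALSE, trim = TRUE)
    if (nchar(s) > 16) s <- substr(s, 1, 16)
    s
  }, character(1)), collapse = "\\")
}

# Encode one data element. value: character (already joined), numeric for
# US/UL, or raw for OB/OW.
dcm_encode_element <- function(group, element, vr, value) {
  if (vr %in% c("US", "UL") && is.numeric(value)) {
    body <- int_to_raw_le(value, if (vr == "US") 2L else 4L)
  } else if (is.raw(value)) {
    body <- value
    if (length(body) %% 2 == 1) body <- c(body, as.raw(0))
  } else {
    value <- paste(as.character(value), collapse = "\\")
    body <- dcm_pad_string(value, pad = if (vr == "UI") as.raw(0) else as.raw(0x20))
  }
  head <- c(int_to_raw_le(group, 2L), int_to_raw_le(element, 2L), charToRaw(vr))
  if (vr %in% DCM_LONG_VRS) {
    c(head, as.raw(c(0, 0)), int_to_raw_le(length(body), 4L), body)
  } else {
    assert_that(length(body) <= 65534, "element too long for short VR form")
    c(head, int_to_raw_le(length(body), 2L), body)
  }
}

# elements: list of list(group, element, vr, value); sorted and serialised
# with a standard Part 10 preamble and file meta group.
dcm_write_file <- function(path, elements, sop_instance_uid) {
  ord <- order(vapply(elements, function(e) e$group * 65536 + e$element, numeric(1)))
  elements <- elements[ord]
  body <- do.call(c, lapply(elements, function(e)
    dcm_encode_element(e$group, e$element, e$vr, e$value)))
  meta_elems <- c(
    dcm_encode_element(0x0002, 0x0001, "OB", as.raw(c(0, 1))),
    dcm_encode_element(0x0002, 0x0002, "UI", UID_MR_STORAGE),
    dcm_encode_element(0x0002, 0x0003, "UI", sop_instance_uid),
    dcm_encode_element(0x0002, 0x0010, "UI", UID_TRANSFER_SYNTAX_ELE),
    dcm_encode_element(0x0002, 0x0012, "UI", "1.2.826.0.1.3680043.9.7431.1")
  )
  meta <- c(dcm_encode_element(0x0002, 0x0000, "UL", length(meta_elems)), meta_elems)
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(raw(128), con)
  writeBin(charToRaw("DICM"), con)
  writeBin(c(meta, body), con)
  invisible(path)
}

raw_u16 <- function(r, off) as.integer(r[off + 1]) + 256L * as.integer(r[off + 2])
raw_u32 <- function(r, off) {
  as.double(r[off + 1]) + 256 * as.double(r[off + 2]) +
    65536 * as.double(r[off + 3]) + 16777216 * as.double(r[off + 4])
}

dcm_string_value <- function(body) {
  s <- rawToChar(body[body != as.raw(0)])
  sub("[ ]+$", "", s)
}

# Parse one Part 10 file into a list keyed "GGGG,EEEE" with vr and value.
dcm_parse_file <- function(path) {
  r <- readBin(path, "raw", file.info(path)$size)
  assert_that(length(r) > 132 && rawToChar(r[129:132]) == "DICM",
              sprintf("%s is not a DICOM Part 10 file", path))
  pos <- 132
  out <- list()
  n <- length(r)
  while (pos + 8 <= n) {
    group <- raw_u16(r, pos); element <- raw_u16(r, pos + 2)
    vr <- rawToChar(r[(pos + 5):(pos + 6)])
    if (vr %in% DCM_LONG_VRS) {
      len <- raw_u32(r, pos + 8)
      hdr <- 12
    } else if (grepl("^[A-Z]{2}$", vr)) {
      len <- raw_u16(r, pos + 6)
      hdr <- 8
    } else {
      stop(sprintf("unsupported (implicit VR?) element at offset %d in %s", pos, path))
    }
    if (len == 4294967295) stop(sprintf("undefined-length element in %s not supported", path))
    body <- if (len > 0) r[(pos + hdr + 1):(pos + hdr + len)] else raw(0)
    pos <- pos + hdr + len
    key <- sprintf("%04X,%04X", group, element)
    value <- switch(vr,
      US = raw_u16(body, 0),
      UL = raw_u32(body, 0),
      OB = body, OW = body, UN = body,
      dcm_string_value(body))
    out[[key]] <- list(group = group, element = element, vr = vr, value = value)
  }
  out
}

tag_chr <- function(tags, key, default = "") {
  v <- tags[[key]]$value
  if (is.null(v)) default else as.character(v)
}
tag_num <- function(tags, key, default = NA_real_) {
  v <- tags[[key]]$value
  if (is.null(v) || !nzchar(as.character(v)[1])) return(default)
  as.numeric(strsplit(as.character(v), "\\\\")[[1]])
}

# --- series writer --------------------------------------------------------

#' Write a volume as a classic DICOM series
#'
#' One explicit-VR-little-endian Part 10 file per slice, carrying the
#' acquisition, identity and private elements of `header` plus per-slice
#' geometry (Image Position/Orientation Patient, Pixel Spacing, Slice
#' Thickness). Pixel data are written as 16-bit unsigned integers with
#' rescale slope/intercept 1/0, so intensities are rounded to integers;
#' [read_series()] round-trips the written files exactly.
#'
#' @param volume An [image_volume()]; intensities should lie in
#'   `[0, 65535]`.
#' @param header A [header_record()] consistent with the volume geometry.
#' @param out_dir Output directory (created if needed).
#' @return Character vector of written file paths, invisibly.
#' @export
write_dicom_series <- function(volume, header, out_dir) {
  d <- dim(volume$data)
  assert_that(all(d[1:2] == header$matrix_size) && d[3] == header$n_slices,
              "volume and header matrix/slice counts disagree")
  assert_that(max(abs(volume$spacing[1:2] - header$pixel_spacing)) < 1e-6,
              "volume and header pixel spacing disagree")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  assert_that(dir.exists(out_dir), sprintf("cannot create directory %s", out_dir))

  id <- header$identity
  study_uid <- make_uid("study", id$patient_id, id$study_date)
  series_uid <- make_uid("series", id$patient_id, id$study_date,
                         header$series_number, header$series_description)
  iop <- c(volume$direction[, 1], volume$direction[, 2])
  dz <- header$spacing_between_slices %||% volume$spacing[3]

  common <- list(
    list(group = 0x0008, element = 0x0008, vr = "CS", value = "ORIGINAL\\PRIMARY"),
    list(group = 0x0008, element = 0x0016, vr = "UI", value = UID_MR_STORAGE),
    list(group = 0x0008, element = 0x0020, vr = "DA", value = id$study_date),
    list(group = 0x0008, element = 0x0050, vr = "SH", value = id$accession),
    list(group = 0x0008, element = 0x0060, vr = "CS", value = "MR"),
    list(group = 0x0008, element = 0x0070, vr = "LO", value = header$manufacturer),
    list(group = 0x0008, element = 0x0080, vr = "LO", value = id$institution),
    list(group = 0x0008, element = 0x0090, vr = "PN", value = id$referring_physician),
    list(group = 0x0008, element = 0x103E, vr = "LO", value = header$series_description),
    list(group = 0x0008, element = 0x1070, vr = "PN", value = id$operators),
    list(group = 0x0008, element = 0x1090, vr = "LO", value = header$model),
    list(group = 0x0010, element = 0x0010, vr = "PN", value = id$patient_name),
    list(group = 0x0010, element = 0x0020, vr = "LO", value = id$patient_id),
    list(group = 0x0010, element = 0x0030, vr = "DA", value = id$birth_date),
    list(group = 0x0010, element = 0x0040, vr = "CS", value = id$sex),
    list(group = 0x0018, element = 0x0010, vr = "LO", value = header$contrast_agent),
    list(group = 0x0018, element = 0x0020, vr = "CS", value = header$scanning_sequence),
    list(group = 0x0018, element = 0x0050, vr = "DS", value = dcm_format_ds(header$slice_thickness)),
    list(group = 0x0020, element = 0x000D, vr = "UI", value = study_uid),
    list(group = 0x0020, element = 0x000E, vr = "UI", value = series_uid),
    list(group = 0x0020, element = 0x0011, vr = "IS", value = as.character(header$series_number)),
    list(group = 0x0020, element = 0x0037, vr = "DS", value = dcm_format_ds(iop)),
    list(group = 0x0020, element = 0x0105, vr = "IS", value = as.character(header$n_temporal_positions)),
    list(group = 0x0028, element = 0x0002, vr = "US", value = 1L),
    list(group = 0x0028, element = 0x0004, vr = "CS", value = "MONOCHROME2"),
    list(group = 0x0028, element = 0x0010, vr = "US", value = d[2]),
    list(group = 0x0028, element = 0x0011, vr = "US", value = d[1]),
    # PixelSpacing is (row spacing, column spacing) = (dy, dx)
    list(group = 0x0028, element = 0x0030, vr = "DS",
         value = dcm_format_ds(c(header$pixel_spacing[2], header$pixel_spacing[1]))),
    list(group = 0x0028, element = 0x0100, vr = "US", value = 16L),
    list(group = 0x0028, element = 0x0101, vr = "US", value = 16L),
    list(group = 0x0028, element = 0x0102, vr = "US", value = 15L),
    list(group = 0x0028, element = 0x0103, vr = "US", value = 0L),
    list(group = 0x0028, element = 0x1052, vr = "DS", value = "0"),
    list(group = 0x0028, element = 0x1053, vr = "DS", value = "1")
  )
  num_or_empty <- function(x) if (is.na(x)) "" else dcm_format_ds(x)
  common <- c(common, list(
    list(group = 0x0018, element = 0x0080, vr = "DS", value = num_or_empty(header$repetition_time)),
    list(group = 0x0018, element = 0x0081, vr = "DS", value = num_or_empty(header$echo_time)),
    list(group = 0x0018, element = 0x0082, vr = "DS", value = num_or_empty(header$inversion_time)),
    list(group = 0x0018, element = 0x0087, vr = "DS", value = num_or_empty(header$field_strength)),
    list(group = 0x0018, element = 0x0088, vr = "DS", value = dcm_format_ds(dz)),
    list(group = 0x0018, element = 0x1314, vr = "DS", value = num_or_empty(header$flip_angle)),
    list(group = 0x0018, element = 0x9087, vr = "DS", value = num_or_empty(header$diffusion_b_value))
  ))
  for (pt in header$private_tags) {
    assert_that(pt$group %% 2 == 1, "private tags must have odd group numbers")
    common <- c(common, list(list(group = pt$group, element = pt$element,
                                  vr = if (is.raw(pt$payload)) "OB" else "LO",
                                  value = pt$payload)))
  }

  pix <- round(volume$data)
  pix[pix < 0] <- 0
  pix[pix > 65535] <- 65535
  paths <- character(d[3])
  for (k in seq_len(d[3])) {
    ipp <- as.numeric(vox_to_phys(volume, matrix(c(0, 0, k - 1), 1)))
    slice <- as.integer(pix[, , k])
    slice[slice > 32767] <- slice[slice > 32767] - 65536L  # two's complement for writeBin
    pd <- writeBin(slice, raw(), size = 2, endian = "little")
    elems <- c(common, list(
      list(group = 0x0008, element = 0x0018, vr = "UI",
           value = make_uid("sop", series_uid, k)),
      list(group = 0x0020, element = 0x0013, vr = "IS", value = as.character(k)),
      list(group = 0x0020, element = 0x0032, vr = "DS", value = dcm_format_ds(ipp)),
      list(group = 0x7FE0, element = 0x0010, vr = "OW", value = pd)
    ))
    paths[k] <- file.path(out_dir, sprintf("s%03d_slice_%04d.dcm",
                                           header$series_number, k))
    dcm_write_file(paths[k], elems, make_uid("sop", series_uid, k))
  }
  invisible(paths)
}

# --- series reader --------------------------------------------------------

header_from_tags <- function(tags, n_slices, spacing_between) {
  ps <- tag_num(tags, "0028,0030")  # (dy, dx)
  priv <- list()
  for (e in tags) {
    if (e$group %% 2 == 1 && e$group > 0x0008) {
      priv[[length(priv) + 1]] <- list(group = e$group, element = e$element,
                                       payload = e$value)
    }
  }
  seqv <- tag_chr(tags, "0018,0020", "unknown")
  if (!seqv %in% c("SE", "GR", "IR", "EP")) seqv <- "unknown"
  header_record(
    scanning_sequence = seqv,
    repetition_time = tag_num(tags, "0018,0080"),
    echo_time = tag_num(tags, "0018,0081"),
    inversion_time = { ti <- tag_num(tags, "0018,0082"); if (is.na(ti)) 0 else ti },
    flip_angle = tag_num(tags, "0018,1314"),
    pixel_spacing = c(ps[2], ps[1]),
    slice_thickness = tag_num(tags, "0018,0050"),
    spacing_between_slices = spacing_between,
    matrix_size = c(tags[["0028,0011"]]$value, tags[["0028,0010"]]$value),
    n_slices = n_slices,
    field_strength = tag_num(tags, "0018,0087"),
    manufacturer = tag_chr(tags, "0008,0070"),
    model = tag_chr(tags, "0008,1090"),
    contrast_agent = tag_chr(tags, "0018,0010"),
    series_number = as.integer(tag_num(tags, "0020,0011", 1)),
    series_description = tag_chr(tags, "0008,103E"),
    diffusion_b_value = tag_num(tags, "0018,9087"),
    n_temporal_positions = as.integer(tag_num(tags, "0020,0105", 1)),
    identity = list(
      patient_name = tag_chr(tags, "0010,0010"),
      patient_id = tag_chr(tags, "0010,0020"),
      birth_date = tag_chr(tags, "0010,0030"),
      study_date = tag_chr(tags, "0008,0020"),
      sex = tag_chr(tags, "0010,0040"),
      accession = tag_chr(tags, "0008,0050"),
      institution = tag_chr(tags, "0008,0080"),
      referring_physician = tag_chr(tags, "0008,0090"),
      operators = tag_chr(tags, "0008,1070")
    ),
    private_tags = priv
  )
}

decode_pixels <- function(body, nx, ny) {
  v <- readBin(body, "integer", n = nx * ny, size = 2, signed = FALSE,
               endian = "little")
  matrix(v, nrow = nx, ncol = ny)  # DICOM stream is row-major over (row, col)
}

#' Read DICOM series from a directory
#'
#' Parses every readable DICOM file under `dir`, groups files by Series
#' Instance UID, sorts slices by the projection of Image Position (Patient)
#' onto the slice normal (the cross product of the two Image Orientation
#' rows), infers the slice spacing from consecutive positions, and
#' assembles one oriented volume plus typed header per series. Sorting is
#' independent of the on-disk file order.
#'
#' A series whose in-plane geometry varies between files, or whose
#' inter-slice distance deviates by more than 10% from the median anywhere
#' (e.g. a missing slice), is flagged (`ok = FALSE` with a diagnostic)
#' rather than failing the batch.
#'
#' @param dir Directory containing DICOM files (possibly several
#'   interleaved series).
#' @return A list with one entry per series:
#'   `list(volume, header, ok, diagnostics)`.
#' @export
read_series <- function(dir) {
  files <- list.files(dir, full.names = TRUE, recursive = TRUE)
  parsed <- list()
  for (f in files) {
    p <- tryCatch(dcm_parse_file(f), error = function(e) NULL)
    if (!is.null(p) && !is.null(p[["0020,000E"]])) parsed[[f]] <- p
  }
  assert_that(length(parsed) > 0, sprintf("no readable DICOM files in %s", dir))
  uids <- vapply(parsed, function(p) tag_chr(p, "0020,000E"), character(1))
  out <- list()
  for (uid in unique(uids)) {
    slices <- parsed[uids == uid]
    out[[length(out) + 1]] <- assemble_series(slices)
  }
  out
}

assemble_series <- function(slices) {
  diagnostics <- character()
  iops <- t(vapply(slices, function(p) tag_num(p, "0020,0037"), numeric(6)))
  pss <- t(vapply(slices, function(p) tag_num(p, "0028,0030"), numeric(2)))
  if (max(abs(sweep(iops, 2, iops[1, ]))) > 1e-4 ||
      max(abs(sweep(pss, 2, pss[1, ]))) > 1e-4) {
    diagnostics <- c(diagnostics, "inconsistent in-series geometry")
  }
  tes <- vapply(slices, function(p) tag_num(p, "0018,0081"), numeric(1))
  if (length(unique(tes[!is.na(tes)])) > 1) {
    # multi-echo acquisitions are flagged, not guessed at
    diagnostics <- c(diagnostics, "mixed echo times")
  }
  iop <- iops[1, ]
  normal <- c(iop[2] * iop[6] - iop[3] * iop[5],
              iop[3] * iop[4] - iop[1] * iop[6],
              iop[1] * iop[5] - iop[2] * iop[4])
  ipps <- t(vapply(slices, function(p) tag_num(p, "0020,0032"), numeric(3)))
  pos <- as.numeric(ipps %*% normal)
  ord <- order(pos)
  slices <- slices[ord]; ipps <- ipps[ord, , drop = FALSE]; pos <- pos[ord]
  nz <- length(slices)
  if (nz > 1) {
    gaps <- diff(pos)
    dz <- stats::median(gaps)
    if (any(abs(gaps - dz) > 0.1 * dz)) {
      diagnostics <- c(diagnostics, "non-uniform slice spacing")
    }
  } else {
    dz <- tag_num(slices[[1]], "0018,0050", 1)
  }
  t1 <- slices[[1]]
  nx <- t1[["0028,0011"]]$value; ny <- t1[["0028,0010"]]$value
  data <- array(0, dim = c(nx, ny, nz))
  for (k in seq_len(nz)) {
    data[, , k] <- decode_pixels(slices[[k]][["7FE0,0010"]]$value, nx, ny)
  }
  ps <- tag_num(t1, "0028,0030")  # (dy, dx)
  direction <- cbind(iop[1:3], iop[4:6], normal / sqrt(sum(normal^2)))
  volume <- tryCatch(
    image_volume(data, c(ps[2], ps[1], dz), ipps[1, ], direction),
    error = function(e) {
      diagnostics <<- c(diagnostics, conditionMessage(e))
      NULL
    })
  header <- header_from_tags(t1, nz, if (nz > 1) dz else NULL)
  list(volume = volume, header = header,
       ok = length(diagnostics) == 0 && !is.null(volume),
       diagnostics = diagnostics)
}
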