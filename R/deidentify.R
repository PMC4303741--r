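#' Header scrubbing policy
#'
#' Declares which identity elements are blanked, how dates are handled and
#' whether private elements are removed. The default covers the
#' name/location/identifier/date subset of the DICOM basic confidentiality
#' profile as represented in a [header_record()]: names, patient ID,
#' accession number, institution, referring physician, operators and any
#' free-form identity strings are blanked; birth and study dates are reset
#' to January 1 of their year (so ages and acquisition years remain usable
#' for analysis); patient sex is retained as an analysis covariate; all
#' vendor private elements are removed. Applying a policy twice equals
#' applying it once.
#'
#' @param blank_fields Identity fields to blank.
#' @param date_fields Identity fields reset to `YYYY0101`.
#' @param keep_fields Identity fields deliberately retained (documented in
#'   the audit, never modified).
#' @param remove_all_private Remove every private (odd-group) element.
#' @param uid_salt Salt for the deterministic UID remap used when writing
#'   de-identified files; keyed hashing preserves referential integrity
#'   across files of one series.
#' @return An object of class `scrub_policy`.
#' @export
scrub_policy <- function(blank_fields = c("patient_name", "patient_id",
                                          "accession", "institution",
                                          "referring_physician", "operators",
                                          "other"),
                         date_fields = c("birth_date", "study_date"),
                         keep_fields = "sex",
                         remove_all_private = TRUE,
                         uid_salt = "mriharvest") {
  all_id <- c("patient_name", "patient_id", "birth_date", "study_date", "sex",
              "accession", "institution", "referring_physician", "operators",
              "other")
  covered <- union(union(blank_fields, date_fields), keep_fields)
  assert_that(all(all_id %in% covered),
              paste("policy must cover every identity field; missing:",
                    paste(setdiff(all_id, covered), collapse = ", ")))
  structure(list(blank_fields = blank_fields, date_fields = date_fields,
                 keep_fields = keep_fields,
                 remove_all_private = isTRUE(remove_all_private),
                 uid_salt = uid_salt),
            class = "scrub_policy")
}

reset_date_to_jan1 <- function(d) {
  if (!nzchar(d)) return(d)
  paste0(substr(d, 1, 4), "0101")
}

#' Scrub identity from a header
#'
#' Applies a [scrub_policy()]: blanks the sensitive identity elements,
#' resets dates to January 1 of their year, and removes all private
#' elements. Acquisition parameters (TR/TE/TI/flip angle, spacings,
#' scanner fields) are untouched. The returned audit lists every modified
#' element (field names and actions only — never the removed values). A
#' missing birth date is left absent and audited. Scrubbing is idempotent.
#'
#' @param header A [header_record()].
#' @param policy A [scrub_policy()].
#' @return `list(header = scrubbed header_record, audit = tibble)` with
#'   audit columns `field`, `action`.
#' @export
scrub_header <- function(header, policy = scrub_policy()) {
  audit <- list()
  note <- function(field, action) {
    audit[[length(audit) + 1]] <<- tibble::tibble(field = field, action = action)
  }
  id <- header$identity
  for (f in policy$blank_fields) {
    v <- id[[f]]
    if (length(v) > 0 && any(nzchar(v))) {
      id[[f]] <- if (f == "other") character() else ""
      note(f, "blanked")
    }
  }
  for (f in policy$date_fields) {
    v <- id[[f]]
    if (is.null(v) || !nzchar(v)) {
      note(f, "absent")
    } else if (!identical(v, reset_date_to_jan1(v))) {
      id[[f]] <- reset_date_to_jan1(v)
      note(f, "reset to January 1")
    }
  }
  header$identity <- id
  if (policy$remove_all_private && length(header$private_tags) > 0) {
    for (pt in header$private_tags) {
      note(sprintf("(%04X,%04X)", pt$group, pt$element), "private element removed")
    }
    header$private_tags <- list()
  }
  audit <- if (length(audit)) dplyr::bind_rows(audit) else
    tibble::tibble(field = character(), action = character())
  list(header = header, audit = audit)
}

parse_dcm_date <- function(d) {
  if (inherits(d, "Date")) return(d)
  d <- gsub("-", "", as.character(d))
  assert_that(grepl("^[0-9]{8}$", d), sprintf("unparseable date '%s'", d))
  as.Date(d, format = "%Y%m%d")
}

#' Age in whole years at the scan date
#'
#' Floor of elapsed calendar years between birth and study date. Intended
#' to run before [scrub_header()] destroys the day/month information.
#'
#' @param birth_date,study_date `"YYYYMMDD"` strings (or `Date`s).
#' @return Integer age in years.
#' @export
compute_age_at_scan <- function(birth_date, study_date) {
  b <- parse_dcm_date(birth_date)
  s <- parse_dcm_date(study_date)
  assert_that(s >= b, "study_date earlier than birth_date")
  bl <- as.POSIXlt(b); sl <- as.POSIXlt(s)
  age <- sl$year - bl$year
  before_birthday <- sl$mon < bl$mon | (sl$mon == bl$mon & sl$mday < bl$mday)
  as.integer(age - as.integer(before_birthday))
}

# --- pseudonymization -----------------------------------------------------

#' Pseudonymization mapping
#'
#' A guarded bijection between hospital IDs and research pseudo-IDs, with
#' an exclusion list for patients whose data must never leave the privacy
#' officer. When `pseudo_ids` is omitted, pseudo-IDs are assigned
#' deterministically (`P00001`, ... in sorted hospital-ID order).
#'
#' @param hospital_ids Character vector of unique hospital identifiers.
#' @param pseudo_ids Optional matching pseudo identifiers (unique).
#' @param exclusions Hospital IDs whose requests are halted.
#' @return An object of class `id_map`.
#' @export
id_map <- function(hospital_ids, pseudo_ids = NULL, exclusions = character()) {
  hospital_ids <- as.character(hospital_ids)
  assert_that(!anyDuplicated(hospital_ids), "hospital_ids must be unique")
  if (is.null(pseudo_ids)) {
    pseudo_ids <- sprintf("P%05d", order(order(hospital_ids)))
  }
  pseudo_ids <- as.character(pseudo_ids)
  assert_that(length(pseudo_ids) == length(hospital_ids) &&
                !anyDuplicated(pseudo_ids),
              "pseudo_ids must be unique and match hospital_ids in length")
  structure(list(pairs = tibble::tibble(hospital_id = hospital_ids,
                                        pseudo_id = pseudo_ids),
                 exclusions = as.character(exclusions)),
            class = "id_map")
}

#' Map a hospital ID to its pseudo-ID
#'
#' Deterministic bijective lookup; [depseudonymize()] inverts it. An ID on
#' the exclusion list halts the request with a condition of class
#' `mriharvest_excluded` (carrying an audit entry); an unknown ID errors.
#'
#' @param hospital_id One hospital identifier.
#' @param map An [id_map()].
#' @return The pseudo-ID string.
#' @export
pseudonymize <- function(hospital_id, map) {
  hospital_id <- as.character(hospital_id)
  if (hospital_id %in% map$exclusions) {
    cond <- structure(class = c("mriharvest_excluded", "error", "condition"),
                      list(message = sprintf(
                        "request halted: id is on the exclusion list"),
                        call = sys.call(),
                        audit = sprintf("excluded id request halted at %s",
                                        format(Sys.time(), "%Y-%m-%dT%H:%M:%S"))))
    stop(cond)
  }
  i <- match(hospital_id, map$pairs$hospital_id)
  assert_that(!is.na(i), "unknown hospital id")
  map$pairs$pseudo_id[i]
}

#' @rdname pseudonymize
#' @param pseudo_id One pseudo identifier.
#' @export
depseudonymize <- function(pseudo_id, map) {
  i <- match(as.character(pseudo_id), map$pairs$pseudo_id)
  assert_that(!is.na(i), "unknown pseudo id")
  map$pairs$hospital_id[i]
}

#' Read / write a two-column TSV mapping table
#' @param path TSV path with columns `hospital_id`, `pseudo_id`.
#' @param exclusions_path Optional plain-text file, one excluded ID per
#'   line.
#' @return An [id_map()].
#' @export
read_id_map <- function(path, exclusions_path = NULL) {
  tab <- utils::read.delim(path, colClasses = "character")
  ex <- if (!is.null(exclusions_path) && file.exists(exclusions_path)) {
    readLines(exclusions_path, warn = FALSE)
  } else character()
  id_map(tab$hospital_id, tab$pseudo_id, exclusions = ex[nzchar(ex)])
}

#' @rdname read_id_map
#' @param map An [id_map()].
#' @export
write_id_map <- function(map, path) {
  utils::write.table(map$pairs, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

# --- defacing -------------------------------------------------------------

#' Remove facial features by a registered atlas mask
#'
#' Registers the atlas intensity image affinely to the subject
#' (mutual-information maximization), transforms the atlas face-exclusion
#' mask (1 = keep, 0 = face) to the subject grid with nearest-neighbour
#' interpolation, and multiplies the subject image with it. Voxels inside
#' the kept region are bit-identical to the input; voxels in the face
#' region become 0. Regions mapping outside the atlas domain are kept.
#' If registration fails to reach at least its initial similarity the
#' series is flagged via an error of class `mriharvest_registration_failed`.
#'
#' @param image Subject [image_volume()].
#' @param atlas_intensity Atlas intensity [image_volume()].
#' @param atlas_face_mask Binary [image_volume()]: 1 = keep, 0 = face.
#' @param config A [reg_config()].
#' @param transform Optional precomputed [affine_transform()] (e.g. shared
#'   with the field-of-view check); skips registration.
#' @return `list(image, mask, transform, registration)` where `image` is
#'   the defaced volume and `mask` the resampled keep mask.
#' @export
deface <- function(image, atlas_intensity, atlas_face_mask,
                   config = reg_config(), transform = NULL) {
  reg <- NULL
  if (is.null(transform)) {
    reg <- affine_register(atlas_intensity, image, config)
    if (!is.finite(reg$mi_final) || reg$mi_final < reg$mi_initial) {
      cond <- structure(class = c("mriharvest_registration_failed", "error",
                                  "condition"),
                        list(message = "defacing registration failed: final similarity below initial",
                             call = sys.call()))
      stop(cond)
    }
    transform <- reg$transform
  }
  mask <- apply_transform(atlas_face_mask, transform, image,
                          interpolation = "nearest", fill = 1)
  out <- image
  out$data <- image$data * (mask$data != 0)
  list(image = out, mask = mask, transform = transform, registration = reg)
}
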