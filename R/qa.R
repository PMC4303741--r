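#' Default MR sequence decision table
#'
#' Classifies a series into T1w / T2w / PDw / DWI / fMRI / unknown from
#' its acquisition parameters. The thresholds are declared defaults in the
#' range of standard MR physics texts — clinical sites publish few exact
#' cut-offs — and are fully overridable: each row is a predicate over the
#' header plus the class it assigns, evaluated in order until one fires.
#'
#' @return A list of rows `list(name =, class =, test = function(header))`.
#' @export
default_sequence_table <- function() {
  num <- function(x) !is.na(x)
  list(
    list(name = "diffusion b-value present", class = "DWI",
         test = function(h) num(h$diffusion_b_value) && h$diffusion_b_value > 0),
    list(name = "EPI with >= 10 temporal positions", class = "fMRI",
         test = function(h) h$scanning_sequence == "EP" &&
           h$n_temporal_positions >= 10),
    list(name = "GR with inversion pulse", class = "T1w",
         test = function(h) h$scanning_sequence == "GR" &&
           num(h$inversion_time) && h$inversion_time > 0),
    list(name = "GR short TE high flip", class = "T1w",
         test = function(h) h$scanning_sequence == "GR" &&
           (!num(h$inversion_time) || h$inversion_time == 0) &&
           num(h$echo_time) && h$echo_time < 10 &&
           num(h$flip_angle) && h$flip_angle >= 8),
    list(name = "SE short TR short TE", class = "T1w",
         test = function(h) h$scanning_sequence == "SE" &&
           num(h$repetition_time) && h$repetition_time < 1000 &&
           num(h$echo_time) && h$echo_time < 30),
    list(name = "SE long TR long TE", class = "T2w",
         test = function(h) h$scanning_sequence == "SE" &&
           num(h$repetition_time) && h$repetition_time >= 2000 &&
           num(h$echo_time) && h$echo_time >= 80),
    list(name = "SE long TR short TE", class = "PDw",
         test = function(h) h$scanning_sequence == "SE" &&
           num(h$repetition_time) && h$repetition_time >= 2000 &&
           num(h$echo_time) && h$echo_time < 30)
  )
}

#' Classify the MR sequence of a series from its header
#'
#' Deterministic decision-table classification on echo time, inversion
#' time, repetition time, flip angle, scanning-sequence code, diffusion
#' b-value and temporal positions. Missing numeric elements simply prevent
#' the rows that need them from firing; when no row fires the class is
#' `"unknown"` — a value, not an error.
#'
#' @param header A [header_record()].
#' @param table Decision table, see [default_sequence_table()].
#' @return A tibble with columns `class` and `rule_fired`.
#' @export
classify_sequence <- function(header, table = default_sequence_table()) {
  for (row in table) {
    fired <- tryCatch(isTRUE(row$test(header)), error = function(e) FALSE)
    if (fired) {
      return(tibble::tibble(class = row$class, rule_fired = row$name))
    }
  }
  tibble::tibble(class = "unknown", rule_fired = "no rule fired")
}

#' Select the highest-resolution series per wanted sequence class
#'
#' For each wanted class, picks the candidate with the smallest voxel
#' volume; ties are broken by the larger in-plane matrix, then by the
#' lowest series number. Classes with no candidate are reported absent
#' (`NA` index).
#'
#' @param series A list of series entries as returned by [read_series()]
#'   (each with a `header`), or a list of bare [header_record()]s.
#' @param wanted Character vector of sequence classes to select.
#' @param table Decision table for [classify_sequence()].
#' @return A tibble with one row per wanted class: `class`, `index` (into
#'   `series`), `series_number`, `voxel_volume_mm3`, `rule_fired`.
#' @export
select_best_series <- function(series, wanted = c("T1w", "PDw", "T2w"),
                               table = default_sequence_table()) {
  headers <- lapply(series, function(s)
    if (inherits(s, "header_record")) s else s$header)
  cls <- dplyr::bind_rows(lapply(headers, classify_sequence, table = table))
  info <- tibble::tibble(
    index = seq_along(headers),
    class = cls$class,
    rule_fired = cls$rule_fired,
    series_number = vapply(headers, function(h) h$series_number, integer(1)),
    voxel_volume_mm3 = vapply(headers, voxel_volume, numeric(1)),
    matrix_cells = vapply(headers, function(h) prod(h$matrix_size), numeric(1)))
  out <- lapply(wanted, function(w) {
    cand <- info[info$class == w, ]
    if (nrow(cand) == 0) {
      return(tibble::tibble(class = w, index = NA_integer_,
                            series_number = NA_integer_,
                            voxel_volume_mm3 = NA_real_,
                            rule_fired = NA_character_))
    }
    cand <- cand[order(cand$voxel_volume_mm3, -cand$matrix_cells,
                       cand$series_number), ]
    tibble::tibble(class = w, index = cand$index[1],
                   series_number = cand$series_number[1],
                   voxel_volume_mm3 = cand$voxel_volume_mm3[1],
                   rule_fired = cand$rule_fired[1])
  })
  dplyr::bind_rows(out)
}

#' Contrast-agent exclusion check
#'
#' A series is excluded when the contrast bolus agent element is
#' non-empty after whitespace normalization (gadolinium appears
#' hyperintense and corrupts tissue volumes).
#'
#' @param header A [header_record()].
#' @return `TRUE` if the series must be excluded.
#' @export
check_contrast <- function(header) {
  nzchar(trimws(header$contrast_agent %||% ""))
}

qa_decision <- function(reasons = character(), metrics = list()) {
  structure(list(passed = length(reasons) == 0, reasons = reasons,
                 metrics = metrics),
            class = "qa_decision")
}

#' @export
print.qa_decision <- function(x, ...) {
  cat(sprintf("<qa_decision> %s%s\n",
              if (x$passed) "passed" else "excluded",
              if (length(x$reasons)) paste0(" (", paste(x$reasons, collapse = ", "), ")")
              else ""))
  invisible(x)
}

#' Field-of-view check via a registered brain mask
#'
#' Registers the atlas to the subject affinely, transforms the atlas brain
#' mask onto the subject grid (nearest-neighbour) and measures the
#' brain-voxel fraction on each of the six boundary planes of the volume
#' (first and last index plane along each axis). The series is excluded
#' when any fraction strictly exceeds 0.20 — more than 20 % brain on an
#' outer plane means the brain is likely truncated; a plane at exactly
#' 20 % passes. Registration failure yields an `unreadable` decision.
#'
#' @param subject Subject [image_volume()].
#' @param atlas_brain_mask Binary atlas brain mask [image_volume()].
#' @param atlas_intensity Atlas intensity [image_volume()] (registration
#'   target).
#' @param config A [reg_config()].
#' @param threshold Exclusion threshold on the boundary fraction (strict).
#' @param transform Optional precomputed [affine_transform()].
#' @return A `qa_decision` with `metrics$boundary_brain_fractions` (6
#'   values: x-low, x-high, y-low, y-high, z-low, z-high).
#' @export
check_fov <- function(subject, atlas_brain_mask, atlas_intensity,
                      config = reg_config(), threshold = 0.20,
                      transform = NULL) {
  if (is.null(transform)) {
    reg <- tryCatch(affine_register(atlas_intensity, subject, config),
                    error = function(e) NULL)
    if (is.null(reg) || !is.finite(reg$mi_final)) {
      return(qa_decision("unreadable"))
    }
    transform <- reg$transform
  }
  mask <- apply_transform(atlas_brain_mask, transform, subject,
                          interpolation = "nearest", fill = 0)
  m <- mask$data != 0
  d <- dim(m)
  fr <- c(x_low = mean(m[1, , ]), x_high = mean(m[d[1], , ]),
          y_low = mean(m[, 1, ]), y_high = mean(m[, d[2], ]),
          z_low = mean(m[, , 1]), z_high = mean(m[, , d[3]]))
  reasons <- if (any(fr > threshold)) "incomplete_fov" else character()
  qa_decision(reasons, metrics = list(boundary_brain_fractions = fr))
}
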