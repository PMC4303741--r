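#' Pipeline configuration
#'
#' Bundles the per-stage settings of the examination pipeline. The PACS
#' side of subject selection is abstracted behind filesystem ingestion:
#' examinations arrive as directories of DICOM files. A network retrieval
#' backend is deliberately a stub (`retrieve_network()`) so the module
#' shape survives without a PACS connection.
#'
#' @param map An [id_map()] (required to pseudonymize).
#' @param policy A [scrub_policy()].
#' @param reg A [reg_config()].
#' @param wanted Sequence-class preference for segmentation input: the
#'   first class present is used; `"PDw+T2w"` pairs the two channels when
#'   no T1w exists.
#' @param k,max_per_class,prob_threshold,icv_mask_threshold,cerebrum_mask_threshold
#'   Segmentation parameters (see [segment_examination()]).
#' @param fov_threshold Field-of-view exclusion threshold.
#' @param nonrigid Use the non-rigid registration refinement.
#' @param seed Base seed; per-examination seeds are derived
#'   deterministically from it and the pseudo-ID, so batch results are
#'   order-invariant.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(map, policy = scrub_policy(), reg = reg_config(),
                            wanted = c("T1w", "PDw+T2w"),
                            k = 45, max_per_class = 2000,
                            prob_threshold = 1.0, icv_mask_threshold = 0.5,
                            cerebrum_mask_threshold = 0.8,
                            fov_threshold = 0.20, nonrigid = TRUE,
                            seed = 1L) {
  structure(list(map = map, policy = policy, reg = reg, wanted = wanted,
                 k = k, max_per_class = max_per_class,
                 prob_threshold = prob_threshold,
                 icv_mask_threshold = icv_mask_threshold,
                 cerebrum_mask_threshold = cerebrum_mask_threshold,
                 fov_threshold = fov_threshold, nonrigid = nonrigid,
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Serialize / restore a pipeline configuration as YAML
#'
#' Everything including the mapping table round-trips unchanged, so a
#' batch can be reproduced from its configuration file alone.
#'
#' @param config A [pipeline_config()].
#' @param path YAML file path.
#' @return `path`; `read_pipeline_config()` returns the config.
#' @export
write_pipeline_config <- function(config, path) {
  obj <- unclass(config)
  obj$map <- list(hospital_id = config$map$pairs$hospital_id,
                  pseudo_id = config$map$pairs$pseudo_id,
                  exclusions = config$map$exclusions)
  obj$policy <- unclass(config$policy)
  obj$reg <- unclass(config$reg)
  yaml::write_yaml(obj, path, precision = 15)
  invisible(path)
}

#' @rdname write_pipeline_config
#' @export
read_pipeline_config <- function(path) {
  obj <- yaml::read_yaml(path)
  map <- id_map(obj$map$hospital_id, obj$map$pseudo_id,
                exclusions = as.character(obj$map$exclusions %||% character()))
  policy <- do.call(scrub_policy, obj$policy)
  reg <- do.call(reg_config, obj$reg)
  pipeline_config(map, policy = policy, reg = reg,
                  wanted = unlist(obj$wanted), k = obj$k,
                  max_per_class = obj$max_per_class,
                  prob_threshold = obj$prob_threshold,
                  icv_mask_threshold = obj$icv_mask_threshold,
                  cerebrum_mask_threshold = obj$cerebrum_mask_threshold,
                  fov_threshold = obj$fov_threshold,
                  nonrigid = obj$nonrigid, seed = obj$seed)
}

#' Stub for DICOM network retrieval
#'
#' The pipeline ingests examinations from the filesystem; the C-FIND /
#' C-MOVE network path is intentionally not configured in this package.
#'
#' @param ... Ignored.
#' @export
retrieve_network <- function(...) {
  stop("network retrieval is not configured; ingest DICOM directories from the filesystem",
       call. = FALSE)
}

exam_result <- function(pseudo_id, stages, failure = NULL, log = character(),
                        record = NULL, paths = character()) {
  structure(list(pseudo_id = pseudo_id, stages = stages, failure = failure,
                 log = log, record = record, paths = paths),
            class = "examination_result")
}

#' @export
print.examination_result <- function(x, ...) {
  done <- names(x$stages)[unlist(x$stages)]
  cat(sprintf("<examination_result> %s: %s%s\n",
              x$pseudo_id %||% "?",
              if (length(done)) utils::tail(done, 1) else "failed at intake",
              if (!is.null(x$failure)) paste0(" [", x$failure, "]") else ""))
  invisible(x)
}

#' Run the full pipeline on one examination directory
#'
#' Executes read, demographic extraction, pseudonymization, header
#' scrubbing, quality assurance (sequence classification, best-series
#' selection, contrast and field-of-view checks), defacing, tissue
#' segmentation and volume computation, stopping at the first failing
#' stage with a recorded reason. Stage errors are captured into the
#' result — an examination never crashes a batch. All outputs are written
#' under `out_dir/<pseudo_id>/`; no identity element from the input
#' header appears in any output file.
#'
#' @param exam_dir Directory with the examination's DICOM files.
#' @param atlases An `atlas_set`.
#' @param config A [pipeline_config()].
#' @param out_dir Output root, or `NULL` to skip writing files.
#' @return An `examination_result` with fields `pseudo_id`, `stages`
#'   (`retrieved`, `deidentified`, `qa`, `segmented`, `volumes`),
#'   `failure`, `log`, `record` (biomarker tibble row) and `paths`.
#' @export
run_examination <- function(exam_dir, atlases, config, out_dir = NULL) {
  stages <- list(retrieved = FALSE, deidentified = FALSE, qa = FALSE,
                 segmented = FALSE, volumes = FALSE)
  log <- character()
  say <- function(...) log <<- c(log, sprintf(...))
  fail <- function(reason, pseudo_id = NA_character_) {
    say("FAILED: %s", reason)
    exam_result(pseudo_id, stages, failure = reason, log = log)
  }

  series <- tryCatch(read_series(exam_dir), error = function(e) e)
  if (inherits(series, "error")) return(fail("unreadable"))
  ok <- vapply(series, function(s) isTRUE(s$ok), logical(1))
  for (s in series[!ok]) {
    say("series %d flagged: %s", s$header$series_number,
        paste(s$diagnostics, collapse = "; "))
  }
  series <- series[ok]
  if (length(series) == 0) return(fail("unreadable"))
  stages$retrieved <- TRUE
  say("retrieved %d readable series", length(series))

  # demographics before the scrub destroys the dates
  id0 <- series[[1]]$header$identity
  age <- tryCatch(compute_age_at_scan(id0$birth_date, id0$study_date),
                  error = function(e) NA_integer_)
  gender <- id0$sex
  pseudo <- tryCatch(pseudonymize(id0$patient_id, config$map),
                     error = function(e) e)
  if (inherits(pseudo, "mriharvest_excluded")) return(fail("excluded"))
  if (inherits(pseudo, "error")) return(fail("unknown_id"))

  for (i in seq_along(series)) {
    sc <- scrub_header(series[[i]]$header, config$policy)
    series[[i]]$header <- sc$header
    series[[i]]$header$identity$patient_id <- pseudo
    say("scrubbed series %d: %d element(s) modified",
        series[[i]]$header$series_number, nrow(sc$audit))
  }
  stages$deidentified <- TRUE

  # --- quality assurance ---
  sel <- select_best_series(series, wanted = c("T1w", "PDw", "T2w"))
  use <- NULL; channels_cls <- NULL
  for (w in config$wanted) {
    cls <- strsplit(w, "+", fixed = TRUE)[[1]]
    idx <- sel$index[match(cls, sel$class)]
    if (!anyNA(idx)) { use <- idx; channels_cls <- cls; break }
  }
  if (is.null(use)) return(fail("unsupported_sequence", pseudo))
  say("selected %s (series %s)", paste(channels_cls, collapse = "+"),
      paste(sel$series_number[match(channels_cls, sel$class)], collapse = "+"))
  reasons <- character()
  if (any(vapply(series[use], function(s) check_contrast(s$header), logical(1)))) {
    reasons <- c(reasons, "contrast_agent")
  }
  primary <- series[[use[1]]]$volume
  atlas1 <- atlases$atlases[[1]]
  reg <- tryCatch(affine_register(atlas1$intensity, primary, config$reg),
                  error = function(e) NULL)
  if (is.null(reg)) {
    reasons <- c(reasons, "unreadable")
    fov <- qa_decision("unreadable")
  } else {
    fov <- check_fov(primary, atlas1$cerebrum, atlas1$intensity, config$reg,
                     threshold = config$fov_threshold,
                     transform = reg$transform)
    reasons <- c(reasons, fov$reasons)
  }
  if (length(reasons) > 0) return(fail(paste(unique(reasons), collapse = ","), pseudo))
  stages$qa <- TRUE
  say("qa passed (max boundary brain fraction %.3f)",
      max(fov$metrics$boundary_brain_fractions))

  # --- defacing (reusing the QA registration) ---
  defaced <- lapply(use, function(i) {
    deface(series[[i]]$volume, atlas1$intensity, atlas1$face_keep,
           config$reg, transform = reg$transform)$image
  })
  say("defaced %d volume(s)", length(defaced))

  # --- segmentation ---
  seed_i <- derive_seed(config$seed, fnv1a32(pseudo) %% 10000)
  seg <- tryCatch(
    segment_examination(if (length(defaced) == 1) defaced[[1]] else defaced,
                        atlases, config$reg, k = config$k,
                        max_per_class = config$max_per_class,
                        prob_threshold = config$prob_threshold,
                        icv_mask_threshold = config$icv_mask_threshold,
                        cerebrum_mask_threshold = config$cerebrum_mask_threshold,
                        seed = seed_i, nonrigid = config$nonrigid),
    error = function(e) e)
  if (inherits(seg, "error")) return(fail("segmentation_failed", pseudo))
  stages$segmented <- TRUE

  hdr <- series[[use[1]]]$header
  record <- compute_volumes(seg$labels, seg$cerebrum_mask,
                            pseudo_id = pseudo, age = age, gender = gender,
                            header = hdr)
  stages$volumes <- TRUE
  say("volumes: ICV %.1f ml, brain %.1f ml", record$icv_ml, record$brain_ml)

  paths <- character()
  if (!is.null(out_dir)) {
    ed <- file.path(out_dir, pseudo)
    dir.create(ed, recursive = TRUE, showWarnings = FALSE)
    paths <- c(
      defaced = write_volume(defaced[[1]], file.path(ed, "defaced.nii.gz")),
      labels = write_volume(seg$labels, file.path(ed, "labels.nii.gz")))
    jsonlite::write_json(as.list(record), file.path(ed, "biomarkers.json"),
                         auto_unbox = TRUE, digits = NA)
    jsonlite::write_json(
      list(pseudo_id = pseudo,
           sequence = channels_cls,
           boundary_brain_fractions = as.list(fov$metrics$boundary_brain_fractions)),
      file.path(ed, "qa.json"), auto_unbox = TRUE)
    writeLines(log, file.path(ed, "log.txt"))
    paths <- c(paths, biomarkers = file.path(ed, "biomarkers.json"),
               qa = file.path(ed, "qa.json"), log = file.path(ed, "log.txt"))
  }
  exam_result(pseudo, stages, record = record, log = log, paths = paths)
}

#' Run a batch of examinations
#'
#' Independent per-examination runs (order-invariant: each examination's
#' seed derives from its pseudo-ID, and the cohort table is sorted by
#' pseudo-ID), a cohort CSV for the statistics stage, and the step-wise
#' success-rate accounting. A plausibility screen on the extracted
#' volumes (all volumes positive and brain below ICV) stands in for the
#' visual inspection step.
#'
#' @param exam_dirs Character vector of examination directories (>= 1).
#' @param atlases An `atlas_set`.
#' @param config A [pipeline_config()].
#' @param out_dir Output root, or `NULL` for in-memory results only.
#' @return A list of class `batch_result`: `results` (per-exam), `cohort`
#'   (tibble), `accounting` ([success_rate_report()]), `cohort_csv` path
#'   (when `out_dir` given).
#' @export
run_batch <- function(exam_dirs, atlases, config, out_dir = NULL) {
  assert_that(length(exam_dirs) >= 1, "empty batch")
  results <- lapply(exam_dirs, function(d) {
    tryCatch(run_examination(d, atlases, config, out_dir = out_dir),
             error = function(e) exam_result(NA_character_,
               list(retrieved = FALSE, deidentified = FALSE, qa = FALSE,
                    segmented = FALSE, volumes = FALSE),
               failure = paste("internal:", conditionMessage(e))))
  })
  recs <- lapply(results, function(r) r$record)
  cohort <- dplyr::bind_rows(recs[!vapply(recs, is.null, logical(1))])
  if (nrow(cohort) > 0) cohort <- cohort[order(cohort$pseudo_id), ]
  plausible <- if (nrow(cohort) > 0) {
    with(cohort, is.finite(icv_ml) & csf_ml > 0 & gm_ml > 0 & wm_ml > 0 &
           brain_ml < icv_ml)
  } else logical(0)
  stage_count <- function(stage) {
    sum(vapply(results, function(r) isTRUE(r$stages[[stage]]), logical(1)))
  }
  counts <- c(selected = length(exam_dirs),
              retrieved = stage_count("retrieved"),
              qa_passed = stage_count("qa"),
              biomarker_ok = stage_count("volumes"),
              visual_ok = sum(plausible))
  accounting <- success_rate_report(counts)
  cohort_csv <- NULL
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    cohort_csv <- file.path(out_dir, "cohort.csv")
    utils::write.csv(cohort, cohort_csv, row.names = FALSE)
    utils::write.csv(accounting, file.path(out_dir, "accounting.csv"),
                     row.names = FALSE)
  }
  structure(list(results = results, cohort = cohort, accounting = accounting,
                 cohort_csv = cohort_csv),
            class = "batch_result")
}

#' @export
print.batch_result <- function(x, ...) {
  cat(sprintf("<batch_result> %d examinations, %d with volumes\n",
              length(x$results), nrow(x$cohort)))
  invisible(x)
}

#' Sweep an output tree for planted identity strings
#'
#' The de-identification acceptance gate: scans every file under `dir`
#' (text and binary alike) for occurrences of the given strings and
#' returns the hits. A de-identified output tree must return zero rows.
#'
#' @param dir Directory to sweep.
#' @param strings Character vector of identity strings.
#' @return Tibble with columns `file`, `string` for every hit.
#' @export
scan_for_identity <- function(dir, strings) {
  files <- list.files(dir, recursive = TRUE, full.names = TRUE)
  hits <- list()
  for (f in files) {
    r <- readBin(f, "raw", file.info(f)$size)
    if (grepl("[.]gz$", f)) {
      r <- tryCatch(memDecompress(r, type = "gzip"), error = function(e) r)
    }
    for (s in strings) {
      if (length(grepRaw(s, r, fixed = TRUE)) > 0) {
        hits[[length(hits) + 1]] <- tibble::tibble(file = f, string = s)
      }
    }
  }
  if (length(hits)) dplyr::bind_rows(hits) else
    tibble::tibble(file = character(), string = character())
}
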