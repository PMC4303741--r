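#' Query radiology report texts with a regular expression
#'
#' The cohort-selection front door: returns the study IDs whose report
#' text matches `pattern`, in table order. Matching is case-insensitive by
#' default and uses Perl-compatible regular expressions, so anchors and
#' word boundaries behave as expected.
#'
#' @param reports Data frame with columns `study_id` (unique) and
#'   `report_text`.
#' @param pattern Regular expression.
#' @param ignore_case Case-insensitive matching (default `TRUE`).
#' @return Character vector of matching study IDs.
#' @export
query_reports <- function(reports, pattern, ignore_case = TRUE) {
  assert_that(all(c("study_id", "report_text") %in% names(reports)),
              "reports needs study_id and report_text columns")
  assert_that(!anyDuplicated(reports$study_id), "study_id must be unique")
  hit <- tryCatch(
    grepl(pattern, reports$report_text, ignore.case = ignore_case, perl = TRUE),
    error = function(e) stop(sprintf("invalid regular expression '%s': %s",
                                     pattern, conditionMessage(e)),
                             call. = FALSE),
    warning = function(w) stop(sprintf("invalid regular expression '%s'",
                                       pattern), call. = FALSE))
  as.character(reports$study_id[hit])
}

#' Keep records aged `min_age` years or older at scan time
#'
#' Inclusive at the boundary (45-year-olds stay in by default). Records
#' with a missing age are dropped with a warning.
#'
#' @param records Data frame with an `age` column (years).
#' @param min_age Minimum age in years (inclusive).
#' @return The filtered tibble.
#' @export
filter_age <- function(records, min_age = 45) {
  records <- tibble::as_tibble(records)
  miss <- is.na(records$age)
  if (any(miss)) {
    warning(sprintf("%d record(s) dropped: missing age", sum(miss)),
            call. = FALSE)
  }
  records[!miss & records$age >= min_age, ]
}

#' Tukey interquartile-range outlier exclusion
#'
#' Excludes records whose value falls strictly outside
#' `[Q1 - 1.5 IQR, Q3 + 1.5 IQR]`, with quartiles by linear interpolation
#' between order statistics. By default the rule is applied within each
#' group; pass `group = NULL` to pool. Groups with fewer than 4 records
#' are left untouched with a warning.
#'
#' @param records Data frame.
#' @param value Unquoted expression for the screened value (e.g.
#'   `brain_ml / icv_ml`).
#' @param group Unquoted grouping column, or `NULL` for pooled screening.
#' @param k IQR multiplier (1.5).
#' @param type Quantile algorithm passed to [stats::quantile()] (7 =
#'   linear interpolation).
#' @return `list(kept, excluded)`: two disjoint tibbles partitioning the
#'   input.
#' @export
iqr_filter <- function(records, value, group = group, k = 1.5, type = 7) {
  records <- tibble::as_tibble(records)
  vals <- rlang::eval_tidy(rlang::enquo(value), data = records)
  gq <- rlang::enquo(group)
  grp <- if (rlang::quo_is_null(gq)) rep("all", nrow(records)) else
    as.character(rlang::eval_tidy(gq, data = records))
  out <- logical(nrow(records))
  for (g in unique(grp)) {
    i <- which(grp == g)
    if (length(i) < 4) {
      warning(sprintf("group '%s': fewer than 4 records, no exclusion applied", g),
              call. = FALSE)
      next
    }
    q <- stats::quantile(vals[i], c(0.25, 0.75), type = type, names = FALSE)
    iqr <- q[2] - q[1]
    out[i] <- vals[i] < q[1] - k * iqr | vals[i] > q[2] + k * iqr
  }
  list(kept = records[!out, ], excluded = records[out, ])
}

#' Specification of the volumetric linear models
#'
#' Declares the design of the two cohort models: intracranial volume (or
#' brain volume) regressed on gender, age, diagnostic group, scanning
#' sequence, scanner model and field strength, with ICV as an additional
#' covariate for the brain-volume model to control for head size.
#' Adjusted group means are evaluated at age 60.5 years and (for the
#' brain model) ICV 1,150 ml, with factors at their reference levels —
#' Philips NT Intera for the scanner — and remaining numeric covariates
#' at their sample mean.
#'
#' @param response `"icv_ml"` or `"brain_ml"`.
#' @param include_icv Add `icv_ml` as covariate (default: yes for the
#'   brain model).
#' @param eval_age,eval_icv Evaluation point of the adjusted means.
#' @param ref_group,ref_scanner,ref_sequence,ref_gender Reference levels.
#' @return An object of class `regression_spec`.
#' @export
volume_model_spec <- function(response = c("brain_ml", "icv_ml"),
                              include_icv = NULL,
                              eval_age = 60.5, eval_icv = 1150,
                              ref_group = "open",
                              ref_scanner = "Philips NT Intera",
                              ref_sequence = "T1w",
                              ref_gender = "F") {
  response <- match.arg(response)
  if (is.null(include_icv)) include_icv <- response == "brain_ml"
  structure(list(response = response, include_icv = include_icv,
                 eval_age = eval_age, eval_icv = eval_icv,
                 ref_group = ref_group, ref_scanner = ref_scanner,
                 ref_sequence = ref_sequence, ref_gender = ref_gender),
            class = "regression_spec")
}

relevel_first <- function(x, ref) {
  x <- factor(x)
  if (ref %in% levels(x)) stats::relevel(x, ref) else x
}

#' Fit a volumetric linear model with adjusted group means
#'
#' Ordinary least squares with dummy-coded factors at the declared
#' reference levels. Returns the fitted object together with per-group and
#' per-gender adjusted means (predictions at the spec's evaluation point
#' with factors at reference and remaining numeric covariates at their
#' sample mean), 95% confidence intervals, and all pairwise group
#' contrasts with Bonferroni-adjusted p-values.
#'
#' @param records Cohort tibble with columns `gender`, `age`, `group`,
#'   `sequence`, `scanner_model`, `field_strength`, `icv_ml` and the
#'   response.
#' @param spec A [volume_model_spec()].
#' @return An object of class `volume_fit`: `lm`, `spec`,
#'   `adjusted_means` (tibble), `contrasts` (tibble).
#' @export
fit_volume_model <- function(records, spec = volume_model_spec()) {
  records <- tibble::as_tibble(records)
  needed <- c("gender", "age", "group", "sequence", "scanner_model",
              "field_strength", spec$response,
              if (spec$include_icv) "icv_ml")
  assert_that(all(needed %in% names(records)),
              paste("records missing columns:",
                    paste(setdiff(needed, names(records)), collapse = ", ")))
  df <- data.frame(
    y = records[[spec$response]],
    gender = relevel_first(records$gender, spec$ref_gender),
    age = records$age,
    group = relevel_first(records$group, spec$ref_group),
    sequence = relevel_first(records$sequence, spec$ref_sequence),
    scanner_model = relevel_first(records$scanner_model, spec$ref_scanner),
    field_strength = records$field_strength)
  if (spec$include_icv) df$icv_ml <- records$icv_ml
  terms <- c("gender", "age", "group", "sequence", "scanner_model",
             "field_strength", if (spec$include_icv) "icv_ml")
  # factors with a single observed level cannot be estimated
  for (f in c("gender", "group", "sequence", "scanner_model")) {
    if (nlevels(droplevels(df[[f]])) < 2) {
      warning(sprintf("term '%s' dropped: fewer than 2 observed levels", f),
              call. = FALSE)
      terms <- setdiff(terms, f)
    } else df[[f]] <- droplevels(df[[f]])
  }
  if (length(unique(df$field_strength)) < 2) {
    warning("term 'field_strength' dropped: constant", call. = FALSE)
    terms <- setdiff(terms, "field_strength")
  }
  assert_that(nrow(df) > length(terms) + 1, "more parameters than observations")
  form <- stats::as.formula(paste("y ~", paste(terms, collapse = " + ")))
  fit <- stats::lm(form, data = df)
  alias <- stats::alias(fit)$Complete
  if (!is.null(alias)) {
    stop(sprintf("rank-deficient design; aliased terms: %s",
                 paste(rownames(alias), collapse = ", ")), call. = FALSE)
  }

  obj <- structure(list(lm = fit, spec = spec, data = df, terms = terms),
                   class = "volume_fit")
  obj$adjusted_means <- adjusted_means(obj)
  obj$contrasts <- group_contrasts(obj)
  obj
}

# design row at the adjusted-mean evaluation point
eval_row <- function(obj, group, gender) {
  df <- obj$data; spec <- obj$spec
  new <- df[1, , drop = FALSE]
  new$age <- spec$eval_age
  if ("icv_ml" %in% names(new)) new$icv_ml <- spec$eval_icv
  if ("field_strength" %in% obj$terms) new$field_strength <- mean(df$field_strength)
  if ("sequence" %in% obj$terms) new$sequence <- factor(levels(df$sequence)[1], levels(df$sequence))
  if ("scanner_model" %in% obj$terms) new$scanner_model <- factor(levels(df$scanner_model)[1], levels(df$scanner_model))
  if ("group" %in% obj$terms) new$group <- factor(group, levels(df$group))
  if ("gender" %in% obj$terms) new$gender <- factor(gender, levels(df$gender))
  stats::model.matrix(stats::delete.response(stats::terms(obj$lm)), new)
}

#' Adjusted means per group and gender
#'
#' The model prediction at the evaluation point (`x' beta`), with a
#' t-based 95% confidence interval from `sqrt(x' V x)`.
#'
#' @param obj A `volume_fit`.
#' @param level Confidence level.
#' @return Tibble: `group`, `gender`, `estimate`, `se`, `conf.low`,
#'   `conf.high`.
#' @export
adjusted_means <- function(obj, level = 0.95) {
  df <- obj$data
  beta <- stats::coef(obj$lm)
  V <- stats::vcov(obj$lm)
  tq <- stats::qt(1 - (1 - level) / 2, obj$lm$df.residual)
  groups <- if ("group" %in% obj$terms) levels(df$group) else NA_character_
  genders <- if ("gender" %in% obj$terms) levels(df$gender) else NA_character_
  grid <- expand.grid(group = groups, gender = genders,
                      stringsAsFactors = FALSE)
  rows <- lapply(seq_len(nrow(grid)), function(i) {
    x <- eval_row(obj, grid$group[i], grid$gender[i])
    est <- as.numeric(x %*% beta)
    se <- sqrt(as.numeric(x %*% V %*% t(x)))
    tibble::tibble(group = grid$group[i], gender = grid$gender[i],
                   estimate = est, se = se,
                   conf.low = est - tq * se, conf.high = est + tq * se)
  })
  dplyr::bind_rows(rows)
}

#' Pairwise group contrasts with Bonferroni correction
#'
#' Differences between the adjusted means of every pair of groups (these
#' reduce to differences of group coefficients), with t-tests on the
#' residual degrees of freedom and Bonferroni-adjusted p-values over the
#' number of pairs.
#'
#' @param obj A `volume_fit`.
#' @return Tibble: `group1`, `group2`, `estimate`, `se`, `statistic`,
#'   `p.value`, `p.bonferroni`.
#' @export
group_contrasts <- function(obj) {
  if (!"group" %in% obj$terms) {
    return(tibble::tibble(group1 = character(), group2 = character(),
                          estimate = numeric(), se = numeric(),
                          statistic = numeric(), p.value = numeric(),
                          p.bonferroni = numeric()))
  }
  df <- obj$data
  beta <- stats::coef(obj$lm)
  V <- stats::vcov(obj$lm)
  dfres <- obj$lm$df.residual
  gs <- levels(df$group)
  gender0 <- if ("gender" %in% obj$terms) levels(df$gender)[1] else NA
  pairs <- utils::combn(gs, 2)
  rows <- lapply(seq_len(ncol(pairs)), function(i) {
    x1 <- eval_row(obj, pairs[1, i], gender0)
    x2 <- eval_row(obj, pairs[2, i], gender0)
    dx <- x1 - x2
    est <- as.numeric(dx %*% beta)
    se <- sqrt(as.numeric(dx %*% V %*% t(dx)))
    tibble::tibble(group1 = pairs[1, i], group2 = pairs[2, i],
                   estimate = est, se = se, statistic = est / se,
                   p.value = 2 * stats::pt(-abs(est / se), dfres))
  })
  out <- dplyr::bind_rows(rows)
  out$p.bonferroni <- pmin(1, out$p.value * nrow(out))
  out
}

#' @export
print.volume_fit <- function(x, ...) {
  cat(sprintf("<volume_fit> %s ~ %s (n = %d)\n", x$spec$response,
              paste(x$terms, collapse = " + "), nrow(x$data)))
  print(glance(x))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy coefficient table of a volume model
#' @param x A `volume_fit`.
#' @param conf.level Confidence level for the intervals.
#' @param ... Unused.
#' @return Tibble with `term`, `estimate`, `std.error`, `statistic`,
#'   `p.value`, `conf.low`, `conf.high`.
#' @export
tidy.volume_fit <- function(x, conf.level = 0.95, ...) {
  s <- summary(x$lm)$coefficients
  ci <- stats::confint(x$lm, level = conf.level)
  tibble::tibble(term = rownames(s), estimate = s[, 1], std.error = s[, 2],
                 statistic = s[, 3], p.value = s[, 4],
                 conf.low = ci[, 1], conf.high = ci[, 2])
}

#' One-row model summary of a volume model
#' @param x A `volume_fit`.
#' @param ... Unused.
#' @return Tibble with `r.squared`, `adj.r.squared`, `statistic` (overall
#'   F), `df`, `df.residual`, `p.value`, `nobs`.
#' @export
glance.volume_fit <- function(x, ...) {
  s <- summary(x$lm)
  f <- s$fstatistic
  tibble::tibble(r.squared = s$r.squared, adj.r.squared = s$adj.r.squared,
                 statistic = unname(f[1]), df = unname(f[2]),
                 df.residual = unname(f[3]),
                 p.value = stats::pf(f[1], f[2], f[3], lower.tail = FALSE),
                 nobs = nrow(x$data))
}

#' Step-wise pipeline success-rate accounting
#'
#' Converts per-group counts at the pipeline steps (selection, retrieval,
#' quality assurance, biomarker extraction, visual check) into percentages
#' of the selected count. Counts must be non-increasing across steps — an
#' increase is a pipeline accounting bug and errors. A group with zero
#' selected yields a warning and an all-`NA` percentage row.
#'
#' @param counts Either a named numeric vector with entries `selected`,
#'   `retrieved`, `qa_passed`, `biomarker_ok`, `visual_ok`, or a data
#'   frame with those columns plus `group`.
#' @return A tibble of class `success_rate_report` in long form: `group`,
#'   `step` (ordered factor), `count`, `percent`.
#' @export
success_rate_report <- function(counts) {
  steps <- c("selected", "retrieved", "qa_passed", "biomarker_ok", "visual_ok")
  if (is.numeric(counts)) {
    counts <- tibble::as_tibble(as.list(counts))
    counts$group <- "all"
  }
  counts <- tibble::as_tibble(counts)
  assert_that(all(steps %in% names(counts)),
              paste("counts must contain:", paste(steps, collapse = ", ")))
  rows <- lapply(seq_len(nrow(counts)), function(i) {
    v <- as.numeric(counts[i, steps])
    assert_that(all(v >= 0), "counts must be non-negative")
    assert_that(all(diff(v) <= 0),
                sprintf("group '%s': counts increase across steps (pipeline accounting bug)",
                        counts$group[i]))
    pct <- if (v[1] == 0) {
      warning(sprintf("group '%s': zero selected", counts$group[i]),
              call. = FALSE)
      rep(NA_real_, length(v))
    } else 100 * v / v[1]
    tibble::tibble(group = counts$group[i],
                   step = factor(steps, levels = steps, ordered = TRUE),
                   count = v, percent = pct)
  })
  out <- dplyr::bind_rows(rows)
  class(out) <- c("success_rate_report", class(out))
  out
}

#' Simulate a synthetic biomarker cohort from the volumetric model
#'
#' Draws a cohort table from the brain-volume linear model with known
#' coefficients, for validating the fitting machinery: five diagnostic
#' groups in roughly the proportions of a mixed clinical population,
#' gender-balanced, ages truncated-normal above 45, four scanner models,
#' two field strengths, T1w or PDw sequences, ICV with a gender effect,
#' and the response generated as `x' beta + noise`.
#'
#' @param n Cohort size.
#' @param beta Named coefficients: `intercept`, `genderM`, `age`, group
#'   effects `group_dementia_pos`, `group_dementia_neg`, `group_ms_pos`,
#'   `group_ms_neg` (open question is reference), `sequencePDw`,
#'   per-scanner effects, `field_strength`, `icv`.
#' @param sigma Residual SD (ml).
#' @param seed Integer seed.
#' @return A cohort tibble with a `true_beta` attribute.
#' @export
simulate_cohort <- function(n = 650,
                            beta = c(intercept = 260, genderM = 0,
                                     age = -0.9,
                                     group_dementia_pos = -24,
                                     group_dementia_neg = 0,
                                     group_ms_pos = 8, group_ms_neg = 8,
                                     sequencePDw = 5,
                                     scanner_ge_discovery = 3,
                                     scanner_ge_signa = -2,
                                     scanner_siemens_sonata = 1,
                                     field_strength = 2,
                                     icv = 0.62),
                            sigma = 20, seed = 1L) {
  withr::with_seed(seed, {
    groups <- sample(c("dementia_pos", "dementia_neg", "ms_pos", "ms_neg", "open"),
                     n, replace = TRUE,
                     prob = c(83, 79, 76, 70, 344) / 652)
    gender <- sample(c("M", "F"), n, replace = TRUE)
    age <- pmax(45, stats::rnorm(n, 60.5, 9.8))
    scanner <- sample(c("Philips NT Intera", "GE Discovery", "GE Signa",
                        "Siemens Sonata"), n, replace = TRUE,
                      prob = c(0.4, 0.2, 0.25, 0.15))
    fs <- sample(c(1.5, 3), n, replace = TRUE, prob = c(0.85, 0.15))
    seqs <- ifelse(groups %in% c("ms_pos", "ms_neg"),
                   sample(c("T1w", "PDw"), n, replace = TRUE, prob = c(0.2, 0.8)),
                   "T1w")
    icv <- stats::rnorm(n, ifelse(gender == "M", 1212, 1084), 55)
    mu <- beta["intercept"] +
      beta["genderM"] * (gender == "M") +
      beta["age"] * age +
      beta["group_dementia_pos"] * (groups == "dementia_pos") +
      beta["group_dementia_neg"] * (groups == "dementia_neg") +
      beta["group_ms_pos"] * (groups == "ms_pos") +
      beta["group_ms_neg"] * (groups == "ms_neg") +
      beta["sequencePDw"] * (seqs == "PDw") +
      beta["scanner_ge_discovery"] * (scanner == "GE Discovery") +
      beta["scanner_ge_signa"] * (scanner == "GE Signa") +
      beta["scanner_siemens_sonata"] * (scanner == "Siemens Sonata") +
      beta["field_strength"] * fs +
      beta["icv"] * icv
    brain <- as.numeric(mu) + stats::rnorm(n, 0, sigma)
    out <- tibble::tibble(
      pseudo_id = sprintf("P%05d", seq_len(n)),
      age = age, gender = gender, group = groups, sequence = seqs,
      scanner_model = scanner, field_strength = fs,
      icv_ml = icv, brain_ml = brain)
    attr(out, "true_beta") <- beta
    attr(out, "sigma") <- sigma
    out
  })
}
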