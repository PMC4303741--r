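reports_fixture <- tibble::tibble(
  study_id = c("S1", "S2", "S3", "S4"),
  report_text = c("Scan under dementia protocol; hippocampal atrophy",
                  "MS protocol examination, periventricular lesions",
                  "open question protocol",
                  "Follow-up, no dementia findings"))

test_that("report queries follow regular-expression semantics, case-insensitive", {
  expect_equal(query_reports(reports_fixture, "dementia"), c("S1", "S4"))
  expect_equal(query_reports(reports_fixture, "DEMENTIA PROTOCOL"), "S1")
  expect_equal(query_reports(reports_fixture, "^MS\\b"), "S2")
  expect_equal(query_reports(reports_fixture, "xyzzy"), character())
  expect_error(query_reports(reports_fixture, "(["), "invalid regular expression")
})

test_that("the age filter is inclusive at 45 and drops missing ages with a warning", {
  rec <- tibble::tibble(age = c(44, 45, 46, NA), id = 1:4)
  expect_warning(out <- filter_age(rec), "missing age")
  expect_equal(out$id, 2:3)
  expect_equal(nrow(filter_age(tibble::tibble(age = numeric()))), 0)
})

test_that("the IQR rule excludes exactly the outlier on the worked 13-point set", {
  rec <- tibble::tibble(val = c(seq(0.70, 0.80, length.out = 12), 0.95),
                        grp = "a")
  res <- iqr_filter(rec, value = val, group = grp)
  expect_equal(res$excluded$val, 0.95)
  expect_equal(nrow(res$kept), 12)
})

test_that("identical values produce no exclusions and the rule partitions its input", {
  rec <- tibble::tibble(val = rep(0.75, 10), grp = "a")
  res <- iqr_filter(rec, value = val, group = grp)
  expect_equal(nrow(res$excluded), 0)
  set.seed(3)
  rec2 <- tibble::tibble(id = 1:40, val = stats::rnorm(40),
                         grp = rep(c("a", "b"), 20))
  res2 <- iqr_filter(rec2, value = val, group = grp)
  expect_setequal(c(res2$kept$id, res2$excluded$id), 1:40)
  expect_length(intersect(res2$kept$id, res2$excluded$id), 0)
})

test_that("the IQR rule agrees with a direct quantile oracle on random sets", {
  for (sd in 1:25) {
    set.seed(sd)
    n <- sample(4:50, 1)
    v <- round(stats::rnorm(n, 0.75, 0.05), 4)
    res <- iqr_filter(tibble::tibble(val = v), value = val, group = NULL)
    q <- stats::quantile(v, c(0.25, 0.75), type = 7, names = FALSE)
    bounds <- c(q[1] - 1.5 * (q[2] - q[1]), q[2] + 1.5 * (q[2] - q[1]))
    oracle_out <- v < bounds[1] | v > bounds[2]
    expect_equal(sort(res$excluded$val), sort(v[oracle_out]),
                 info = paste("seed", sd))
  }
})

test_that("small groups are left unfiltered with a warning", {
  rec <- tibble::tibble(val = c(1, 2, 100), grp = "tiny")
  expect_warning(res <- iqr_filter(rec, value = val, group = grp), "fewer than 4")
  expect_equal(nrow(res$excluded), 0)
})

test_that("zero-noise synthetic cohorts return the exact generating coefficients", {
  co <- simulate_cohort(n = 650, sigma = 0, seed = 3)
  fit <- suppressWarnings(fit_volume_model(co, volume_model_spec("brain_ml")))
  tb <- attr(co, "true_beta")
  td <- suppressWarnings(tidy(fit))
  est <- function(term) td$estimate[td$term == term]
  expect_lt(abs(est("age") - tb["age"]), 1e-8)
  expect_lt(abs(est("icv_ml") - tb["icv"]), 1e-8)
  expect_lt(abs(est("groupdementia_pos") - tb["group_dementia_pos"]), 1e-8)
  expect_lt(abs(est("field_strength") - tb["field_strength"]), 1e-8)
  expect_lt(max(abs(stats::residuals(fit$lm))), 1e-8)
})

test_that("the adjusted mean equals the coefficient dot product with the evaluation row", {
  co <- simulate_cohort(n = 300, sigma = 12, seed = 5)
  fit <- fit_volume_model(co, volume_model_spec("brain_ml"))
  row <- mriharvest:::eval_row(fit, "dementia_pos", "M")
  manual <- as.numeric(row %*% stats::coef(fit$lm))
  am <- fit$adjusted_means
  expect_equal(am$estimate[am$group == "dementia_pos" & am$gender == "M"],
               manual)
})

test_that("refactoring the group reference level leaves fits, adjusted means and contrasts unchanged", {
  co <- simulate_cohort(n = 400, sigma = 10, seed = 6)
  f1 <- fit_volume_model(co, volume_model_spec("brain_ml", ref_group = "open"))
  f2 <- fit_volume_model(co, volume_model_spec("brain_ml",
                                               ref_group = "ms_neg"))
  expect_equal(stats::fitted(f1$lm), stats::fitted(f2$lm), tolerance = 1e-9)
  a1 <- dplyr::arrange(f1$adjusted_means, group, gender)
  a2 <- dplyr::arrange(f2$adjusted_means, group, gender)
  expect_equal(a1$estimate, a2$estimate, tolerance = 1e-9)
  key <- function(x) paste(pmin(x$group1, x$group2), pmax(x$group1, x$group2))
  c1 <- f1$contrasts[order(key(f1$contrasts)), ]
  c2 <- f2$contrasts[order(key(f2$contrasts)), ]
  expect_equal(abs(c1$estimate), abs(c2$estimate), tolerance = 1e-9)
  expect_equal(c1$p.bonferroni, c2$p.bonferroni, tolerance = 1e-9)
})

test_that("adjusted means agree with an independent reference-grid computation", {
  co <- simulate_cohort(n = 650, sigma = 15, seed = 4)
  fit <- fit_volume_model(co, volume_model_spec("brain_ml"))
  em <- as.data.frame(emmeans::emmeans(
    fit$lm, ~ group + gender,
    at = list(age = 60.5, icv_ml = 1150, sequence = "T1w",
              scanner_model = "Philips NT Intera",
              field_strength = mean(fit$data$field_strength))))
  m <- merge(em, fit$adjusted_means, by = c("group", "gender"))
  expect_equal(m$emmean, m$estimate, tolerance = 1e-8)
  expect_equal(m$lower.CL, m$conf.low, tolerance = 1e-8)
})

test_that("a rank-deficient design errors with the aliased term named", {
  co <- simulate_cohort(n = 200, sigma = 10, seed = 7)
  co$field_strength <- ifelse(co$scanner_model == "GE Signa", 3, 1.5)
  co$scanner_model <- ifelse(co$scanner_model == "GE Signa", "GE Signa",
                             "Philips NT Intera")
  expect_error(suppressWarnings(fit_volume_model(co, volume_model_spec("brain_ml"))),
               "alias")
})

test_that("tidy and glance expose the broom-style surfaces", {
  co <- simulate_cohort(n = 300, sigma = 10, seed = 8)
  fit <- fit_volume_model(co, volume_model_spec("icv_ml"))
  td <- tidy(fit)
  expect_true(all(c("term", "estimate", "std.error", "statistic", "p.value",
                    "conf.low", "conf.high") %in% names(td)))
  gl <- glance(fit)
  expect_equal(gl$nobs, 300)
  expect_lte(gl$adj.r.squared, gl$r.squared)
  expect_s3_class(autoplot(fit), "ggplot")
})

test_that("success-rate accounting turns counts into percentages of selection", {
  sr <- success_rate_report(c(selected = 100, retrieved = 97, qa_passed = 86,
                              biomarker_ok = 84, visual_ok = 82))
  expect_equal(sr$percent, c(100, 97, 86, 84, 82))
  expect_true(all(diff(sr$percent) <= 0))
  expect_s3_class(autoplot(sr), "ggplot")
  expect_error(success_rate_report(c(selected = 10, retrieved = 11,
                                     qa_passed = 9, biomarker_ok = 8,
                                     visual_ok = 8)),
               "accounting")
  expect_warning(success_rate_report(c(selected = 0, retrieved = 0,
                                       qa_passed = 0, biomarker_ok = 0,
                                       visual_ok = 0)),
                 "zero selected")
})
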