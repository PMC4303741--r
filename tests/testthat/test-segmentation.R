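test_that("bias correction is near-unity on a bias-free phantom and strictly positive", {
  ph <- generate_phantom(phantom_spec(
    seed = 2, bias_field = list(amplitude = 0,
                                coef = c(x = 0, y = 0, z = 0,
                                         x2 = 0, y2 = 0, z2 = 0))))
  res <- correct_bias(ph$image)
  expect_lt(max(abs(res$field$data - 1)), 0.02)
  expect_true(all(res$field$data > 0))
  # mean foreground intensity preserved
  fg <- ph$image$data > 0.25 * stats::quantile(ph$image$data[ph$image$data > 0], 0.99)
  expect_equal(mean(res$image$data[fg]), mean(ph$image$data[fg]),
               tolerance = 1e-6)
})

test_that("a 20% smooth field is recovered: within-WM variation halves after correction", {
  sp <- phantom_spec(seed = 3, class_noise_sd = 1,
                     bias_field = list(amplitude = 0.2,
                                       coef = c(x = 1, y = 0.5, z = 0.7,
                                                x2 = 0.4, y2 = -0.3, z2 = 0.3)))
  ph <- generate_phantom(sp)
  res <- correct_bias(ph$image)
  wm <- ph$class_map == 3L
  cv <- function(x) stats::sd(x) / mean(x)
  expect_lte(cv(res$image$data[wm]), 0.5 * cv(ph$image$data[wm]))
})

test_that("an all-zero image cannot be bias-corrected", {
  z <- image_volume(array(0, dim = c(8, 8, 8)), c(3, 3, 3))
  expect_error(correct_bias(z), "all-zero")
})

test_that("identical identity-posed atlases give a 0/1 probability map equal to the labels", {
  sp <- clean_spec(seed = 4)
  ph <- generate_phantom(sp)
  atl <- generate_atlas_set(sp, n = 6, jitter = NULL, seed = 9L)
  pm <- build_probability_map(atl, ph$image, fast_reg(), nonrigid = FALSE)
  expect_equal(pm$n_atlases, 6)
  # probabilities quantized to sixths and summing to one
  probs <- cbind(as.numeric(pm$background), as.numeric(pm$csf),
                 as.numeric(pm$gm), as.numeric(pm$wm))
  expect_true(all(abs(probs * 6 - round(probs * 6)) < 1e-9))
  expect_true(all(abs(rowSums(probs) - 1) < 1e-6))
  # with identical atlases the map is hard and matches the ground truth
  # almost everywhere (identity pose, exact self-alignment)
  hard <- max.col(probs) - 1L
  agree <- mean(hard == as.integer(ph$labels$data))
  expect_gt(agree, 0.98)
})

test_that("majority voting implements the 0.8 threshold arithmetic", {
  g <- image_volume(array(0, dim = c(4, 4, 2)), c(1, 1, 1))
  mk <- function(on) { m <- g; m$data[on] <- 1; m }
  masks5 <- c(replicate(5, mk(1:8), simplify = FALSE), list(mk(integer(0))))
  m5 <- majority_mask(masks5, 0.8)   # 5 of 6 = 0.833 -> in
  expect_true(all(m5$data[1:8] == 1))
  masks4 <- c(replicate(4, mk(1:8), simplify = FALSE),
              replicate(2, mk(integer(0)), simplify = FALSE))
  m4 <- majority_mask(masks4, 0.8)   # 4 of 6 = 0.667 -> out
  expect_true(all(m4$data == 0))
  m6 <- majority_mask(replicate(6, mk(1:8), simplify = FALSE), 0.8)
  expect_true(all(m6$data[1:8] == 1))
  expect_error(majority_mask(list()), "at least one")
})

test_that("training extraction honours unanimity, determinism and the per-class cap", {
  sp <- clean_spec(seed = 5)
  ph <- generate_phantom(sp)
  atl <- generate_atlas_set(sp, n = 6, jitter = NULL, seed = 9L)
  pm <- build_probability_map(atl, ph$image, fast_reg(), nonrigid = FALSE)
  m1 <- sample_training_set(ph$image, pm, max_per_class = 500, seed = 3L)
  m2 <- sample_training_set(ph$image, pm, max_per_class = 500, seed = 3L)
  expect_identical(m1$features, m2$features)
  expect_identical(m1$classes, m2$classes)
  expect_lte(max(table(m1$classes)), 500)
  # noise-free phantom: unanimity samples carry the ground-truth intensity
  means <- sp$class_means
  expect_true(all(m1$features[m1$classes == 1, 1] == means["csf"]))
  expect_true(all(m1$features[m1$classes == 3, 1] == means["wm"]))
})

test_that("the threshold falls back stepwise when a class lacks candidates", {
  sp <- clean_spec(seed = 6)
  ph <- generate_phantom(sp)
  atl <- generate_atlas_set(sp, n = 6, jitter = NULL, seed = 9L)
  pm <- build_probability_map(atl, ph$image, fast_reg(), nonrigid = FALSE)
  # demote all unanimous CSF votes to 5/6: one fallback step succeeds
  pm2 <- pm
  pm2$csf[pm2$csf == 1] <- 5 / 6
  expect_warning(model <- sample_training_set(ph$image, pm2, k = 45, seed = 1L),
                 "lowered")
  expect_gte(sum(model$classes == 1), 45)
  # starve CSF entirely: the error names the class
  pm3 <- pm
  pm3$csf[] <- 0
  expect_error(suppressWarnings(sample_training_set(ph$image, pm3, k = 45)),
               "csf")
})

test_that("kNN with separated classes and k = 1 reproduces ground truth inside the mask", {
  sp <- clean_spec(seed = 7)
  ph <- generate_phantom(sp)
  icv <- ph$image
  icv$data <- array(as.numeric(ph$labels$data > 0), dim = dim(ph$labels$data))
  feats <- matrix(c(30, 65, 100), ncol = 1)
  model <- structure(list(features = feats, classes = 1:3, k = 1L,
                          tie_rule = ""), class = "knn_model")
  seg <- knn_segment(ph$image, model, icv)
  expect_identical(seg$data, ph$labels$data)
  # outside the mask everything is background
  expect_true(all(seg$data[icv$data == 0] == 0L))
})

test_that("kNN labels match an exhaustive brute-force scan on small noisy instances", {
  for (sd in 1:5) {
    set.seed(sd)
    n <- sample(100:300, 1)
    train <- round(stats::rnorm(n, rep(c(30, 65, 100), length.out = n), 10))
    cls <- rep(1:3, length.out = n)
    k <- sample(c(5, 15, 45), 1)
    q <- round(stats::runif(800, 15, 115))
    expect_identical(mriharvest:::knn_classify_1d(train, cls, k, q),
                     brute_knn_1d(train, cls, k, q),
                     info = paste("seed", sd))
  }
})

test_that("segmentation is invariant to global linear intensity rescaling", {
  sp <- small_spec(seed = 8)
  ph <- generate_phantom(sp)
  icv <- ph$image
  icv$data <- array(as.numeric(ph$labels$data > 0), dim = dim(ph$labels$data))
  set.seed(1)
  feats <- matrix(stats::rnorm(300, rep(c(30, 65, 100), each = 100), 3), ncol = 1)
  model <- structure(list(features = feats, classes = rep(1:3, each = 100),
                          k = 15L, tie_rule = ""), class = "knn_model")
  seg1 <- knn_segment(ph$image, model, icv)
  scaled <- ph$image; scaled$data <- scaled$data * 4
  model4 <- model; model4$features <- model$features * 4
  seg2 <- knn_segment(scaled, model4, icv)
  expect_identical(seg1$data, seg2$data)
})

test_that("a duplicated second channel reproduces the single-channel segmentation", {
  # distances in the duplicated 2-D feature space are a monotone rescaling
  # of the 1-D distances, so neighbourhoods and labels must not change
  sp <- small_spec(seed = 16)
  ph <- generate_phantom(sp)
  icv <- ph$image
  icv$data <- array(as.numeric(ph$labels$data > 0), dim = dim(ph$labels$data))
  set.seed(2)
  f1 <- matrix(stats::rnorm(150, rep(c(30, 65, 100), each = 50), 3), ncol = 1)
  m1 <- structure(list(features = f1, classes = rep(1:3, each = 50),
                       k = 9L, tie_rule = ""), class = "knn_model")
  m2 <- m1; m2$features <- cbind(f1, f1)
  seg1 <- knn_segment(ph$image, m1, icv)
  seg2 <- knn_segment(list(ph$image, ph$image), m2, icv)
  expect_identical(seg1$data, seg2$data)
})

test_that("k larger than a class sample count is rejected at segmentation time", {
  ph <- generate_phantom(small_spec(seed = 9))
  icv <- ph$image
  icv$data <- array(1, dim = dim(ph$image$data))
  model <- structure(list(features = matrix(c(30, 65, 100), ncol = 1),
                          classes = 1:3, k = 5L, tie_rule = ""),
                     class = "knn_model")
  expect_error(knn_segment(ph$image, model, icv), "sample count")
})

test_that("volumes follow count times voxel volume and the sum identities hold exactly", {
  lab <- array(0L, dim = c(20, 20, 10))
  lab[1:10, 1:10, 1:10] <- 2L   # 1000 GM voxels
  lab[11:15, 1:10, 1:10] <- 1L  # 500 CSF
  lab[16:18, 1:10, 1:10] <- 3L  # 300 WM
  lv <- label_volume(lab, c(1, 1, 1))
  rec <- compute_volumes(lv)
  expect_equal(rec$gm_ml, 1.0)
  expect_equal(rec$csf_ml, 0.5)
  expect_equal(rec$wm_ml, 0.3)
  expect_identical(rec$icv_ml - (rec$csf_ml + rec$gm_ml + rec$wm_ml), 0)
  expect_identical(rec$brain_ml - (rec$gm_ml + rec$wm_ml), 0)
})

test_that("noise-free phantom volumes recover the analytic truth within 5% at 3 mm", {
  sp <- clean_spec(seed = 10)
  ph <- generate_phantom(sp)
  rec <- compute_volumes(ph$labels)
  truth <- phantom_true_volumes(sp)
  for (tis in c("csf_ml", "gm_ml", "wm_ml")) {
    expect_lt(abs(rec[[tis]] - truth[tis]) / truth[tis], 0.05, label = tis)
  }
})

test_that("fixed seeds make the whole segmentation stage bit-reproducible", {
  sp <- small_spec(seed = 11)
  ph <- generate_phantom(sp)
  atl <- small_atlases()
  s1 <- segment_examination(ph$image, atl, fast_reg(), seed = 2L,
                            nonrigid = FALSE)
  s2 <- segment_examination(ph$image, atl, fast_reg(), seed = 2L,
                            nonrigid = FALSE)
  expect_identical(s1$labels$data, s2$labels$data)
  expect_identical(s1$record, s2$record)
})
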