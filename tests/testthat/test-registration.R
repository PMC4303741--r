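test_that("mutual information reduces to entropy on identical images and is symmetric", {
  ph <- generate_phantom(small_spec(seed = 1))
  x <- ph$image
  expect_lt(abs(mutual_information(x, x) - volume_entropy(x)), 1e-9)
  sp2 <- small_spec(seed = 2); sp2$class_means <- sp2$class_means * 0.8
  y <- generate_phantom(sp2)$image
  expect_equal(mutual_information(x, y), mutual_information(y, x))
  expect_gte(mutual_information(x, y), 0)
})

test_that("permuting voxels destroys mutual information", {
  ph <- generate_phantom(small_spec(seed = 3))
  x <- ph$image
  set.seed(7)
  mis <- replicate(5, {
    y <- x
    y$data <- array(sample(x$data), dim = dim(x$data))
    mutual_information(x, y)
  })
  # MI of an independent pairing concentrates near 0 (finite-sample bias
  # only); bound by 3 sigma above the replicate mean
  expect_lt(mean(mis) + 3 * stats::sd(mis), 0.1 * volume_entropy(x))
  expect_lt(mean(mis), 0.05 * volume_entropy(x))
})

test_that("registering an image to itself returns (near) identity", {
  x <- generate_phantom(phantom_spec(seed = 4))$image
  reg <- affine_register(x, x, fast_reg())
  expect_true(reg$improved || reg$mi_final >= reg$mi_initial)
  expect_lt(max(abs(reg$transform$translation)), 0.1 * x$spacing[1])
  expect_lt(max(abs(reg$transform$matrix - diag(3))), 0.02)
})

test_that("a known translation is recovered within half a voxel", {
  base <- phantom_spec(seed = 5)
  atlas <- generate_phantom(base)$image
  sp <- base; sp$pose$translation <- c(6, 0, 0); sp$seed <- 55L
  subj <- generate_phantom(sp)$image
  reg <- affine_register(atlas, subj, precision_reg())
  t_rec <- as.numeric(mriharvest:::affine_points(reg$transform,
                                                 matrix(0, 1, 3)))
  expect_lt(max(abs(t_rec + c(6, 0, 0))), 0.5 * subj$spacing[1])
})

test_that("a known rotation is recovered within one degree", {
  base <- phantom_spec(seed = 5)
  atlas <- generate_phantom(base)$image
  sp <- base; sp$pose$rotation <- c(0, 0, 5); sp$seed <- 56L
  subj <- generate_phantom(sp)$image
  reg <- affine_register(atlas, subj, precision_reg())
  M <- reg$transform$matrix
  rec <- atan2(M[2, 1], M[1, 1]) * 180 / pi
  expect_lt(abs(rec + 5), 1)
})

test_that("final MI never falls below the initialization MI", {
  base <- phantom_spec(seed = 6)
  atlas <- generate_phantom(base)$image
  sp <- base; sp$pose$translation <- c(8, -8, 4); sp$seed <- 66L
  subj <- generate_phantom(sp)$image
  reg <- affine_register(atlas, subj, fast_reg())
  expect_gte(reg$mi_final, reg$mi_initial)
})

test_that("identity transform reproduces the input under apply_transform", {
  ph <- generate_phantom(small_spec(seed = 7))
  out <- apply_transform(ph$image, affine_transform(), ph$image, "linear")
  expect_equal(out$data, ph$image$data, tolerance = 1e-9)
  lab <- apply_transform(ph$labels, affine_transform(), ph$labels, "nearest")
  expect_identical(lab$data, ph$labels$data)
})

test_that("linear interpolation of label volumes is rejected", {
  ph <- generate_phantom(small_spec(seed = 8))
  expect_error(apply_transform(ph$labels, affine_transform(), ph$labels,
                               "linear"),
               "nearest")
})

test_that("resampled labels only take input label values", {
  ph <- generate_phantom(small_spec(seed = 9))
  tf <- affine_transform(translation = c(2.5, -1.3, 4.1))
  lab <- apply_transform(ph$labels, tf, ph$labels, "nearest")
  expect_true(all(lab$data %in% 0:3))
})

test_that("translate-then-inverse-translate keeps mask Dice at 3 mm voxels", {
  ph <- generate_phantom(phantom_spec(seed = 10))
  mask <- ph$image
  mask$data <- array(as.numeric(ph$labels$data > 0), dim = dim(ph$labels$data))
  tf <- affine_transform(translation = c(4.2, -2.7, 1.9))
  fwd <- apply_transform(mask, tf, mask, "nearest")
  back <- apply_transform(fwd, invert_affine(tf), mask, "nearest")
  expect_gte(mriharvest:::dice_overlap(back$data != 0, mask$data != 0), 0.95)
})

test_that("non-rigid refinement of identical images keeps displacements at zero", {
  x <- generate_phantom(phantom_spec(seed = 11))$image
  nr <- nonrigid_register(x, x, affine_transform(), reg_config())
  expect_lt(max(abs(nr$field$disp)), 0.25 * x$spacing[1])
})

test_that("non-rigid refinement does not reduce label overlap after affine and respects the cap", {
  base <- phantom_spec(seed = 12)
  atlas <- generate_phantom(base)
  sp <- base; sp$pose$scale <- c(1.05, 0.95, 1.04); sp$seed <- 12L
  subj <- generate_phantom(sp)
  ar <- affine_register(atlas$image, subj$image,
                        reg_config(estimate_scale = FALSE))
  nr <- nonrigid_register(atlas$image, subj$image, ar$transform, reg_config())
  la <- apply_transform(atlas$labels, ar$transform, subj$image, "nearest")
  ln <- apply_transform(atlas$labels, nr$field, subj$image, "nearest")
  truth <- subj$labels$data > 0
  expect_gte(mriharvest:::dice_overlap(ln$data > 0, truth),
             mriharvest:::dice_overlap(la$data > 0, truth))
  mags <- sqrt(apply(nr$field$disp^2, 1:3, sum))
  expect_lte(max(mags), reg_config()$cap_mm)
  expect_gte(nr$mi_final, nr$mi_initial)
})

test_that("transforms serialize to text and back", {
  tf <- affine_transform(mriharvest:::rotation_matrix(c(3, -2, 7)),
                         c(1.5, -2.5, 3.5), c(10, 20, 30))
  p <- withr::local_tempfile(fileext = ".yaml")
  write_transform(tf, p)
  back <- read_transform(p)
  expect_equal(back$matrix, tf$matrix, tolerance = 1e-12)
  expect_equal(back$translation, tf$translation)
  # composing with the inverse yields identity
  comp <- invert_affine(tf)
  pts <- matrix(rnorm(30), 10, 3)
  round_trip <- mriharvest:::affine_points(comp,
                                           mriharvest:::affine_points(tf, pts))
  expect_lt(max(abs(round_trip - pts)), 1e-6)
})

test_that("registration is deterministic given seed and config", {
  base <- phantom_spec(seed = 13)
  atlas <- generate_phantom(base)$image
  sp <- base; sp$pose$translation <- c(5, 3, -4); sp$seed <- 77L
  subj <- generate_phantom(sp)$image
  r1 <- affine_register(atlas, subj, fast_reg())
  r2 <- affine_register(atlas, subj, fast_reg())
  expect_identical(r1$transform, r2$transform)
})
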