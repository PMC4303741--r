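hdr <- function(seq = "GR", tr = NA, te = NA, ti = 0, flip = NA, b = NA,
                temporal = 1L, ...) {
  header_record(scanning_sequence = seq, repetition_time = tr, echo_time = te,
                inversion_time = ti, flip_angle = flip,
                diffusion_b_value = b, n_temporal_positions = temporal, ...)
}

test_that("the decision table classifies the catalogued clinical parameter combinations", {
  cases <- list(
    # dementia protocol: inversion-prepared gradient echo
    list(hdr("GR", 7.9, 3.1, 450, 12), "T1w"),
    # MS protocol: long-TR short-TE spin echo
    list(hdr("SE", 2500, 15.0, 0, 90), "PDw"),
    # short-TR short-TE spin echo
    list(hdr("SE", 565, 12.0, 0, 90), "T1w"),
    list(hdr("SE", 437, 10.1, 0, 90), "T1w"),
    # spoiled gradient echo without inversion
    list(hdr("GR", 17.1, 7.6, 0, 30), "T1w"),
    list(hdr("GR", 14.0, 4.8, 450, 23), "T1w"),
    list(hdr("SE", 513, 12.7, 0, 90), "T1w"),
    list(hdr("SE", 2480, 15.0, 0, 90), "PDw"),
    # long-TR long-TE spin echo
    list(hdr("SE", 3000, 100, 0, 90), "T2w"),
    # diffusion and functional
    list(hdr("EP", 3000, 80, 0, 90, b = 1000), "DWI"),
    list(hdr("EP", 2000, 30, 0, 77, temporal = 120L), "fMRI"))
  for (cs in cases) {
    res <- classify_sequence(cs[[1]])
    expect_equal(res$class, cs[[2]],
                 info = sprintf("TR %s TE %s", cs[[1]]$repetition_time,
                                cs[[1]]$echo_time))
    expect_true(nzchar(res$rule_fired))
  }
})

test_that("missing elements yield unknown, never an error", {
  expect_equal(classify_sequence(hdr("SE", 2500, NA))$class, "unknown")
  expect_equal(classify_sequence(hdr("unknown"))$class, "unknown")
  res <- classify_sequence(hdr("GR", NA, NA, 0, NA))
  expect_equal(res$class, "unknown")
  expect_equal(res$rule_fired, "no rule fired")
})

test_that("the highest-resolution series wins, with matrix and series-number tie-breaks", {
  h1 <- hdr("GR", 7.9, 3.1, 450, 12, pixel_spacing = c(1, 1),
            slice_thickness = 1, series_number = 4L)          # 1.0 mm3
  h2 <- hdr("GR", 7.9, 3.1, 450, 12, pixel_spacing = c(1.5, 1.5),
            slice_thickness = 1.5, series_number = 2L)        # 3.375 mm3
  sel <- select_best_series(list(h1, h2), wanted = "T1w")
  expect_equal(sel$index, 1L)
  expect_equal(sel$voxel_volume_mm3, 1.0)
  # single candidate selects itself
  expect_equal(select_best_series(list(h2), wanted = "T1w")$index, 1L)
  # exact tie on voxel volume and matrix: lower series number
  h3 <- h1; h3$series_number <- 9L
  sel3 <- select_best_series(list(h3, h1), wanted = "T1w")
  expect_equal(sel3$series_number, 4L)
  # larger matrix wins at equal voxel volume
  h4 <- hdr("GR", 7.9, 3.1, 450, 12, pixel_spacing = c(1, 1),
            slice_thickness = 1, matrix_size = c(256L, 256L),
            series_number = 7L)
  sel4 <- select_best_series(list(h1, h4), wanted = "T1w")
  expect_equal(sel4$index, 2L)
  # absent class reported absent
  expect_true(is.na(select_best_series(list(h1), wanted = "T2w")$index))
})

test_that("contrast agent excludes, empty and whitespace-only keep", {
  expect_true(check_contrast(header_record(contrast_agent = "GADOLINIUM")))
  expect_false(check_contrast(header_record(contrast_agent = "")))
  expect_false(check_contrast(header_record(contrast_agent = "   ")))
})

test_that("boundary-plane fractions drive the field-of-view rule with a strict 20% threshold", {
  # constructed mask on a 20 x 20 x 10 grid: identity transform, no
  # registration involved
  blank <- image_volume(array(0, dim = c(20, 20, 10)), c(3, 3, 3))
  interior <- blank
  interior$data[8:13, 8:13, 4:7] <- 1
  dec <- check_fov(blank, interior, blank, transform = affine_transform())
  expect_true(dec$passed)
  expect_equal(unname(dec$metrics$boundary_brain_fractions),
               rep(0, 6))
  # top plane fraction 0.25 -> exclude
  top25 <- blank
  top25$data[1:10, 1:10, 10] <- 1   # 100 of 400 = 0.25
  dec2 <- check_fov(blank, top25, blank, transform = affine_transform())
  expect_false(dec2$passed)
  expect_equal(dec2$reasons, "incomplete_fov")
  expect_equal(unname(dec2$metrics$boundary_brain_fractions["z_high"]), 0.25)
  # exactly 0.20 passes (strict inequality)
  top20 <- blank
  top20$data[1:8, 1:10, 10] <- 1    # 80 of 400 = 0.20
  dec3 <- check_fov(blank, top20, blank, transform = affine_transform())
  expect_true(dec3$passed)
})

test_that("a cropped phantom is excluded by the registered-mask FOV check and the intact one passes", {
  ph <- generate_phantom(phantom_spec(seed = 14))
  atl <- default_atlases()
  a1 <- atl$atlases[[1]]
  dec_ok <- check_fov(ph$image, a1$cerebrum, a1$intensity, fast_reg())
  expect_true(dec_ok$passed)
  cropped <- crop_top(ph$image, 20)  # brain now reaches the top plane
  dec_bad <- check_fov(cropped, a1$cerebrum, a1$intensity, fast_reg())
  expect_false(dec_bad$passed)
  expect_true("incomplete_fov" %in% dec_bad$reasons)
  expect_gt(max(dec_bad$metrics$boundary_brain_fractions), 0.20)
})

test_that("QA never mutates pixel data", {
  ph <- generate_phantom(small_spec(seed = 15))
  before <- ph$image$data
  invisible(classify_sequence(ph$header))
  invisible(check_contrast(ph$header))
  blank <- ph$image
  invisible(check_fov(ph$image, blank, blank, transform = affine_transform()))
  expect_identical(ph$image$data, before)
})
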