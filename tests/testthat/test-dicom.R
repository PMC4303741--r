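test_that("a written series round-trips to the same pixels, spacing and header", {
  ph <- generate_phantom(small_spec(seed = 5))
  dir <- withr::local_tempdir()
  paths <- write_dicom_series(ph$image, ph$header, dir)
  expect_length(paths, dim(ph$image$data)[3])
  sl <- read_series(dir)
  expect_length(sl, 1)
  expect_true(sl[[1]]$ok)
  v <- sl[[1]]$volume
  expect_identical(v$data, array(as.numeric(round(ph$image$data)),
                                 dim = dim(ph$image$data)))
  expect_equal(v$spacing, ph$image$spacing, tolerance = 1e-4)
  expect_equal(v$origin, ph$image$origin, tolerance = 1e-4)
  h <- sl[[1]]$header
  expect_equal(h$repetition_time, ph$header$repetition_time)
  expect_equal(h$echo_time, ph$header$echo_time)
  expect_equal(h$inversion_time, ph$header$inversion_time)
  expect_equal(h$scanning_sequence, ph$header$scanning_sequence)
  expect_equal(h$identity$patient_name, ph$header$identity$patient_name)
  expect_equal(h$identity$birth_date, ph$header$identity$birth_date)
})

test_that("private tags survive writing and are parsed back", {
  ph <- generate_phantom(small_spec(seed = 6))
  ph$header$private_tags <- list(list(group = 0x0019, element = 0x1010,
                                      payload = "SECRET PAYLOAD"))
  dir <- withr::local_tempdir()
  write_dicom_series(ph$image, ph$header, dir)
  h <- read_series(dir)[[1]]$header
  expect_length(h$private_tags, 1)
  expect_equal(h$private_tags[[1]]$payload, "SECRET PAYLOAD")
  expect_equal(h$private_tags[[1]]$group, 0x0019)
})

test_that("slice sorting is invariant to on-disk file order", {
  ph <- generate_phantom(small_spec(seed = 7))
  dir <- withr::local_tempdir()
  paths <- write_dicom_series(ph$image, ph$header, dir)
  # shuffle by renaming so the directory listing order changes
  set.seed(42)
  newnames <- file.path(dir, sprintf("f%04d.dcm", sample(length(paths))))
  file.rename(paths, newnames)
  v <- read_series(dir)[[1]]$volume
  expect_identical(v$data, array(as.numeric(round(ph$image$data)),
                                 dim = dim(ph$image$data)))
  expect_equal(v$origin, ph$image$origin, tolerance = 1e-4)
})

test_that("two interleaved series in one directory yield two volumes", {
  ph1 <- generate_phantom(small_spec(seed = 8))
  ph2 <- generate_phantom(small_spec(seed = 9))
  ph2$header$series_number <- 5L
  ph2$header$series_description <- "PD"
  dir <- withr::local_tempdir()
  write_dicom_series(ph1$image, ph1$header, dir)
  write_dicom_series(ph2$image, ph2$header, dir)
  sl <- read_series(dir)
  expect_length(sl, 2)
  nums <- sort(vapply(sl, function(s) s$header$series_number, integer(1)))
  expect_equal(nums, c(2L, 5L))
})

test_that("a missing mid-stack slice flags non-uniform slice spacing", {
  ph <- generate_phantom(small_spec(seed = 10))
  dir <- withr::local_tempdir()
  paths <- write_dicom_series(ph$image, ph$header, dir)
  file.remove(paths[10])
  s <- read_series(dir)[[1]]
  expect_false(s$ok)
  expect_true(any(grepl("non-uniform slice spacing", s$diagnostics)))
})

test_that("a series with mixed echo times is flagged, not guessed at", {
  ph <- generate_phantom(small_spec(seed = 13))
  dir <- withr::local_tempdir()
  paths <- write_dicom_series(ph$image, ph$header, dir)
  parsed <- lapply(paths, mriharvest:::dcm_parse_file)
  parsed[[5]][["0018,0081"]]$value <- "80"
  s <- mriharvest:::assemble_series(parsed)
  expect_false(s$ok)
  expect_true(any(grepl("mixed echo times", s$diagnostics)))
})

test_that("an empty directory errors, unreadable files are skipped", {
  dir <- withr::local_tempdir()
  expect_error(read_series(dir), "no readable DICOM")
  writeLines("not dicom", file.path(dir, "junk.txt"))
  expect_error(read_series(dir), "no readable DICOM")
})

test_that("pydicom independently parses the written files", {
  ph <- generate_phantom(small_spec(seed = 11))
  dir <- withr::local_tempdir()
  write_dicom_series(ph$image, ph$header, dir)
  script <- file.path(dir, "check.py")
  writeLines(c(
    "import sys, glob, pydicom",
    sprintf("fs = sorted(glob.glob('%s/*.dcm'))", dir),
    "ds = pydicom.dcmread(fs[0])",
    "print(ds.PatientName)",
    "print(ds.RepetitionTime)",
    "print(ds.Rows, ds.Columns)",
    "print(int(ds.pixel_array.sum()))"), script)
  out <- system2("python", script, stdout = TRUE)
  expect_equal(out[1], ph$header$identity$patient_name)
  expect_equal(as.numeric(out[2]), ph$header$repetition_time)
  expect_equal(out[3], "32 32")
  expect_equal(as.numeric(out[4]), sum(round(ph$image$data[, , 1])))
})

test_that("voxel volume is the product of the spacings", {
  expect_equal(voxel_volume(c(1, 1, 1)), 1.0)
  expect_equal(voxel_volume(c(0.8, 0.8, 1.0)), 0.64)
  expect_equal(voxel_volume(c(0.5, 0.5, 5.0)), 1.25)
  h <- header_record(pixel_spacing = c(0.8, 0.8), slice_thickness = 1.0)
  expect_equal(voxel_volume(h), 0.64)
  h2 <- header_record(pixel_spacing = c(0.5, 0.5), slice_thickness = 4,
                      spacing_between_slices = 5)
  expect_equal(voxel_volume(h2), 1.25)  # gap takes precedence over thickness
  expect_error(voxel_volume(c(1, NA, 1)), "spacing")
})

test_that("NIfTI round trip preserves data and LPS geometry", {
  ph <- generate_phantom(small_spec(seed = 12))
  path <- withr::local_tempfile(fileext = ".nii.gz")
  write_volume(ph$image, path)
  back <- read_volume(path)
  expect_equal(back$data, ph$image$data, tolerance = 1e-6)
  expect_equal(back$spacing, ph$image$spacing, tolerance = 1e-4)
  expect_equal(back$origin, ph$image$origin, tolerance = 1e-4)
  lpath <- withr::local_tempfile(fileext = ".nii.gz")
  write_volume(ph$labels, lpath)
  lback <- read_volume(lpath, labels = TRUE)
  expect_identical(lback$data, ph$labels$data)
})
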