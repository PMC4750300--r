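test_that("stack write/read round-trips voxels exactly with no rescaling", {
  set.seed(11)
  vox <- array(sample(0:255, 3 * 6 * 5, replace = TRUE), c(3, 6, 5))
  st <- zstack(vox, dxy = 0.1, dz = 0.25)
  path <- withr::local_tempfile(fileext = ".tif")
  write_stack(st, path)
  back <- read_stack(path, dxy = 0.1, dz = 0.25)
  expect_identical(back$voxels, array(as.integer(vox), dim(vox)))
  expect_equal(back$dxy, 0.1)
  expect_equal(n_slices(back), 3L)
})

test_that("OME metadata supplies calibration and overrides win", {
  path <- withr::local_tempfile(fileext = ".ome.tif")
  write_ome_fixture(path, nz = 12, dxy = 0.1, dz = 0.25)
  st <- suppressWarnings(read_stack(path))
  expect_equal(st$dz, 0.25)
  expect_equal(st$dxy, 0.1)
  expect_equal(n_slices(st), 12L)
  # explicit override beats the file metadata
  st2 <- suppressWarnings(read_stack(path, dz = 0.5))
  expect_equal(st2$dz, 0.5)
  expect_equal(st2$dxy, 0.1)
})

test_that("single-page TIFF reads as a valid 1-slice stack", {
  st <- zstack(array(7L, c(1, 4, 4)), dxy = 0.2, dz = 1)
  path <- withr::local_tempfile(fileext = ".tif")
  write_stack(st, path)
  back <- read_stack(path, dxy = 0.2, dz = 1)
  expect_equal(n_slices(back), 1L)
  expect_true(all(back$voxels == 7L))
})

test_that("read_stack refuses missing calibration and multi-channel input", {
  st <- zstack(array(0L, c(2, 4, 4)), dxy = 0.1, dz = 0.25)
  path <- withr::local_tempfile(fileext = ".tif")
  write_stack(st, path)
  expect_error(read_stack(path), "calibration")
  expect_error(read_stack(path, dxy = 0.1), "axial")
  # RGB page = multi-channel
  rgb <- withr::local_tempfile(fileext = ".tif")
  tiff::writeTIFF(array(0.5, c(4, 4, 3)), rgb, bits.per.sample = 8L)
  expect_error(read_stack(rgb, dxy = 0.1, dz = 0.25), "multi-channel")
  expect_error(read_stack("/nonexistent/file.tif", dxy = 1, dz = 1), "not found")
})

test_that("zstack validates calibration and intensity range", {
  expect_error(zstack(array(0, c(1, 2, 2)), dxy = 0, dz = 1), "dxy")
  expect_error(zstack(array(0, c(1, 2, 2)), dxy = 1, dz = -1), "dz")
  expect_error(zstack(array(300, c(1, 2, 2)), dxy = 1, dz = 1), "\\[0, 255\\]")
})

test_that("interleaved annotation rows group into per-cilium polylines", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c(
    "cilium_id,point_index,x,y,z_first,z_last",
    "a,0,1.5,2.0,0,3",
    "b,0,10,10,2,8",
    "a,2,4.5,6.0,0,3",
    "b,1,14,13,2,8",
    "a,1,3.0,4.0,0,3",
    "b,2,18,16,2,8"
  ), path)
  ann <- read_annotations(path)
  # hand-grouped parse of the same 6 rows
  a <- ann[ann$cilium_id == "a", ]
  b <- ann[ann$cilium_id == "b", ]
  expect_equal(nrow(ann), 6L)
  expect_equal(a$x, c(1.5, 3.0, 4.5))
  expect_equal(a$point_index, 0:2)
  expect_equal(b$y, c(10, 13, 16))
  expect_equal(unique(a$z_last), 3)
  expect_equal(unique(b$z_first), 2)
})

test_that("annotation invariants are enforced", {
  bad_span <- make_annotation("c", c(0, 1), c(0, 1), z_first = 3, z_last = 2)
  expect_error(validate_annotations(bad_span), "z_first")
  one_point <- make_annotation("c", 1, 1, 0, 0)
  expect_error(validate_annotations(one_point), "2 points")
  dup <- make_annotation("c", c(1, 1, 2), c(2, 2, 3), 0, 1)
  expect_error(validate_annotations(dup), "distinct")
  out_of_stack <- make_annotation("c", c(0, 1), c(0, 1), 0, 9)
  expect_error(validate_annotations(out_of_stack, n_slices = 5), "slice count")
  nonnum <- tibble::tibble(cilium_id = "c", point_index = 0:1,
    x = c("a", "b"), y = c(0, 1), z_first = 0, z_last = 1)
  expect_error(validate_annotations(nonnum), "numeric")
})

test_that("annotation write/read round-trip preserves coordinates", {
  ann <- make_annotation("c1", c(0.123456789, 10.987654321),
    c(5.5, 6.25), 2, 9)
  path <- withr::local_tempfile(fileext = ".csv")
  write_annotations(ann, path, header = c("seed=1"))
  back <- read_annotations(path)
  expect_equal(back$x, ann$x, tolerance = 1e-12)
  expect_identical(as.integer(back$z_first), rep(2L, 2))
  expect_identical(as.integer(back$z_last), rep(9L, 2))
})

test_that("measurement CSV round-trips, including the empty case", {
  recs <- tibble::tibble(
    cilium_id = c("a", "a", "b"), method = c("MIP", "PYT", "DAAS"),
    replicate = c(1L, 1L, 2L),
    length_um = c(3.14159265, 2.71828183, 1.23456789),
    classification = c("FLAT", "FLAT", "ANGLED")
  )
  path <- withr::local_tempfile(fileext = ".csv")
  write_measurements(recs, path)
  back <- read_measurements(path)
  expect_equal(as.data.frame(back), as.data.frame(recs), tolerance = 1e-12)

  empty <- recs[0, ]
  path2 <- withr::local_tempfile(fileext = ".csv")
  write_measurements(empty, path2)
  lines <- readLines(path2)
  expect_equal(length(lines), 1L) # header only
  expect_match(lines[1], "cilium_id")
  expect_error(write_measurements(recs[, 1:3], path), "lack columns")
})
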