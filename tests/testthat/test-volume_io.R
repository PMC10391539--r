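test_that("NIfTI round trip preserves voxels, spacing and intensity flag", {
  dir <- withr::local_tempdir()
  v <- ct_volume(array(rnorm(4 * 6 * 5, 0, 200), c(4, 6, 5)), c(5, 1, 1), "HU")
  p <- file.path(dir, "ct.nii.gz")
  write_volume(v, p)
  v2 <- read_volume(p)
  expect_equal(v2$voxels, v$voxels, tolerance = 1e-6)
  expect_equal(v2$spacing, c(5, 1, 1))
  expect_equal(v2$intensity_space, "HU")

  # header spacing passthrough
  v3 <- ct_volume(array(0, c(3, 4, 4)), c(5.0, 1.0, 1.0))
  p3 <- file.path(dir, "sp.nii.gz")
  write_volume(v3, p3)
  expect_equal(read_volume(p3)$spacing, c(5.0, 1.0, 1.0))

  # overwrite wins
  v4 <- ct_volume(array(7, c(3, 4, 4)), c(5, 1, 1))
  write_volume(v4, p3)
  expect_equal(read_volume(p3)$voxels[1, 1, 1], 7)

  # normalized volumes keep their flag through the sidecar
  vn <- ct_volume(array(runif(3 * 4 * 4, 0, 255), c(3, 4, 4)), c(5, 1, 1),
                  "normalized_0_255")
  pn <- file.path(dir, "win.nii.gz")
  write_volume(vn, pn)
  expect_equal(read_volume(pn)$intensity_space, "normalized_0_255")
})

test_that("PNG slice stacks read with sidecar spacing", {
  dir <- withr::local_tempdir()
  set.seed(1)
  for (i in 1:10)
    png::writePNG(matrix(runif(256 * 256), 256, 256),
                  file.path(dir, sprintf("slice_%02d.png", i)))
  jsonlite::write_json(list(spacing = c(5, 1.5, 1.5)),
                       file.path(dir, "volume.json"), auto_unbox = TRUE)
  v <- read_volume(dir)
  expect_equal(dim(v$voxels), c(10L, 256L, 256L))
  expect_equal(v$spacing, c(5, 1.5, 1.5))
  expect_equal(v$intensity_space, "normalized_0_255")
  expect_true(all(v$voxels >= 0 & v$voxels <= 255))

  # inconsistent slice shapes are rejected
  png::writePNG(matrix(0, 64, 64), file.path(dir, "slice_99.png"))
  expect_error(read_volume(dir), class = "ts_format_error")
})

test_that("labelmap round trip and validation errors", {
  dir <- withr::local_tempdir()
  lt <- c(a = 1L, b = 2L, c = 5L)
  lab <- array(sample(c(0L, 1L, 2L, 5L), 3 * 8 * 8, TRUE), c(3, 8, 8))
  lv <- label_volume(lab, c(5, 2, 2), lt)
  p <- file.path(dir, "labels.nii.gz")
  write_labelmap(lv, p)
  lv2 <- read_labelmap(p)
  expect_identical(lv2$labels, lv$labels)
  expect_equal(lv2$spacing, c(5, 2, 2))
  expect_equal(lv2$label_table, lt)

  # a label value missing from the table is a validation error
  expect_error(label_volume(array(2L, c(2, 2, 2)), c(1, 1, 1), c(x = 1L)),
               class = "ts_validation_error")
  # non-integer voxels are a format error
  expect_error(label_volume(array(0.5, c(2, 2, 2)), c(1, 1, 1)),
               class = "ts_format_error")
})

test_that("missing files and malformed volumes raise classed errors", {
  expect_error(read_volume(file.path(tempdir(), "nope.nii.gz")),
               class = "ts_not_found_error")
  expect_error(ct_volume(array(0, c(2, 2)), c(1, 1, 1)), class = "ts_format_error")
  expect_error(ct_volume(array(0, c(2, 2, 2)), c(1, -1, 1)), class = "ts_format_error")
  dir <- withr::local_tempdir()
  # 2-D NIfTI is rejected
  RNifti::writeNifti(RNifti::asNifti(matrix(0, 4, 4)), file.path(dir, "flat.nii.gz"))
  expect_error(read_volume(file.path(dir, "flat.nii.gz")), class = "ts_format_error")
})
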