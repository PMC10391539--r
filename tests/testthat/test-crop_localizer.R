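test_that("centroid is the mean foreground coordinate", {
  m <- matrix(FALSE, 20, 20)
  m[10, 10] <- TRUE; m[10, 12] <- TRUE
  expect_equal(centroid(m), c(row = 10, col = 11))
  m2 <- matrix(FALSE, 20, 20); m2[5, 7] <- TRUE
  expect_equal(centroid(m2), c(row = 5, col = 7))
  m3 <- matrix(FALSE, 20, 20); m3[2:6, 3:7] <- TRUE   # filled 5x5, top-left (2,3)
  expect_equal(centroid(m3), c(row = 4, col = 5))
  expect_error(centroid(matrix(FALSE, 3, 3)), class = "ts_empty_mask_error")
})

test_that("inference center shifts 5 mm left and 5 mm up in pixels", {
  sp <- crop_spec()
  expect_equal(inference_center(c(200, 260), c(1, 1), sp),
               c(row = 195, col = 255))
  expect_equal(inference_center(c(200, 260), c(2.5, 2.5), sp),
               c(row = 198, col = 258))    # 5 mm / 2.5 mm per px = 2 px
  sp0 <- crop_spec(shift_left_mm = 0, shift_up_mm = 0)
  expect_equal(inference_center(c(200, 260), c(1, 1), sp0),
               c(row = 200, col = 260))
})

test_that("training jitter has bounded magnitude and uniform-magnitude law", {
  sp0 <- crop_spec(jitter_range_mm = c(0, 0))
  set.seed(1)
  expect_equal(training_center(c(100, 100), c(1, 1), sp0),
               inference_center(c(100, 100), c(1, 1), sp0))
  sp <- crop_spec()
  set.seed(5)
  a <- training_center(c(100, 100), c(1, 1), sp)
  set.seed(5)
  b <- training_center(c(100, 100), c(1, 1), sp)
  expect_identical(a, b)
  base <- inference_center(c(100, 100), c(1.5, 1.5), sp)
  set.seed(6)
  mags <- replicate(2000, {
    ctr <- training_center(c(100, 100), c(1.5, 1.5), sp)
    sqrt(((ctr[1] - base[1]) * 1.5)^2 + ((ctr[2] - base[2]) * 1.5)^2)
  })
  expect_true(all(mags <= 4 + 1e-9))
  expect_gt(suppressWarnings(stats::ks.test(mags, "punif", 0, 4)$p.value), 0.01)
})

test_that("crop extraction windows are anchored at round(center) - size/2", {
  img <- matrix(seq_len(256 * 256), 256, 256)
  got <- extract_crop(img, c(95, 95), crop_spec())
  expect_equal(unname(got$region$origin), c(63L, 63L))
  expect_equal(sum(got$region$pad), 0)
  expect_equal(dim(got$crop), c(64L, 64L))
  expect_equal(got$crop[1, 1], img[63, 63])
  # near the border the window is clipped, padded, and recorded
  got2 <- extract_crop(img, c(10, 10), crop_spec())
  expect_equal(dim(got2$crop), c(64L, 64L))
  expect_equal(unname(got2$region$pad[c("top", "left")]), c(23L, 23L))
  expect_true(all(got2$crop[1:23, ] == 0))
})

test_that("paste_crop inverts extract_crop on the in-bounds region", {
  set.seed(2)
  img <- matrix(rnorm(128 * 128), 128, 128)
  for (ctr in list(c(64, 64), c(5, 120), c(127, 3))) {
    got <- extract_crop(img, ctr, crop_spec())
    back <- paste_crop(img, got$crop, got$region)
    expect_equal(back, img)
  }
})

test_that("fallback centers step 1 mm in the configured direction", {
  sp <- crop_spec()
  expect_equal(fallback_center(c(100, 100), c(1, 1), sp), c(row = 100, col = 99))
  ctr <- c(100, 100)
  for (i in 1:3) ctr <- fallback_center(ctr, c(1, 1), sp)
  expect_equal(unname(ctr), c(100, 97))
  sp0 <- crop_spec(fallback_step_mm = 0)
  expect_equal(fallback_center(c(100, 100), c(1, 1), sp0), c(row = 100, col = 100))
  spd <- crop_spec(fallback_direction = "down")
  expect_equal(fallback_center(c(100, 100), c(2, 2), spd), c(row = 100.5, col = 100))
})

test_that("paste_esophagus gives stage 2 exclusive ownership of the esophagus", {
  lt <- default_label_table()
  lab <- array(0L, c(2, 16, 16))
  lab[1, 3, 3] <- lt[["trachea"]]
  lab[1, 5, 5] <- lt[["esophagus"]]   # stage-1 esophagus inside the crop
  lab[2, 9, 9] <- lt[["esophagus"]]   # stage-1 esophagus outside any crop
  lab[1, 4, 4] <- lt[["heart"]]
  lv <- label_volume(lab, c(5, 1, 1), lt)
  spec <- crop_spec(crop_size = 8L)
  crop <- matrix(0, 8, 8)
  crop[2, 2] <- 1   # overlaps stage-1 trachea at (3,3) with origin (2,2)
  crop[6, 6] <- 1   # lands on background at (7,7)
  region <- structure(list(slice_index = 1L, origin = c(row = 2L, col = 2L),
                           size = 8L, pad = c(top = 0L, bottom = 0L, left = 0L, right = 0L)),
                      class = "crop_region")
  out <- paste_esophagus(lv, list(crop), list(region))
  expect_equal(out$labels[1, 3, 3], lt[["trachea"]])      # organ labels win
  expect_equal(out$labels[1, 7, 7], lt[["esophagus"]])    # background becomes esophagus
  expect_equal(out$labels[1, 5, 5], 0L)                   # stage-1 esophagus erased
  expect_equal(out$labels[2, 9, 9], 0L)                   # removed outside crops too
  expect_equal(out$labels[1, 4, 4], lt[["heart"]])
  # all non-esophagus labels bitwise unchanged
  keep <- !(lv$labels %in% c(0L, lt[["esophagus"]]))
  expect_identical(out$labels[keep], lv$labels[keep])
  # an all-background crop leaves no esophagus inside the crop
  out0 <- paste_esophagus(lv, list(matrix(0, 8, 8)), list(region))
  expect_equal(sum(out0$labels == lt[["esophagus"]]), 0L)
  bad <- region; bad$slice_index <- 9L
  expect_error(paste_esophagus(lv, list(crop), list(bad)),
               class = "ts_validation_error")
})

test_that("crop spec validates its geometry", {
  expect_error(crop_spec(crop_size = 7), class = "ts_config_error")
  expect_error(crop_spec(crop_size = 4), class = "ts_config_error")
  expect_error(crop_spec(jitter_range_mm = c(4, 0)), class = "ts_config_error")
  expect_error(crop_spec(shift_left_mm = -1), class = "ts_config_error")
})
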