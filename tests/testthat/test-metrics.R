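sp511 <- c(5, 1, 1)

test_that("dsc counts voxel overlap", {
  a <- array(FALSE, c(1, 8, 8)); a[1, , ] <- TRUE   # not used below; reset
  a <- array(FALSE, c(1, 8, 8)); a[1, 1:8, 1:8] <- TRUE
  expect_equal(dsc(a, a), 1)
  b <- array(FALSE, c(1, 8, 8))
  expect_equal(dsc(b, b), 1)                        # both empty by convention
  b[1, 1, 1] <- TRUE
  expect_equal(dsc(b, array(FALSE, c(1, 8, 8))), 0) # one empty
  # 8x8 square against itself shifted 4 columns: |a|=|b|=64, overlap 32
  sq <- array(FALSE, c(1, 8, 16)); sq[1, , 1:8] <- TRUE
  sh <- array(FALSE, c(1, 8, 16)); sh[1, , 5:12] <- TRUE
  expect_equal(dsc(sq, sh), 0.5)
  expect_error(dsc(sq, array(FALSE, c(1, 8, 8))), class = "ts_validation_error")
})

test_that("surface extraction uses 6-connectivity with out-of-volume background", {
  one <- array(FALSE, c(3, 3, 3)); one[2, 2, 2] <- TRUE
  expect_equal(unname(extract_surface(one)[1, ]), c(2L, 2L, 2L))
  cube <- array(FALSE, c(5, 5, 5)); cube[2:4, 2:4, 2:4] <- TRUE
  expect_equal(nrow(extract_surface(cube)), 26L)    # all but the center
  full <- array(TRUE, c(3, 4, 5))
  inner <- 1 * 2 * 3                                # interior voxels
  expect_equal(nrow(extract_surface(full)), 3 * 4 * 5 - inner)
  expect_error(extract_surface(array(FALSE, c(2, 2, 2))),
               class = "ts_empty_mask_error")
})

test_that("directed distances honor anisotropic spacing", {
  a <- array(FALSE, c(3, 5, 7)); a[2, 3, 2] <- TRUE
  b <- array(FALSE, c(3, 5, 7)); b[2, 3, 5] <- TRUE
  expect_equal(directed_distances(a, b, c(5, 1, 1)), 3)   # 3 cols at 1 mm
  c1 <- array(FALSE, c(3, 5, 7)); c1[3, 3, 2] <- TRUE
  expect_equal(directed_distances(a, c1, c(5, 1, 1)), 5)  # 1 slice at 5 mm
  expect_equal(directed_distances(a, a, c(5, 1, 1)), 0)
  expect_error(directed_distances(a, array(FALSE, c(3, 5, 7)), sp511),
               class = "ts_empty_mask_error")
})

test_that("hd95 and asd match hand-computable cases", {
  a <- array(FALSE, c(3, 9, 9)); a[2, 4:6, 4:6] <- TRUE
  expect_equal(hd95(a, a, sp511), 0)
  expect_equal(asd(a, a, sp511), 0)
  s1 <- array(FALSE, c(1, 3, 9)); s1[1, 2, 2] <- TRUE
  s2 <- array(FALSE, c(1, 3, 9)); s2[1, 2, 7] <- TRUE
  expect_equal(hd95(s1, s2, c(5, 1, 1)), 5)   # singleton percentile is the distance
  expect_equal(asd(s1, s2, c(5, 1, 1)), 5)
  s3 <- array(FALSE, c(1, 3, 9)); s3[1, 2, 5] <- TRUE
  expect_equal(asd(s1, s3, c(5, 1, 1)), 3)
})

test_that("hd95 on a displaced line endpoint matches the brute-force oracle", {
  a <- array(FALSE, c(1, 12, 21)); a[1, 2, 1:21] <- TRUE
  b <- a; b[1, 2, 21] <- FALSE; b[1, 12, 21] <- TRUE  # endpoint 10 mm lateral
  o <- bf_metrics(a, b, c(5, 1, 1))
  expect_equal(hd95(a, b, c(5, 1, 1)), o$hd95, tolerance = 1e-12)
  expect_equal(asd(a, b, c(5, 1, 1)), o$asd, tolerance = 1e-12)
})

test_that("asd on concentric squares matches the brute-force oracle", {
  a <- array(FALSE, c(1, 15, 15)); a[1, 3:13, 3:13] <- TRUE   # 11x11
  b <- array(FALSE, c(1, 15, 15)); b[1, 5:11, 5:11] <- TRUE   # 7x7
  o <- bf_metrics(a, b, c(5, 1, 1))
  expect_equal(asd(a, b, c(5, 1, 1)), o$asd, tolerance = 1e-12)
  expect_equal(hd95(a, b, c(5, 1, 1)), o$hd95, tolerance = 1e-12)
})

test_that("metrics are symmetric, translation-equivariant and bounded by HD", {
  set.seed(42)
  for (k in 1:20) {
    dims <- c(sample(3:10, 1), sample(3:12, 1), sample(3:12, 1))
    sp <- c(runif(1, 1, 5), runif(1, 0.5, 2), runif(1, 0.5, 2))
    a <- blob_mask(dims); b <- blob_mask(dims)
    expect_equal(dsc(a, b), dsc(b, a))
    expect_equal(hd95(a, b, sp), hd95(b, a, sp))
    expect_equal(asd(a, b, sp), asd(b, a, sp))
    o <- bf_metrics(a, b, sp)
    expect_lte(hd95(a, b, sp), o$hd100 + 1e-12)
    # translate both masks by one voxel inside a larger canvas
    big <- function(m, off) {
      out <- array(FALSE, dims + 2L)
      out[off + seq_len(dims[1]), off + seq_len(dims[2]), off + seq_len(dims[3])] <- m
      out
    }
    expect_equal(hd95(big(a, 1L), big(b, 1L), sp), hd95(big(a, 2L), big(b, 2L), sp))
    expect_equal(asd(big(a, 1L), big(b, 1L), sp), asd(big(a, 2L), big(b, 2L), sp))
    expect_equal(dsc(big(a, 1L), big(b, 1L)), dsc(a, b))
  }
})

test_that("small-surface hd95 equals the exact Hausdorff distance", {
  set.seed(11)
  for (k in 1:10) {
    a <- array(FALSE, c(4, 6, 6)); a[sample(length(a), 3)] <- TRUE
    b <- array(FALSE, c(4, 6, 6)); b[sample(length(b), 3)] <- TRUE
    sp <- c(5, 1, 1)
    if (nrow(extract_surface(a)) <= 20 && nrow(extract_surface(b)) <= 20) {
      o <- bf_metrics(a, b, sp)
      expect_equal(hd95(a, b, sp, percentile = 1), o$hd100, tolerance = 1e-12)
    }
  }
})

test_that("per-patient evaluation reports missing distances, never zeros", {
  lt <- c(x = 1L, y = 2L)
  gt <- label_volume(array(c(rep(0L, 20), rep(1L, 4), rep(0L, 40)), c(4, 4, 4)),
                     sp511, lt)
  r <- evaluate_patient(gt, gt, c("x", "y"), patient_id = "p1")
  expect_equal(r$dsc, c(1, 1))           # y empty in both -> DSC 1
  expect_equal(r$hd95_mm[r$organ == "x"], 0)
  expect_true(is.na(r$hd95_mm[r$organ == "y"]))
  pred <- label_volume(array(0L, c(4, 4, 4)), sp511, lt)
  r2 <- evaluate_patient(pred, gt, c("x", "y"))
  expect_equal(r2$dsc[r2$organ == "x"], 0)
  expect_true(is.na(r2$asd_mm[r2$organ == "x"]))
  bad <- label_volume(array(0L, c(4, 4, 4)), c(1, 1, 1), lt)
  expect_error(evaluate_patient(bad, gt), class = "ts_validation_error")
})

test_that("slicewise and pooled variants stay close to the 3-D convention on aligned masks", {
  a <- array(FALSE, c(3, 12, 12)); a[1:3, 4:8, 4:8] <- TRUE
  b <- array(FALSE, c(3, 12, 12)); b[1:3, 5:9, 5:9] <- TRUE
  expect_equal(hd95(a, b, c(5, 1, 1), combine = "pooled"),
               hd95(a, b, c(5, 1, 1), combine = "max"), tolerance = 0.5)
  lt <- c(x = 1L)
  gt <- label_volume(array(as.integer(a), dim(a)), c(5, 1, 1), lt)
  pd <- label_volume(array(as.integer(b), dim(b)), c(5, 1, 1), lt)
  r3 <- evaluate_patient(pd, gt, "x")
  r2d <- evaluate_patient(pd, gt, "x", slicewise = TRUE)
  expect_false(is.na(r2d$hd95_mm))
  expect_lte(abs(r2d$asd_mm - r3$asd_mm), 1.0)
})
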