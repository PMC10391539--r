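test_that("patient generation is deterministic in (config, seed)", {
  cfg <- tiny_phantom_cfg()
  a <- generate_patient(cfg, 10L)
  b <- generate_patient(cfg, 10L)
  expect_identical(a$ct$voxels, b$ct$voxels)
  expect_identical(a$labels$labels, b$labels$labels)
  c <- generate_patient(cfg, 11L)
  expect_false(identical(a$ct$voxels, c$ct$voxels))
})

test_that("organ intensities sit near their configured tissue means", {
  cfg <- phantom_config(image_size = 128L, n_slices = 8L, carina_slice = 3L,
                        noise_sd_hu = 10)
  s <- generate_patient(cfg, 3L)
  m <- function(o) mean(s$ct$voxels[organ_mask(s$labels, o)])
  expect_lt(abs(m("left_lung") - (-750)), 40)
  expect_lt(abs(m("trachea") - (-950)), 40)
  expect_lt(abs(m("cord") - 45), 20)
  # the bony ring around the cord is bright
  expect_gt(max(s$ct$voxels[ceiling(cfg$n_slices / 2), , ]), 500)
})

test_that("a zero air fraction leaves no air in the esophagus lumen", {
  cfg <- tiny_phantom_cfg(image_size = 128L, esophagus_air_fraction = c(0, 0))
  s <- generate_patient(cfg, 4L)
  eso <- organ_mask(s$labels, "esophagus")
  expect_gt(sum(eso), 0)
  expect_equal(sum(s$ct$voxels[eso] < -500), 0)
  # and a full lumen does put air inside the esophagus label
  cfg2 <- tiny_phantom_cfg(image_size = 128L, esophagus_air_fraction = c(0.6, 0.6))
  s2 <- generate_patient(cfg2, 4L)
  expect_gt(sum(s2$ct$voxels[organ_mask(s2$labels, "esophagus")] < -500), 0)
})

test_that("the esophagus drifts image-left of the trachea below the carina", {
  cfg <- phantom_config()   # default study conditions
  s <- generate_patient(cfg, 6L)
  eso <- organ_mask(s$labels, "esophagus")
  tra <- organ_mask(s$labels, "trachea")
  for (i in (cfg$carina_slice + 1L):cfg$n_slices) {
    ec <- centroid(eso[i, , ]); tc <- centroid(tra[i, , ])
    expect_lt(ec[["col"]], tc[["col"]])
  }
  # esophagus and trachea labels never overlap
  expect_equal(dsc(eso, tra), 0)
})

test_that("cohorts are reproducible and pass the anatomical contract", {
  cfg <- tiny_phantom_cfg(image_size = 96L)
  a <- generate_cohort(cfg, 3, seed = 7)
  b <- generate_cohort(cfg, 3, seed = 7)
  expect_identical(lapply(a, function(s) s$ct$voxels),
                   lapply(b, function(s) s$ct$voxels))
  for (s in a) expect_true(isTRUE(check_phantom_contract(s, cfg)))
})

test_that("cohort directories mirror the 39/8/12 patient split", {
  cfg <- tiny_phantom_cfg(image_size = 32L, n_slices = 4L, carina_slice = 2L)
  cohort <- generate_cohort(cfg, 59, seed = 1)
  dir <- withr::local_tempdir()
  write_cohort(cohort, dir, c(train = 39L, val = 8L, test = 12L))
  counts <- vapply(c("train", "val", "test"), function(s)
    length(list.dirs(file.path(dir, s), recursive = FALSE)), integer(1))
  expect_equal(unname(counts), c(39L, 8L, 12L))
  # written volumes read back identically
  got <- load_dataset(dir)
  expect_equal(got$test[["patient_059"]]$labels$labels,
               cohort[["patient_059"]]$labels$labels)
  expect_equal(got$train[["patient_001"]]$ct$voxels,
               cohort[["patient_001"]]$ct$voxels, tolerance = 1e-6)
})
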