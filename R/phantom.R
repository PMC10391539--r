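# Seeded parametric thoracic CT phantom: axial slices with two lateral lung
# fields, a central-anterior heart, a posterior spinal cord inside a bony
# ring, a central air-filled trachea, and a small esophagus posterior to the
# trachea that drifts toward the image left below the carina. Organs are
# analytic ellipses/disks/annuli; the method under test needs topology and
# contrast statistics, not anatomical texture.

with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  force(code)
}

runif1 <- function(rng) if (length(rng) == 1L) rng else runif(1, rng[1], rng[2])

#' Phantom generator configuration
#'
#' Defaults emulate the acquisition the segmentation pipeline targets:
#' 5 mm slices, a 384 mm in-plane field of view, and an esophagus whose
#' lumen air filling and left drift below the carina vary per patient.
#'
#' @param image_size In-plane pixels per axis.
#' @param n_slices Number of axial slices.
#' @param spacing `(dz, dy, dx)` voxel spacing in mm. When `NULL`, dy = dx
#'   are chosen so the in-plane field of view stays at `fov_mm`.
#' @param fov_mm In-plane field of view in mm (used when `spacing` is NULL).
#' @param carina_slice 1-based slice index of the carina; below it the
#'   esophagus drifts toward the image left.
#' @param esophagus_radius_mm Range (min, max) of the esophagus radius.
#' @param esophagus_air_fraction Range of the lumen air fraction in `[0, 1]`.
#' @param esophagus_trachea_gap_mm Range of the wall-to-wall gap between
#'   trachea and esophagus.
#' @param drift_mm_per_slice Range of the per-slice leftward esophagus drift
#'   below the carina.
#' @param noise_sd_hu Standard deviation of additive Gaussian image noise.
#' @param hu Named list of mean tissue intensities (HU); config, not
#'   constants, so low-contrast regimes can be stressed.
#' @param seed Master seed for cohort generation.
#' @return A `phantom_config` list.
#' @export
phantom_config <- function(image_size = 256L, n_slices = 24L, spacing = NULL,
                           fov_mm = 384, carina_slice = 8L,
                           esophagus_radius_mm = c(4, 7),
                           esophagus_air_fraction = c(0, 0.5),
                           esophagus_trachea_gap_mm = c(1, 4),
                           drift_mm_per_slice = c(1.6, 2.6),
                           noise_sd_hu = 20,
                           hu = list(air = -1000, lung = -750, soft = 40,
                                     heart = 90, cord = 45, bone = 700,
                                     trachea = -950, esophagus_wall = 40,
                                     esophagus_lumen = -950),
                           seed = 1L) {
  if (is.null(spacing)) spacing <- c(5.0, fov_mm / image_size, fov_mm / image_size)
  if (carina_slice >= n_slices)
    ts_error("carina_slice must be below n_slices", "ts_validation_error")
  chk_rng <- function(r) length(r) %in% 1:2 && all(is.finite(r)) && (length(r) == 1L || r[1] <= r[2])
  for (r in list(esophagus_radius_mm, esophagus_air_fraction,
                 esophagus_trachea_gap_mm, drift_mm_per_slice))
    if (!chk_rng(r)) ts_error("ranges must be (min, max) with min <= max", "ts_validation_error")
  structure(list(image_size = as.integer(image_size), n_slices = as.integer(n_slices),
                 spacing = as.numeric(spacing), carina_slice = as.integer(carina_slice),
                 esophagus_radius_mm = esophagus_radius_mm,
                 esophagus_air_fraction = esophagus_air_fraction,
                 esophagus_trachea_gap_mm = esophagus_trachea_gap_mm,
                 drift_mm_per_slice = drift_mm_per_slice,
                 noise_sd_hu = noise_sd_hu, hu = hu, seed = as.integer(seed)),
            class = "phantom_config")
}

# mm coordinate grids for one slice, origin at the image center;
# x increases with column, y with row (downward = posterior, supine).
slice_grids <- function(cfg) {
  n <- cfg$image_size
  dy <- cfg$spacing[2]; dx <- cfg$spacing[3]
  y <- ((seq_len(n) - 1) - (n - 1) / 2) * dy
  x <- ((seq_len(n) - 1) - (n - 1) / 2) * dx
  list(Y = matrix(y, n, n, byrow = FALSE), X = matrix(x, n, n, byrow = TRUE))
}

ellipse_mask <- function(g, cx, cy, ax, ay) {
  ((g$X - cx) / ax)^2 + ((g$Y - cy) / ay)^2 <= 1
}

#' Generate one phantom patient
#'
#' Deterministic given `(cfg, patient_seed)`: the per-patient geometry
#' (organ centers, radii, esophagus air fraction, drift rate) is sampled
#' from the configured ranges, rasterized slice by slice, and Gaussian
#' image noise is added to the CT.
#'
#' @param cfg A [phantom_config].
#' @param patient_seed Integer seed for this patient.
#' @return A `phantom_sample` list with elements `ct` ([ct_volume], HU),
#'   `labels` ([label_volume]) and `truth_params` (sampled geometry).
#' @export
generate_patient <- function(cfg, patient_seed) {
  stopifnot(inherits(cfg, "phantom_config"))
  with_seed(patient_seed, {
    n <- cfg$image_size; ns <- cfg$n_slices
    half_fov <- (n - 1) / 2 * cfg$spacing[3]
    p <- list(
      patient_seed = patient_seed,
      body_ax = runif(1, 0.78, 0.88) * half_fov,
      body_ay = runif(1, 0.56, 0.64) * half_fov,
      lung_ax = runif(1, 48, 60), lung_ay = runif(1, 76, 90),
      lung_gap = runif(1, 24, 32),          # half-width of the mediastinum
      heart_cx = runif(1, -10, 6), heart_cy = runif(1, -38, -24),
      heart_ax = runif(1, 38, 48), heart_ay = runif(1, 30, 38),
      cord_cy = runif(1, 56, 68), cord_r = runif(1, 4.5, 5.5),
      bone_router = runif(1, 13, 16),
      tra_cx = runif(1, -3, 3), tra_cy = runif(1, 6, 14),
      tra_r = runif(1, 7, 9.5),
      eso_r = runif1(cfg$esophagus_radius_mm),
      eso_gap = runif1(cfg$esophagus_trachea_gap_mm),
      eso_air = runif1(cfg$esophagus_air_fraction),
      drift = runif1(cfg$drift_mm_per_slice)
    )
    # per-slice in-plane jitter of the two air columns (mm)
    p$tra_jx <- runif(ns, -1, 1); p$tra_jy <- runif(ns, -1, 1)
    p$eso_jx <- runif(ns, -1, 1); p$eso_jy <- runif(ns, -1, 1)
    p$eso_cy <- p$tra_cy + p$tra_r + p$eso_gap + p$eso_r

    max_drift <- p$drift * max(0, ns - cfg$carina_slice)
    if (p$eso_cy + p$eso_r > p$cord_cy - p$bone_router - 1 ||
        abs(p$tra_cx) - max_drift < -(p$lung_gap - p$eso_r - 1) * 1.5 &&
        max_drift > p$lung_gap + p$lung_ax)
      ts_error("sampled geometry cannot be placed inside the body", "ts_generation_error")

    g <- slice_grids(cfg)
    hu <- cfg$hu
    ct <- array(hu$air, dim = c(ns, n, n))
    masks <- list(left_lung = array(FALSE, c(ns, n, n)),
                  right_lung = array(FALSE, c(ns, n, n)),
                  heart = array(FALSE, c(ns, n, n)),
                  cord = array(FALSE, c(ns, n, n)),
                  trachea = array(FALSE, c(ns, n, n)),
                  esophagus = array(FALSE, c(ns, n, n)))
    eso_centers <- matrix(0, ns, 2, dimnames = list(NULL, c("cx", "cy")))

    for (i in seq_len(ns)) {
      scl <- 0.82 + 0.18 * sin(pi * (i - 0.5) / ns)   # lung taper toward apex/base
      body <- ellipse_mask(g, 0, 4, p$body_ax, p$body_ay)
      llung <- ellipse_mask(g, -(p$lung_gap + p$lung_ax * scl), -4,
                            p$lung_ax * scl, p$lung_ay * scl) & body
      rlung <- ellipse_mask(g, p$lung_gap + p$lung_ax * scl, -4,
                            p$lung_ax * scl, p$lung_ay * scl) & body
      heart <- ellipse_mask(g, p$heart_cx, p$heart_cy, p$heart_ax, p$heart_ay) & body
      cord <- ellipse_mask(g, 0, p$cord_cy, p$cord_r, p$cord_r)
      bone <- ellipse_mask(g, 0, p$cord_cy, p$bone_router, p$bone_router) &
              !ellipse_mask(g, 0, p$cord_cy, p$cord_r + 2, p$cord_r + 2)
      tcx <- p$tra_cx + p$tra_jx[i]; tcy <- p$tra_cy + p$tra_jy[i]
      trachea <- ellipse_mask(g, tcx, tcy, p$tra_r, p$tra_r)
      drift <- if (i > cfg$carina_slice) p$drift * (i - cfg$carina_slice) else 0
      ecx <- p$tra_cx - drift + if (i > cfg$carina_slice) min(0, p$eso_jx[i]) else p$eso_jx[i]
      ecy <- p$eso_cy + p$eso_jy[i]
      eso <- ellipse_mask(g, ecx, ecy, p$eso_r, p$eso_r)
      eso_centers[i, ] <- c(ecx, ecy)

      sl <- ct[i, , ]
      sl[body] <- hu$soft
      sl[llung | rlung] <- hu$lung
      sl[heart] <- hu$heart
      sl[bone] <- hu$bone
      sl[cord] <- hu$cord
      sl[trachea] <- hu$trachea
      sl[eso] <- hu$esophagus_wall
      if (p$eso_air > 0) {
        lumen <- ellipse_mask(g, ecx, ecy, p$eso_r * sqrt(p$eso_air),
                              p$eso_r * sqrt(p$eso_air))
        sl[lumen] <- hu$esophagus_lumen
      }
      ct[i, , ] <- sl
      # label masks keep the full esophagus disk (lumen is intensity only)
      masks$left_lung[i, , ] <- llung
      masks$right_lung[i, , ] <- rlung
      masks$heart[i, , ] <- heart
      masks$cord[i, , ] <- cord
      masks$trachea[i, , ] <- trachea
      masks$esophagus[i, , ] <- eso & !trachea
    }
    ct <- ct + array(rnorm(length(ct), 0, cfg$noise_sd_hu), dim = dim(ct))
    labels <- assemble_labels(masks, default_label_table(), cfg$spacing)
    p$eso_centers <- eso_centers
    structure(list(ct = ct_volume(ct, cfg$spacing, "HU"),
                   labels = labels, truth_params = p),
              class = "phantom_sample")
  })
}

#' Generate a phantom cohort
#'
#' Per-patient seeds are drawn deterministically from the master seed, so
#' the whole cohort is reproducible from `(cfg, n_patients, seed)`.
#'
#' @param cfg A [phantom_config].
#' @param n_patients Number of patients (>= 1).
#' @param seed Master seed (defaults to `cfg$seed`).
#' @return List of `phantom_sample` objects named `patient_001`, ...
#' @export
generate_cohort <- function(cfg, n_patients, seed = cfg$seed) {
  stopifnot(n_patients >= 1)
  seeds <- with_seed(seed, sample.int(.Machine$integer.max, n_patients))
  out <- lapply(seq_len(n_patients), function(i) generate_patient(cfg, seeds[i]))
  names(out) <- sprintf("patient_%03d", seq_len(n_patients))
  out
}

#' Write a cohort as a dataset directory
#'
#' Layout: `<split>/<patient_id>/ct.nii.gz` + `labels.nii.gz`. Splits are
#' disjoint by patient and assigned in cohort order (first `train`, then
#' `val`, then `test`), mirroring a fixed patient-level split.
#'
#' @param cohort List of `phantom_sample`s from [generate_cohort].
#' @param dir Output directory (created).
#' @param split Named integer vector, e.g. `c(train = 39, val = 8, test = 12)`;
#'   must sum to `length(cohort)`.
#' @return Invisibly, a data.frame of patient_id and split.
#' @export
write_cohort <- function(cohort, dir, split = c(train = 39L, val = 8L, test = 12L)) {
  if (sum(split) != length(cohort))
    ts_error("split sizes must sum to the cohort size", "ts_validation_error")
  assign_split <- rep(names(split), times = split)
  ids <- names(cohort)
  for (i in seq_along(cohort)) {
    d <- file.path(dir, assign_split[i], ids[i])
    dir.create(d, recursive = TRUE, showWarnings = FALSE)
    write_volume(cohort[[i]]$ct, file.path(d, "ct.nii.gz"))
    write_labelmap(cohort[[i]]$labels, file.path(d, "labels.nii.gz"))
  }
  invisible(data.frame(patient_id = ids, split = assign_split))
}

# 4-connected single-component check for one binary slice: grow the first
# seed by dilation restricted to the mask until it stops changing
single_component_2d <- function(m) {
  idx <- which(m)
  if (!length(idx)) return(TRUE)
  nr <- nrow(m); nc <- ncol(m)
  reach <- matrix(FALSE, nr, nc)
  reach[idx[1L]] <- TRUE
  repeat {
    grown <- reach
    grown[-1L, ] <- grown[-1L, ] | reach[-nr, ]
    grown[-nr, ] <- grown[-nr, ] | reach[-1L, ]
    grown[, -1L] <- grown[, -1L] | reach[, -nc]
    grown[, -nc] <- grown[, -nc] | reach[, -1L]
    grown <- grown & m
    if (identical(grown, reach)) break
    reach <- grown
  }
  sum(reach) == length(idx)
}

#' Check the anatomical contract of a phantom sample
#'
#' Verifies, from the generated labels themselves, that: lungs sit on
#' opposite sides of the midline; the cord is posterior of heart and
#' trachea and surrounded by a high-intensity ring; the esophagus is
#' disjoint from the trachea, within the configured wall-to-wall gap of
#' it, and drifts image-left of the trachea below the carina; and every
#' organ is a single 4-connected component on each slice where it appears.
#'
#' @param sample A `phantom_sample`.
#' @param cfg The [phantom_config] used to generate it.
#' @return `TRUE` if all checks pass, else a character vector of failures.
#' @export
check_phantom_contract <- function(sample, cfg) {
  lv <- sample$labels
  fails <- character(0)
  note <- function(msg) fails <<- c(fails, msg)
  cw <- function(m) if (any(m)) mean(which(m, arr.ind = TRUE)[, 3]) else NA_real_
  ch <- function(m) if (any(m)) mean(which(m, arr.ind = TRUE)[, 2]) else NA_real_
  msk <- lapply(names(lv$label_table), function(o) organ_mask(lv, o))
  names(msk) <- names(lv$label_table)
  mid <- (cfg$image_size + 1) / 2
  if (!(cw(msk$left_lung) < mid && cw(msk$right_lung) > mid))
    note("lungs are not lateral of the midline")
  if (!(ch(msk$cord) > ch(msk$heart) && ch(msk$cord) > ch(msk$trachea)))
    note("cord is not posterior of heart and trachea")
  if (any(msk$trachea & msk$esophagus)) note("trachea and esophagus overlap")
  # bony ring: high-HU voxels surround the cord centroid on the middle slice
  i <- ceiling(cfg$n_slices / 2)
  bone_sl <- sample$ct$voxels[i, , ] > 400
  cord_sl <- msk$cord[i, , ]
  if (any(cord_sl)) {
    rc <- colMeans(which(cord_sl, arr.ind = TRUE))
    ring <- which(bone_sl, arr.ind = TRUE)
    if (nrow(ring) < 8) {
      note("no bony ring around the cord")
    } else {
      ang <- atan2(ring[, 1] - rc[1], ring[, 2] - rc[2])
      if (length(unique(cut(ang, breaks = seq(-pi, pi, length.out = 9)))) < 6)
        note("bony ring does not surround the cord")
    }
  }
  # esophagus adjacency and drift
  sp <- lv$spacing
  for (i in seq_len(cfg$n_slices)) {
    tr <- msk$trachea[i, , ]; es <- msk$esophagus[i, , ]
    if (!any(tr)) { note(sprintf("slice %d: empty trachea", i)); next }
    if (!any(es)) { note(sprintf("slice %d: empty esophagus", i)); next }
    ti <- which(tr, arr.ind = TRUE); ei <- which(es, arr.ind = TRUE)
    dmin <- sqrt(min(outer(ei[, 1] * sp[2], ti[, 1] * sp[2], "-")^2 +
                     outer(ei[, 2] * sp[3], ti[, 2] * sp[3], "-")^2))
    allowed <- max(cfg$esophagus_trachea_gap_mm) + 3 * max(sp[2:3]) +
      max(cfg$drift_mm_per_slice) * max(0L, i - cfg$carina_slice)
    if (dmin > allowed)
      note(sprintf("slice %d: esophagus too far from trachea (%.1f mm)", i, dmin))
    if (i > cfg$carina_slice && !(mean(ei[, 2]) < mean(ti[, 2])))
      note(sprintf("slice %d: esophagus not left of trachea below carina", i))
    for (o in names(msk))
      if (!single_component_2d(msk[[o]][i, , ]))
        note(sprintf("slice %d: %s not a single component", i, o))
  }
  if (length(fails)) fails else TRUE
}
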