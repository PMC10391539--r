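# Stage-2 localization: the per-slice trachea centroid, shifted 5 mm left
# and 5 mm up, centers a 64x64 crop that must contain the esophagus.
# Training adds an isotropic random jitter of 0-4 mm; slices with an empty
# trachea mask fall back to the previous slice's center displaced 1 mm per
# slice. Rows increase downward, so "up" decreases the row index and "left"
# decreases the column index.

#' Crop localization contract
#'
#' @param crop_size Crop side length in pixels (even, >= 8).
#' @param shift_left_mm,shift_up_mm Systematic offsets applied to the
#'   trachea centroid to leave room for the esophagus (defaults 5 mm each).
#' @param jitter_range_mm `(min, max)` of the training-time displacement
#'   magnitude in mm (default 0-4).
#' @param fallback_step_mm Per-slice displacement when chaining from the
#'   previous slice's center (default 1 mm).
#' @param fallback_direction Direction of the fallback displacement
#'   (`"left"`, `"right"`, `"up"`, `"down"`).
#' @return A `crop_spec` list.
#' @export
crop_spec <- function(crop_size = 64L, shift_left_mm = 5, shift_up_mm = 5,
                      jitter_range_mm = c(0, 4), fallback_step_mm = 1,
                      fallback_direction = c("left", "right", "up", "down")) {
  fallback_direction <- match.arg(fallback_direction)
  crop_size <- as.integer(crop_size)
  if (crop_size < 8L || crop_size %% 2L != 0L)
    ts_error("crop_size must be even and >= 8", "ts_config_error")
  if (shift_left_mm < 0 || shift_up_mm < 0 || fallback_step_mm < 0 ||
      any(jitter_range_mm < 0) || jitter_range_mm[1] > jitter_range_mm[2])
    ts_error("mm offsets must be >= 0 with a non-decreasing jitter range",
             "ts_config_error")
  structure(list(crop_size = crop_size, shift_left_mm = shift_left_mm,
                 shift_up_mm = shift_up_mm, jitter_range_mm = jitter_range_mm,
                 fallback_step_mm = fallback_step_mm,
                 fallback_direction = fallback_direction),
            class = "crop_spec")
}

#' Centroid (center of gravity) of a 2-D binary mask
#'
#' @param mask2d Binary matrix.
#' @return `(row, col)` as reals; errors with class `ts_empty_mask_error`
#'   on an empty mask so the caller can chain to the fallback.
#' @export
centroid <- function(mask2d) {
  idx <- which(mask2d != 0, arr.ind = TRUE)
  if (!nrow(idx)) ts_error("centroid of an empty mask", "ts_empty_mask_error")
  c(row = mean(idx[, 1]), col = mean(idx[, 2]))
}

#' Inference-time crop center from a trachea centroid
#'
#' Shifts the centroid left by `shift_left_mm` and up by `shift_up_mm`,
#' converted to pixels by the in-plane spacing.
#'
#' @param trachea_centroid `(row, col)`.
#' @param spacing `(dy, dx)` in mm.
#' @param spec A [crop_spec].
#' @return `(row, col)` crop center as reals.
#' @export
inference_center <- function(trachea_centroid, spacing, spec = crop_spec()) {
  stopifnot(all(spacing > 0))
  c(row = unname(trachea_centroid[1]) - spec$shift_up_mm / spacing[1],
    col = unname(trachea_centroid[2]) - spec$shift_left_mm / spacing[2])
}

#' Training-time crop center: inference center plus random jitter
#'
#' The jitter has magnitude uniform on `jitter_range_mm` and uniform
#' direction, mimicking the stage-1 localization error the crop network
#' must tolerate. Uses the current RNG state; seed the session for
#' reproducibility.
#'
#' @inheritParams inference_center
#' @param label_trachea_centroid `(row, col)` centroid of the label trachea.
#' @return `(row, col)` crop center as reals.
#' @export
training_center <- function(label_trachea_centroid, spacing, spec = crop_spec()) {
  ctr <- inference_center(label_trachea_centroid, spacing, spec)
  m <- runif(1, spec$jitter_range_mm[1], spec$jitter_range_mm[2])
  th <- runif(1, 0, 2 * pi)
  c(row = unname(ctr[1]) + m * sin(th) / spacing[1],
    col = unname(ctr[2]) + m * cos(th) / spacing[2])
}

#' Extract a square crop around a center
#'
#' The window starts at `round(center) - crop_size/2` on each axis and spans
#' `crop_size` pixels; parts outside the image are zero-padded and recorded.
#'
#' @param image2d Numeric matrix.
#' @param center `(row, col)` crop center.
#' @param spec A [crop_spec].
#' @param slice_index Slice index stored in the region record.
#' @return List with `crop` (crop_size x crop_size matrix) and `region`
#'   (a `crop_region`: slice_index, 1-based `origin` `(row, col)`, `size`,
#'   and `pad` `(top, bottom, left, right)`).
#' @export
extract_crop <- function(image2d, center, spec = crop_spec(), slice_index = 1L) {
  sz <- spec$crop_size
  or <- as.integer(round(center[1])) - sz %/% 2L
  oc <- as.integer(round(center[2])) - sz %/% 2L
  nr <- nrow(image2d); nc <- ncol(image2d)
  rows <- or:(or + sz - 1L); cols <- oc:(oc + sz - 1L)
  rin <- rows >= 1L & rows <= nr; cin <- cols >= 1L & cols <= nc
  crop <- matrix(0, sz, sz)
  crop[rin, cin] <- image2d[rows[rin], cols[cin], drop = FALSE]
  pad <- c(top = sum(rows < 1L), bottom = sum(rows > nr),
           left = sum(cols < 1L), right = sum(cols > nc))
  region <- structure(list(slice_index = as.integer(slice_index),
                           origin = c(row = or, col = oc), size = sz, pad = pad),
                      class = "crop_region")
  list(crop = crop, region = region)
}

#' Paste a crop back into a full-size image
#'
#' Inverse of [extract_crop] on the in-bounds region; out-of-bounds padding
#' is dropped.
#'
#' @param image2d Target matrix (modified copy returned).
#' @param crop `crop_size` square matrix.
#' @param region The `crop_region` from [extract_crop].
#' @return The updated matrix.
#' @export
paste_crop <- function(image2d, crop, region) {
  sz <- region$size
  rows <- region$origin[["row"]]:(region$origin[["row"]] + sz - 1L)
  cols <- region$origin[["col"]]:(region$origin[["col"]] + sz - 1L)
  rin <- rows >= 1L & rows <= nrow(image2d)
  cin <- cols >= 1L & cols <= ncol(image2d)
  image2d[rows[rin], cols[cin]] <- crop[rin, cin]
  image2d
}

#' Fallback crop center from the previous slice
#'
#' When the current slice has no usable trachea centroid (or the crop missed
#' the esophagus during training-set construction), the previous slice's
#' center is displaced `fallback_step_mm` in `fallback_direction`
#' (leftward by default, following the esophagus drift below the carina).
#'
#' @param prev_center `(row, col)` center used on the previous slice.
#' @param spacing `(dy, dx)` in mm.
#' @param spec A [crop_spec].
#' @return `(row, col)` center for the current slice.
#' @export
fallback_center <- function(prev_center, spacing, spec = crop_spec()) {
  step <- spec$fallback_step_mm
  d <- switch(spec$fallback_direction,
              left = c(0, -step / spacing[2]),
              right = c(0, step / spacing[2]),
              up = c(-step / spacing[1], 0),
              down = c(step / spacing[1], 0))
  c(row = unname(prev_center[1]) + d[1], col = unname(prev_center[2]) + d[2])
}

#' Correct stage-1 labels with stage-2 esophagus crops
#'
#' The esophagus is exclusively stage 2's: all stage-1 esophagus voxels are
#' removed, then each crop's foreground is written as esophagus wherever
#' stage 1 assigned background (or esophagus); stage-1 non-esophagus organ
#' labels win conflicts and are never modified.
#'
#' @param stage1_labels A [label_volume] from the stage-1 network.
#' @param crop_preds List of binary `crop_size` square matrices.
#' @param regions List of matching `crop_region`s.
#' @return A corrected [label_volume].
#' @export
paste_esophagus <- function(stage1_labels, crop_preds, regions) {
  stopifnot(inherits(stage1_labels, "label_volume"),
            length(crop_preds) == length(regions))
  lt <- stage1_labels$label_table
  eso <- lt[["esophagus"]]
  lab <- stage1_labels$labels
  lab[lab == eso] <- 0L
  d <- dim(lab)
  for (i in seq_along(regions)) {
    rg <- regions[[i]]
    if (rg$slice_index < 1L || rg$slice_index > d[1])
      ts_error("crop region slice out of bounds", "ts_validation_error")
    sz <- rg$size
    rows <- rg$origin[["row"]]:(rg$origin[["row"]] + sz - 1L)
    cols <- rg$origin[["col"]]:(rg$origin[["col"]] + sz - 1L)
    rin <- rows >= 1L & rows <= d[2]; cin <- cols >= 1L & cols <= d[3]
    sl <- lab[rg$slice_index, , ]
    sub <- sl[rows[rin], cols[cin], drop = FALSE]
    pred <- (crop_preds[[i]] != 0)[rin, cin, drop = FALSE]
    sub[pred & sub == 0L] <- eso
    sl[rows[rin], cols[cin]] <- sub
    lab[rg$slice_index, , ] <- sl
  }
  label_volume(lab, stage1_labels$spacing, lt)
}
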