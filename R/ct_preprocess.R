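# CT window/level preprocessing and label-volume assembly.

#' Window/level configuration
#'
#' Standard mediastinal display window: intensities in
#' `[level - width/2, level + width/2]` HU map linearly onto `[0, out_max]`
#' and are clipped outside. Defaults are width 400 HU, level 40 HU, 8-bit
#' output range.
#'
#' @param window_width Window width in HU (> 0).
#' @param window_level Window level (center) in HU.
#' @param out_max Upper end of the output range.
#' @return A `window_config` list.
#' @export
window_config <- function(window_width = 400, window_level = 40, out_max = 255) {
  if (window_width <= 0) ts_error("window_width must be > 0", "ts_contract_error")
  if (out_max <= 0) ts_error("out_max must be > 0", "ts_contract_error")
  structure(list(window_width = window_width, window_level = window_level,
                 out_max = out_max), class = "window_config")
}

#' Apply a window/level intensity mapping
#'
#' Maps HU linearly so the window spans `[0, cfg$out_max]`, clipping values
#' outside the window. Output stays real-valued (no 8-bit quantization);
#' quantization happens only on PNG export.
#'
#' @param vol A [ct_volume] in HU.
#' @param cfg A [window_config].
#' @return A [ct_volume] with `intensity_space = "normalized_0_255"`.
#' @export
apply_window <- function(vol, cfg = window_config()) {
  stopifnot(inherits(vol, "ct_volume"))
  if (vol$intensity_space != "HU")
    ts_error("apply_window expects a volume in HU", "ts_contract_error")
  lo <- cfg$window_level - cfg$window_width / 2
  out <- (vol$voxels - lo) / cfg$window_width * cfg$out_max
  out[out < 0] <- 0
  out[out > cfg$out_max] <- cfg$out_max
  ct_volume(out, vol$spacing, "normalized_0_255")
}

#' Rescale a windowed volume to the unit interval
#'
#' @param vol A [ct_volume] in `normalized_0_255` space.
#' @param out_max Value that maps to 1 (default 255).
#' @return A [ct_volume] with `intensity_space = "unit_interval"`.
#' @export
to_unit_interval <- function(vol, out_max = 255) {
  stopifnot(inherits(vol, "ct_volume"))
  if (vol$intensity_space != "normalized_0_255")
    ts_error("to_unit_interval expects a normalized_0_255 volume", "ts_contract_error")
  ct_volume(vol$voxels / out_max, vol$spacing, "unit_interval")
}

#' Assemble per-organ binary masks into an exclusive label volume
#'
#' Each voxel receives the code of the covering organ. Where expert masks
#' overlap, the organ earlier in [organ_precedence] wins, so the thin
#' air-column structures (trachea, then cord, then esophagus) are never
#' overwritten by the large soft-tissue organs.
#'
#' @param per_organ_masks Named list of binary (logical or 0/1) 3-D arrays,
#'   all the same shape; names must appear in `label_table`.
#' @param label_table Named integer vector of organ codes.
#' @param spacing Voxel spacing `(dz, dy, dx)` in mm.
#' @return A [label_volume].
#' @export
assemble_labels <- function(per_organ_masks, label_table = default_label_table(),
                            spacing = c(5, 1, 1)) {
  if (!length(per_organ_masks)) ts_error("no masks supplied", "ts_validation_error")
  shp <- dim(per_organ_masks[[1L]])
  ok <- vapply(per_organ_masks, function(m) identical(dim(m), shp), logical(1L))
  if (!all(ok)) ts_error("per-organ masks differ in shape", "ts_validation_error")
  unknown <- setdiff(names(per_organ_masks), names(label_table))
  if (length(unknown))
    ts_error(sprintf("organs missing from label_table: %s", paste(unknown, collapse = ", ")),
             "ts_validation_error")
  out <- array(0L, dim = shp)
  # paint lowest precedence first; higher precedence overwrites
  order_names <- rev(intersect(organ_precedence(), names(per_organ_masks)))
  order_names <- c(setdiff(names(per_organ_masks), order_names), order_names)
  for (nm in order_names) {
    m <- per_organ_masks[[nm]] != 0
    out[m] <- label_table[[nm]]
  }
  label_volume(out, spacing, label_table)
}

#' Extract one organ's binary mask from a label volume
#'
#' @param lv A [label_volume].
#' @param organ Organ name present in the label table.
#' @return Logical 3-D array.
#' @export
organ_mask <- function(lv, organ) {
  stopifnot(inherits(lv, "label_volume"))
  if (!organ %in% names(lv$label_table))
    ts_error(sprintf("unknown organ: %s", organ), "ts_validation_error")
  lv$labels == lv$label_table[[organ]]
}
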