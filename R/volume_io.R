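# Format boundary of the package: CT and label volumes on disk (NIfTI, or a
# directory of 8-bit grayscale PNG slices with a JSON sidecar). All arrays are
# (slice z, row y, col x), 0-based indexing in the API where stated; rows
# increase downward (image convention).

ts_error <- function(msg, class) {
  stop(structure(class = c(class, "thoraxseg_error", "error", "condition"),
                 list(message = msg, call = sys.call(-1))))
}

#' Construct a CT volume
#'
#' @param voxels 3-D numeric array ordered (slice z, row y, col x).
#' @param spacing Numeric length-3 vector `(dz, dy, dx)` in mm, all positive.
#' @param intensity_space One of `"HU"`, `"normalized_0_255"`,
#'   `"unit_interval"`.
#' @return An object of class `ct_volume`.
#' @export
ct_volume <- function(voxels, spacing, intensity_space = c("HU", "normalized_0_255", "unit_interval")) {
  intensity_space <- match.arg(intensity_space)
  if (!is.array(voxels) || length(dim(voxels)) != 3L || any(dim(voxels) < 1L))
    ts_error("voxels must be a 3-D array with positive dimensions", "ts_format_error")
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    ts_error("spacing must be three strictly positive values (dz, dy, dx)", "ts_format_error")
  if (intensity_space == "normalized_0_255") {
    rng <- range(voxels)
    if (rng[1] < 0 || rng[2] > 255)
      ts_error("normalized_0_255 volumes must lie in [0, 255]", "ts_contract_error")
  }
  structure(list(voxels = voxels, spacing = spacing, intensity_space = intensity_space),
            class = "ct_volume")
}

#' Construct a label volume
#'
#' @param labels 3-D integer array of organ codes (0 = background).
#' @param spacing Numeric `(dz, dy, dx)` in mm.
#' @param label_table Named integer vector mapping organ name to code.
#' @return An object of class `label_volume`.
#' @export
label_volume <- function(labels, spacing, label_table = default_label_table()) {
  if (!is.array(labels) || length(dim(labels)) != 3L)
    ts_error("labels must be a 3-D array", "ts_format_error")
  if (any(labels != round(labels)))
    ts_error("label volume contains non-integer values", "ts_format_error")
  storage.mode(labels) <- "integer"
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(spacing <= 0))
    ts_error("spacing must be three strictly positive values", "ts_format_error")
  lt <- as.integer(label_table)
  names(lt) <- names(label_table)
  present <- setdiff(unique(as.integer(labels)), 0L)
  unknown <- setdiff(present, lt)
  if (length(unknown))
    ts_error(sprintf("label values not in label_table: %s", paste(unknown, collapse = ", ")),
             "ts_validation_error")
  structure(list(labels = labels, spacing = spacing, label_table = lt),
            class = "label_volume")
}

#' @export
print.ct_volume <- function(x, ...) {
  cat(sprintf("<ct_volume> %s voxels, spacing (%s) mm, %s\n",
              paste(dim(x$voxels), collapse = "x"),
              paste(format(x$spacing), collapse = ", "), x$intensity_space))
  invisible(x)
}

#' @export
print.label_volume <- function(x, ...) {
  cat(sprintf("<label_volume> %s voxels, spacing (%s) mm, organs: %s\n",
              paste(dim(x$labels), collapse = "x"),
              paste(format(x$spacing), collapse = ", "),
              paste(names(x$label_table), collapse = ", ")))
  invisible(x)
}

sidecar_path <- function(path) {
  if (dir.exists(path)) return(file.path(path, "volume.json"))
  paste0(sub("\\.nii(\\.gz)?$", "", path), ".json")
}

read_sidecar <- function(path) {
  sp <- sidecar_path(path)
  if (file.exists(sp)) jsonlite::read_json(sp, simplifyVector = TRUE) else NULL
}

write_sidecar <- function(path, meta) {
  jsonlite::write_json(meta, sidecar_path(path), auto_unbox = TRUE, digits = NA)
}

# NIfTI stores (x, y, z) fastest-first; internal order is (z, y, x).
nifti_to_internal <- function(img) aperm(img, c(3L, 2L, 1L))
internal_to_nifti <- function(arr) aperm(arr, c(3L, 2L, 1L))

read_nifti_array <- function(path) {
  img <- RNifti::readNifti(path)
  if (length(dim(img)) != 3L)
    ts_error(sprintf("expected a 3-D NIfTI volume, got %d dims", length(dim(img))),
             "ts_format_error")
  pd <- RNifti::pixdim(img)[1:3]          # (dx, dy, dz)
  list(arr = nifti_to_internal(as.array(img)), spacing = rev(as.numeric(pd)))
}

write_nifti_array <- function(arr, spacing, path) {
  img <- RNifti::asNifti(internal_to_nifti(arr))
  RNifti::pixdim(img) <- rev(spacing)     # (dx, dy, dz)
  RNifti::writeNifti(img, path)
}

read_png_stack <- function(path) {
  meta <- read_sidecar(path)
  if (is.null(meta) || is.null(meta$spacing))
    ts_error("PNG stack directory needs a volume.json sidecar with spacing", "ts_format_error")
  files <- sort(list.files(path, pattern = "\\.png$", full.names = TRUE))
  if (!length(files)) ts_error("no PNG slices found", "ts_not_found_error")
  slices <- lapply(files, function(f) {
    p <- png::readPNG(f)
    if (length(dim(p)) == 3L) p <- p[, , 1L]
    p * 255
  })
  shp <- dim(slices[[1L]])
  if (!all(vapply(slices, function(s) identical(dim(s), shp), logical(1L))))
    ts_error("PNG slices have inconsistent shapes", "ts_format_error")
  arr <- array(0, dim = c(length(slices), shp))
  for (i in seq_along(slices)) arr[i, , ] <- slices[[i]]
  list(arr = arr, spacing = as.numeric(meta$spacing))
}

#' Read a CT volume
#'
#' Reads a NIfTI file (`.nii`/`.nii.gz`; intensities taken as Hounsfield
#' units unless a JSON sidecar says otherwise) or a directory of equally
#' sized 8-bit grayscale PNG slices plus a `volume.json` sidecar holding the
#' voxel spacing (PNG stacks are read as `normalized_0_255`).
#'
#' @param path Path to a NIfTI file or a PNG-stack directory.
#' @return A [ct_volume].
#' @export
read_volume <- function(path) {
  if (!file.exists(path))
    ts_error(sprintf("no such file or directory: %s", path), "ts_not_found_error")
  if (dir.exists(path)) {
    got <- read_png_stack(path)
    meta <- read_sidecar(path)
    space <- if (!is.null(meta$intensity_space)) meta$intensity_space else "normalized_0_255"
    return(ct_volume(got$arr, got$spacing, space))
  }
  got <- read_nifti_array(path)
  meta <- read_sidecar(path)
  space <- if (!is.null(meta$intensity_space)) meta$intensity_space else "HU"
  ct_volume(got$arr, got$spacing, space)
}

#' Write a CT volume
#'
#' Writes NIfTI plus a JSON sidecar recording the intensity space, so that
#' [read_volume] round-trips voxels, spacing and intensity flag exactly.
#'
#' @param vol A [ct_volume].
#' @param path Output path (`.nii` or `.nii.gz`).
#' @export
write_volume <- function(vol, path) {
  stopifnot(inherits(vol, "ct_volume"))
  if (!dir.exists(dirname(path)))
    ts_error(sprintf("parent directory does not exist: %s", dirname(path)), "ts_io_error")
  write_nifti_array(vol$voxels, vol$spacing, path)
  write_sidecar(path, list(intensity_space = vol$intensity_space))
  invisible(NULL)
}

#' Read a label volume
#'
#' @param path NIfTI path; a JSON sidecar holding `label_table` is required.
#' @return A [label_volume].
#' @export
read_labelmap <- function(path) {
  if (!file.exists(path))
    ts_error(sprintf("no such file: %s", path), "ts_not_found_error")
  got <- read_nifti_array(path)
  if (any(got$arr != round(got$arr)))
    ts_error("labelmap contains non-integer voxel values", "ts_format_error")
  meta <- read_sidecar(path)
  if (is.null(meta$label_table))
    ts_error("labelmap sidecar with label_table is missing", "ts_format_error")
  lt <- unlist(meta$label_table)
  label_volume(got$arr, got$spacing, setNames(as.integer(lt), names(lt)))
}

#' Write a label volume
#'
#' @param lv A [label_volume].
#' @param path Output path (`.nii` or `.nii.gz`).
#' @export
write_labelmap <- function(lv, path) {
  stopifnot(inherits(lv, "label_volume"))
  if (!dir.exists(dirname(path)))
    ts_error(sprintf("parent directory does not exist: %s", dirname(path)), "ts_io_error")
  write_nifti_array(lv$labels, lv$spacing, path)
  write_sidecar(path, list(label_table = as.list(lv$label_table)))
  invisible(NULL)
}
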