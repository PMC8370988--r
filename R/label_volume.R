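#' Lumen label volume
#'
#' A 3D voxel grid of integer labels: 0 background, 1 true lumen,
#' 2 false lumen.  Voxel `(i, j, k)` (1-based in R) has its center at
#' `origin + (c(i, j, k) - 1) * spacing` in world mm; the grid axes are
#' aligned with the world axes.  Straightened (OCT) volumes run along
#' the z axis with slice 1 at the distal end (the OCT catheter starts
#' distal to the region of interest and is pulled back proximally).
#'
#' @param array integer 3D array with values in `{0, 1, 2}`.
#' @param spacing numeric length-3, voxel spacing in mm (> 0).
#' @param origin numeric length-3, world position (mm) of the center of
#'   voxel `(1, 1, 1)`.
#' @return object of class `label_volume`.
#' @export
#' @examples
#' v <- label_volume(array(0L, c(4, 4, 2)), spacing = c(0.1, 0.1, 0.2))
#' label_volume_counts(v)
label_volume <- function(array, spacing, origin = c(0, 0, 0)) {
  if (length(dim(array)) != 3) stop("label array must be 3D")
  spacing <- as.numeric(spacing)
  if (length(spacing) == 1) spacing <- rep(spacing, 3)
  if (length(spacing) != 3 || any(spacing <= 0)) stop("spacing must be 3 positive values")
  if (!all(array %in% c(0L, 1L, 2L))) stop("labels must be in {0, 1, 2}")
  storage.mode(array) <- "integer"
  structure(list(array = array, spacing = spacing, origin = as.numeric(origin)),
            class = "label_volume")
}

#' @export
print.label_volume <- function(x, ...) {
  d <- dim(x$array)
  cat(sprintf("<label_volume> %d x %d x %d voxels @ %.4f x %.4f x %.4f mm\n",
              d[1], d[2], d[3], x$spacing[1], x$spacing[2], x$spacing[3]))
  cat(sprintf("  labels: bg %d, true %d, false %d\n",
              sum(x$array == 0L), sum(x$array == 1L), sum(x$array == 2L)))
  invisible(x)
}

#' Voxel counts per label
#' @param volume a [label_volume].
#' @return named integer vector (background, true_lumen, false_lumen).
#' @export
label_volume_counts <- function(volume) {
  c(background = sum(volume$array == 0L),
    true_lumen = sum(volume$array == 1L),
    false_lumen = sum(volume$array == 2L))
}

#' Physical volume (mm^3) of a label subset
#' @param volume a [label_volume].
#' @param labels labels counted (default lumen labels 1 and 2).
#' @return scalar volume in mm^3.
#' @export
label_volume_mm3 <- function(volume, labels = c(1L, 2L)) {
  sum(volume$array %in% labels) * prod(volume$spacing)
}

#' World coordinates (mm) of voxel centers for a label subset
#' @param volume a [label_volume].
#' @param labels labels to extract.
#' @return m x 3 matrix of world coordinates.
#' @export
label_voxel_coords <- function(volume, labels = c(1L, 2L)) {
  m <- array(volume$array %in% labels, dim(volume$array))
  idx <- which(m, arr.ind = TRUE)
  sweep(sweep(idx - 1, 2, volume$spacing, "*"), 2, volume$origin, "+")
}

#' Per-slice lumen area (mm^2) of a straightened volume
#'
#' Counts lumen voxels per z slice and multiplies by in-plane voxel
#' area.  Used for ground-truth bookkeeping and area-conservation
#' checks.
#'
#' @param volume a [label_volume].
#' @param labels labels counted as lumen.
#' @return numeric vector, one area per slice (mm^2).
#' @export
slice_areas <- function(volume, labels = c(1L, 2L)) {
  apply(volume$array, 3, function(sl) sum(sl %in% labels)) *
    volume$spacing[1] * volume$spacing[2]
}

#' Write a label volume as NIfTI
#' @param volume a [label_volume].
#' @param path output `.nii` (or `.nii.gz`) file.
#' @return `path`, invisibly.
#' @export
write_label_volume <- function(volume, path) {
  img <- RNifti::asNifti(volume$array, pixdim = volume$spacing)
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Read a label volume from NIfTI
#' @param path NIfTI file written by [write_label_volume].
#' @param origin world origin to attach (NIfTI stores orientation, not
#'   the package's simple axis-aligned origin; defaults to zero).
#' @return a [label_volume].
#' @export
read_label_volume <- function(path, origin = c(0, 0, 0)) {
  img <- RNifti::readNifti(path)
  spacing <- RNifti::pixdim(img)[1:3]
  label_volume(round(as.array(img)), spacing = spacing, origin = origin)
}
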