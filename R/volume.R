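#' CT volume with voxel spacing
#'
#' A `volume_image` bundles a rank-3 array of Hounsfield-unit (HU) values with
#' the physical voxel spacing in millimetres. The array is indexed as
#' `(depth, height, width)`, i.e. slice, row, column; `spacing` follows the
#' same order, so `spacing[1]` is the slice thickness and `spacing[2:3]` the
#' in-plane pixel height/width.
#'
#' @param voxels numeric rank-3 array `(depth, height, width)` of HU values.
#'   A matrix is promoted to a single-slice volume.
#' @param spacing numeric length-3 vector of strictly positive voxel sizes in
#'   mm, ordered `(slice thickness, pixel height, pixel width)`.
#' @param orientation optional orientation/axis metadata carried through from
#'   the source file (e.g. an xform code); not interpreted by the package.
#'
#' @return An object of class `volume_image` with fields `voxels`, `spacing`
#'   and `orientation`.
#' @examples
#' vol <- volume_image(array(0, c(4, 8, 8)), spacing = c(3, 1, 1))
#' voxel_volume_mm3(vol)
#' @export
volume_image <- function(voxels, spacing, orientation = NULL) {
  if (is.matrix(voxels)) voxels <- array(voxels, c(1L, dim(voxels)))
  if (!is.array(voxels) || length(dim(voxels)) != 3L)
    stop("`voxels` must be a rank-3 array (depth, height, width)", call. = FALSE)
  if (!all(is.finite(voxels)))
    stop("`voxels` must be finite", call. = FALSE)
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || !all(is.finite(spacing)) || any(spacing <= 0))
    stop("`spacing` must be 3 strictly positive values (mm)", call. = FALSE)
  structure(
    list(voxels = voxels, spacing = spacing, orientation = orientation),
    class = "volume_image"
  )
}

#' @export
print.volume_image <- function(x, ...) {
  d <- dim(x$voxels)
  cat(sprintf(
    "<volume_image> %d x %d x %d voxels, spacing %.3g x %.3g x %.3g mm, HU range [%.1f, %.1f]\n",
    d[1], d[2], d[3], x$spacing[1], x$spacing[2], x$spacing[3],
    min(x$voxels), max(x$voxels)
  ))
  invisible(x)
}

#' @rdname volume_image
#' @param x object to test / a `volume_image`.
#' @export
is_volume_image <- function(x) inherits(x, "volume_image")

#' @rdname volume_image
#' @export
voxel_volume_mm3 <- function(x) {
  stopifnot(is_volume_image(x))
  prod(x$spacing)
}

as_volume_image <- function(x, spacing = c(1, 1, 1)) {
  if (is_volume_image(x)) x else volume_image(x, spacing)
}

#' Read and write NIfTI volumes
#'
#' Thin wrappers around [RNifti::readNifti()] / [RNifti::writeNifti()] that
#' translate between the on-disk NIfTI axis order `(x, y, z)` and the
#' package's internal `(depth, height, width)` convention, and recover voxel
#' spacing (mm) from `pixdim`.
#'
#' @param path path of a `.nii` or `.nii.gz` file.
#' @return `read_nifti_volume()` returns a [volume_image];
#'   `write_nifti_volume()` returns `path` invisibly.
#' @export
read_nifti_volume <- function(path) {
  img <- RNifti::readNifti(path)
  a <- as.array(img)
  if (length(dim(a)) == 2L) a <- array(a, c(dim(a), 1L))
  if (length(dim(a)) != 3L)
    stop("expected a 3-D NIfTI volume: ", path, call. = FALSE)
  pd <- RNifti::pixdim(img)
  if (length(pd) < 3L || any(!is.finite(pd[1:3])) || any(pd[1:3] <= 0))
    stop("missing or invalid voxel spacing in NIfTI header: ", path, call. = FALSE)
  # NIfTI is (x, y, z) = (width, height, depth); internal is (depth, height, width)
  volume_image(
    aperm(a, c(3L, 2L, 1L)),
    spacing = c(pd[3], pd[2], pd[1]),
    orientation = tryCatch(RNifti::orientation(img), error = function(e) NULL)
  )
}

#' @rdname read_nifti_volume
#' @param vol a [volume_image] (or a bare array, written with `spacing`).
#' @param spacing spacing used when `vol` is a bare array.
#' @export
write_nifti_volume <- function(vol, path, spacing = c(1, 1, 1)) {
  vol <- as_volume_image(vol, spacing)
  a <- aperm(vol$voxels, c(3L, 2L, 1L))
  img <- RNifti::asNifti(a)
  RNifti::pixdim(img) <- c(vol$spacing[3], vol$spacing[2], vol$spacing[1])
  RNifti::writeNifti(img, path, datatype = "double")
  invisible(path)
}
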