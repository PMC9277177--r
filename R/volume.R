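#' 3D scalar volume with voxel spacing
#'
#' A `volume_grid` is a plain 3D numeric or logical array carrying its voxel
#' spacing (mm per axis) as an attribute. All distances and lesion dimensions
#' reported by the package are in millimetres, computed with this spacing, so
#' anisotropic acquisitions (e.g. 0.65 x 0.65 mm in-plane with 1.0 mm slices)
#' are handled correctly.
#'
#' @param data 3D array (numeric or logical).
#' @param voxel_size_mm positive numeric length-3, spacing per axis in mm.
#' @return the array with class `volume_grid` and a `voxel_size_mm` attribute.
#' @export
volume_grid <- function(data, voxel_size_mm = c(1, 1, 1)) {
  data <- as.array(data)
  if (length(dim(data)) != 3L) stop("volume_grid requires a 3D array")
  voxel_size_mm <- as.numeric(voxel_size_mm)
  if (length(voxel_size_mm) != 3L || any(!is.finite(voxel_size_mm)) ||
      any(voxel_size_mm <= 0))
    stop("voxel_size_mm must be 3 strictly positive values")
  attr(data, "voxel_size_mm") <- voxel_size_mm
  class(data) <- c("volume_grid", class(data))
  data
}

#' Voxel spacing of a volume
#' @param x a `volume_grid`, or any array (falls back to `default`).
#' @param default spacing used when `x` carries none.
#' @return numeric length-3 spacing in mm.
#' @export
voxel_size <- function(x, default = NULL) {
  vs <- attr(x, "voxel_size_mm")
  if (is.null(vs)) vs <- default
  if (is.null(vs)) stop("no voxel size available; supply voxel_size_mm")
  as.numeric(vs)
}

#' @export
print.volume_grid <- function(x, ...) {
  cat("<volume_grid> ", paste(dim(x), collapse = " x "),
      " voxels, spacing ", paste(voxel_size(x), collapse = " x "),
      " mm\n", sep = "")
  invisible(x)
}

# voxel coordinate helpers: voxels are n x 3 integer matrices of 1-based
# array indices; linear keys are used for set operations
.vox_key <- function(vox, dm) {
  (as.integer(vox[, 3L]) - 1L) * (dm[1L] * dm[2L]) +
    (as.integer(vox[, 2L]) - 1L) * dm[1L] + as.integer(vox[, 1L])
}

.vox_from_mask <- function(mask) {
  which(mask != 0, arr.ind = TRUE, useNames = FALSE)
}

.mask_from_vox <- function(vox, dm) {
  m <- array(FALSE, dm)
  if (nrow(vox)) m[vox] <- TRUE
  m
}

.same_grid <- function(a, b) identical(dim(a), dim(b))

#' Read a NIfTI volume
#'
#' Thin wrapper around [RNifti::readNifti()] returning a [volume_grid] with
#' the spacing taken from the NIfTI header.
#' @param path path to a `.nii` or `.nii.gz` file.
#' @return a [volume_grid].
#' @export
read_volume <- function(path) {
  img <- RNifti::readNifti(path)
  vs <- RNifti::pixdim(img)[1:3]
  volume_grid(array(as.numeric(img), dim = dim(img)[1:3]), vs)
}

#' Write a volume as NIfTI-1
#' @param x a [volume_grid] (or array plus `voxel_size_mm`).
#' @param path output path (`.nii` or `.nii.gz`).
#' @param voxel_size_mm spacing override.
#' @param datatype NIfTI datatype, e.g. `"uint8"` for masks.
#' @return `path`, invisibly.
#' @export
write_volume <- function(x, path, voxel_size_mm = NULL, datatype = "auto") {
  vs <- if (is.null(voxel_size_mm)) voxel_size(x) else voxel_size_mm
  arr <- array(as.numeric(x), dim = dim(x))
  attr(arr, "pixdim") <- as.numeric(vs)
  img <- RNifti::asNifti(arr, datatype = datatype)
  RNifti::writeNifti(img, path)
  invisible(path)
}
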