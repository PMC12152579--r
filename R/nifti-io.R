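#' Read and write NIfTI-1 volumes
#'
#' Thin wrappers around RNifti for the volume types the pipeline exchanges:
#' 4-D DWI series, 6-component tensor volumes, 3-D scalar maps and ROI masks.
#' Volumes are reoriented to RAS on load so that tensor component x is
#' left-right, matching the assumption that medullary veins run along x at
#' the ALPS reference slice.
#'
#' @param path Path to a `.nii` or `.nii.gz` file.
#' @return `read_nifti_volume()`: a plain numeric array with attribute
#'   `voxel_size_mm`.
#' @export
read_nifti_volume <- function(path) {
  img <- RNifti::readNifti(path)
  orn <- tryCatch(RNifti::orientation(img), error = function(e) NA_character_)
  if (!is.na(orn) && orn != "RAS") {
    RNifti::orientation(img) <- "RAS"
  }
  arr <- as.array(img)
  attr(arr, "voxel_size_mm") <- RNifti::pixdim(img)[1:3]
  arr
}

#' @rdname read_nifti_volume
#' @param arr Numeric array (3-D or 4-D) to write.
#' @param voxel_size_mm Voxel edge lengths in mm.
#' @return `write_nifti_volume()`: `path`, invisibly.
#' @export
write_nifti_volume <- function(arr, path, voxel_size_mm = c(1, 1, 1)) {
  img <- RNifti::asNifti(unclass(arr))
  nd <- length(dim(arr))
  RNifti::pixdim(img) <- c(voxel_size_mm, rep(1, max(0, nd - 3)))
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' @rdname read_nifti_volume
#' @param tensors A [tensor_volume]; written as a 4-D volume with the six
#'   unique components (Dxx, Dyy, Dzz, Dxy, Dxz, Dyz) along the 4th dimension.
#' @export
write_tensor_nifti <- function(tensors, path) {
  stopifnot(inherits(tensors, "tensor_volume"))
  write_nifti_volume(tensors$D, path, tensors$voxel_size_mm)
}

#' @rdname read_nifti_volume
#' @export
read_tensor_nifti <- function(path) {
  arr <- read_nifti_volume(path)
  if (length(dim(arr)) != 4L || dim(arr)[4] != 6L) {
    abort("Tensor NIfTI must be 4-D with 6 components in the 4th dimension.")
  }
  vs <- attr(arr, "voxel_size_mm")
  attr(arr, "voxel_size_mm") <- NULL
  tensor_volume(arr, voxel_size_mm = vs)
}
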