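#' Spherical region-of-interest specification
#'
#' Describes one named spherical ROI in voxel space: where it sits, how big it
#' is, which fiber population it samples (projection fibers run
#' inferior-superior, association fibers anterior-posterior at the ALPS
#' reference slice) and which hemisphere it belongs to.
#'
#' @param name Label for the ROI.
#' @param center_voxel Length-3 integer voxel index of the sphere center
#'   (1-based).
#' @param diameter_mm Sphere diameter in mm (default 5, the conventional
#'   perivascular-space ROI size).
#' @param fiber_class `"projection"` or `"association"`.
#' @param hemisphere `"left"` or `"right"`.
#' @return An object of class `roi_spec`.
#' @export
roi_spec <- function(name, center_voxel, diameter_mm = 5,
                     fiber_class = c("projection", "association"),
                     hemisphere = c("left", "right")) {
  fiber_class <- match.arg(fiber_class)
  hemisphere <- match.arg(hemisphere)
  center_voxel <- as.integer(center_voxel)
  if (length(center_voxel) != 3L || any(is.na(center_voxel))) {
    abort("`center_voxel` must be 3 integer indices.")
  }
  if (!is.numeric(diameter_mm) || length(diameter_mm) != 1L || diameter_mm <= 0) {
    abort("`diameter_mm` must be a single positive number.")
  }
  structure(
    list(
      name = as.character(name), center_voxel = center_voxel,
      diameter_mm = as.numeric(diameter_mm), fiber_class = fiber_class,
      hemisphere = hemisphere
    ),
    class = "roi_spec"
  )
}

#' @export
print.roi_spec <- function(x, ...) {
  cat(sprintf(
    "<roi_spec> %s: %s/%s, %g mm sphere at voxel (%d, %d, %d)\n",
    x$name, x$hemisphere, x$fiber_class, x$diameter_mm,
    x$center_voxel[1], x$center_voxel[2], x$center_voxel[3]
  ))
  invisible(x)
}

#' Rasterize a spherical ROI to a voxel mask
#'
#' A voxel belongs to the sphere when the physical (mm) distance between its
#' center and the center voxel's center is at most `diameter_mm / 2`
#' (inclusive boundary). The mask is clipped to the grid; the center voxel is
#' always included, so the mask is never empty.
#'
#' @param spec A [roi_spec].
#' @param voxel_size_mm Length-3 voxel edge lengths in mm.
#' @param grid_shape Length-3 integer grid dimensions.
#' @return Logical 3-D array of `grid_shape`.
#' @examples
#' m <- make_spherical_roi(
#'   roi_spec("demo", c(16, 16, 16)),
#'   voxel_size_mm = c(1, 1, 1), grid_shape = c(32, 32, 32)
#' )
#' sum(m) # 81 voxels for a 5 mm sphere on a 1 mm grid
#' @export
make_spherical_roi <- function(spec, voxel_size_mm, grid_shape) {
  stopifnot(inherits(spec, "roi_spec"))
  voxel_size_mm <- as.numeric(voxel_size_mm)
  grid_shape <- as.integer(grid_shape)
  stopifnot(length(voxel_size_mm) == 3L, all(voxel_size_mm > 0),
    length(grid_shape) == 3L, all(grid_shape >= 1L))
  ctr <- spec$center_voxel
  if (any(ctr < 1L) || any(ctr > grid_shape)) {
    abort(sprintf(
      "ROI '%s': center voxel (%d, %d, %d) is outside the %d x %d x %d grid.",
      spec$name, ctr[1], ctr[2], ctr[3], grid_shape[1], grid_shape[2], grid_shape[3]
    ))
  }
  r <- spec$diameter_mm / 2
  # candidate index ranges, clipped to the grid
  lo <- pmax(1L, ctr - ceiling(r / voxel_size_mm))
  hi <- pmin(grid_shape, ctr + ceiling(r / voxel_size_mm))
  mask <- array(FALSE, dim = grid_shape)
  xs <- lo[1]:hi[1]
  ys <- lo[2]:hi[2]
  zs <- lo[3]:hi[3]
  dx2 <- ((xs - ctr[1]) * voxel_size_mm[1])^2
  dy2 <- ((ys - ctr[2]) * voxel_size_mm[2])^2
  dz2 <- ((zs - ctr[3]) * voxel_size_mm[3])^2
  d2 <- outer(outer(dx2, dy2, "+"), dz2, "+")
  mask[xs, ys, zs] <- d2 <= r^2 + 1e-12
  mask
}

#' Mean directional diffusivities within a mask
#'
#' Arithmetic means of the diagonal tensor components (Dxx, Dyy, Dzz) over
#' the masked voxels -- the per-axis water diffusivities the ALPS index is
#' built from. Diffusivity along an axis is read from the tensor's diagonal
#' in the template frame, the standard ALPS practice.
#'
#' @param tensors A [tensor_volume].
#' @param mask Logical 3-D array of the same grid shape.
#' @return Named numeric vector `c(dxx, dyy, dzz)` in mm^2/s, with attribute
#'   `n_voxels`.
#' @export
extract_directional_diffusivities <- function(tensors, mask) {
  stopifnot(inherits(tensors, "tensor_volume"))
  mask <- as.logical(mask)
  dm <- dim(tensors$D)
  if (length(mask) != prod(dm[1:3])) {
    abort("`mask` shape does not match the tensor grid.")
  }
  idx <- which(mask)
  if (!length(idx)) {
    abort("Empty ROI mask: no voxels to average.")
  }
  nvox <- prod(dm[1:3])
  Dm <- matrix(tensors$D, nrow = nvox, ncol = 6L)
  vals <- Dm[idx, 1:3, drop = FALSE]
  bad <- idx[rowSums(!is.finite(vals)) > 0L]
  if (length(bad)) {
    abort(sprintf(
      "Non-finite tensors inside the ROI at voxel index(es): %s",
      paste(head(arrayInd(bad, dm[1:3]) |>
        apply(1, paste, collapse = ","), 10), collapse = "; ")
    ))
  }
  out <- c(dxx = mean(vals[, 1]), dyy = mean(vals[, 2]), dzz = mean(vals[, 3]))
  attr(out, "n_voxels") <- length(idx)
  out
}
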