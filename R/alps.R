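#' DTI-ALPS index from directional diffusivities
#'
#' The ALPS index is the ratio of the mean x-axis diffusivity in the
#' projection- and association-fiber ROIs to the mean of the diffusivities
#' perpendicular to each fiber class (y in the projection area, z in the
#' association area):
#' `mean(Dx_proj, Dx_assoc) / mean(Dy_proj, Dz_assoc)`.
#' Values near 1 indicate no preferential perivascular diffusion along the
#' medullary-vein (x) axis; healthy adults typically sit around 1.3-1.6.
#'
#' @param dx_proj,dy_proj Mean Dxx and Dyy in the projection-fiber ROI
#'   (mm^2/s).
#' @param dx_assoc,dz_assoc Mean Dxx and Dzz in the association-fiber ROI
#'   (mm^2/s).
#' @return The unitless ALPS index (single number).
#' @examples
#' compute_alps(
#'   dx_proj = 0.5e-3, dx_assoc = 0.5e-3,
#'   dy_proj = 0.4e-3, dz_assoc = 0.4e-3
#' ) # 1.25
#' @export
compute_alps <- function(dx_proj, dx_assoc, dy_proj, dz_assoc) {
  vals <- c(dx_proj, dx_assoc, dy_proj, dz_assoc)
  if (length(vals) != 4L || any(!is.finite(vals))) {
    abort("All four directional diffusivities must be single finite numbers.")
  }
  if (any(vals <= 0)) {
    abort("ALPS is undefined for nonpositive diffusivities (check ROI placement / fit QC).")
  }
  ((dx_proj + dx_assoc) / 2) / ((dy_proj + dz_assoc) / 2)
}

#' Combine hemispheric ALPS indices
#'
#' @param alps_left,alps_right Per-hemisphere ALPS indices; either (but not
#'   both) may be `NA` or `NULL`.
#' @param mode `"mean"` (default: average available hemispheres), `"left"` or
#'   `"right"`.
#' @return A single ALPS index. When `mode = "mean"` and only one hemisphere
#'   is present, that hemisphere is returned with a message noting the
#'   downgrade.
#' @export
bilateral_alps <- function(alps_left = NULL, alps_right = NULL,
                           mode = c("mean", "left", "right")) {
  mode <- match.arg(mode)
  l <- if (is.null(alps_left) || !length(alps_left)) NA_real_ else as.numeric(alps_left)
  r <- if (is.null(alps_right) || !length(alps_right)) NA_real_ else as.numeric(alps_right)
  if (is.na(l) && is.na(r)) {
    abort("At least one hemisphere's ALPS index is required.")
  }
  if (mode == "left") {
    if (is.na(l)) abort("mode = 'left' but the left-hemisphere index is missing.")
    return(l)
  }
  if (mode == "right") {
    if (is.na(r)) abort("mode = 'right' but the right-hemisphere index is missing.")
    return(r)
  }
  if (is.na(l) || is.na(r)) {
    inform("bilateral_alps: only one hemisphere available; returning it instead of the mean.")
    return(if (is.na(l)) r else l)
  }
  (l + r) / 2
}

#' Per-subject ALPS result from a tensor volume
#'
#' Rasterizes the four (or two, for unilateral data) spherical ROIs, averages
#' the diagonal diffusivities in each, and assembles the hemispheric and
#' combined ALPS indices.
#'
#' @param tensors A [tensor_volume].
#' @param rois List of [roi_spec] objects. Each hemisphere that is present
#'   must contribute exactly one projection and one association ROI.
#' @param mode Hemisphere aggregation mode passed to [bilateral_alps()].
#' @param subject_id Optional identifier carried into the output.
#' @return A one-row tibble with per-hemisphere directional means
#'   (`dx_proj_left`, ..., in mm^2/s), ROI voxel counts, `alps_left`,
#'   `alps_right`, and the combined `alps`.
#' @export
alps_from_tensors <- function(tensors, rois, mode = c("mean", "left", "right"),
                              subject_id = NA_character_) {
  mode <- match.arg(mode)
  stopifnot(inherits(tensors, "tensor_volume"))
  if (inherits(rois, "roi_spec")) rois <- list(rois)
  stopifnot(length(rois) >= 2L, all(vapply(rois, inherits, TRUE, "roi_spec")))
  grid_shape <- dim(tensors$D)[1:3]

  hemi_vals <- list(left = NULL, right = NULL)
  row <- list(subject_id = subject_id)
  for (h in c("left", "right")) {
    specs <- rois[vapply(rois, function(s) s$hemisphere == h, TRUE)]
    if (!length(specs)) next
    cls <- vapply(specs, function(s) s$fiber_class, "")
    if (!setequal(cls, c("projection", "association")) || length(specs) != 2L) {
      abort(sprintf(
        "Hemisphere '%s' needs exactly one projection and one association ROI.", h
      ))
    }
    proj <- specs[[which(cls == "projection")]]
    assoc <- specs[[which(cls == "association")]]
    mp <- extract_directional_diffusivities(
      tensors, make_spherical_roi(proj, tensors$voxel_size_mm, grid_shape)
    )
    ma <- extract_directional_diffusivities(
      tensors, make_spherical_roi(assoc, tensors$voxel_size_mm, grid_shape)
    )
    row[[paste0("dx_proj_", h)]] <- unname(mp["dxx"])
    row[[paste0("dy_proj_", h)]] <- unname(mp["dyy"])
    row[[paste0("dx_assoc_", h)]] <- unname(ma["dxx"])
    row[[paste0("dz_assoc_", h)]] <- unname(ma["dzz"])
    row[[paste0("n_voxels_proj_", h)]] <- attr(mp, "n_voxels")
    row[[paste0("n_voxels_assoc_", h)]] <- attr(ma, "n_voxels")
    hemi_vals[[h]] <- compute_alps(
      dx_proj = mp["dxx"], dx_assoc = ma["dxx"],
      dy_proj = mp["dyy"], dz_assoc = ma["dzz"]
    )
  }
  if (is.null(hemi_vals$left) && is.null(hemi_vals$right)) {
    abort("No hemisphere had a complete projection/association ROI pair.")
  }
  row$alps_left <- hemi_vals$left %||% NA_real_
  row$alps_right <- hemi_vals$right %||% NA_real_
  row$alps <- bilateral_alps(row$alps_left, row$alps_right, mode = mode)
  tibble::as_tibble(row)
}
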