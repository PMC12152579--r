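#' Diffusion tensor volume
#'
#' A per-voxel symmetric diffusion tensor field in the template frame. The
#' component axis holds the six unique tensor elements in the order
#' (Dxx, Dyy, Dzz, Dxy, Dxz, Dyz), in mm^2/s, with x = left-right,
#' y = anterior-posterior, z = inferior-superior. Voxel indices are 1-based,
#' as everywhere in R.
#'
#' @param D 4-D numeric array `dim = c(nx, ny, nz, 6)` of tensor components.
#' @param voxel_size_mm Length-3 positive numeric, voxel edge lengths in mm.
#' @param fit_mask Optional logical 3-D array marking voxels with a valid fit;
#'   defaults to all `TRUE`.
#' @return An object of class `tensor_volume` with elements `D`,
#'   `voxel_size_mm`, `fit_mask`.
#' @export
tensor_volume <- function(D, voxel_size_mm = c(1, 1, 1), fit_mask = NULL) {
  D <- unclass(D)
  if (length(dim(D)) != 4L || dim(D)[4] != 6L) {
    abort("`D` must be a 4-D array with 6 tensor components in the 4th dimension.")
  }
  voxel_size_mm <- as.numeric(voxel_size_mm)
  if (length(voxel_size_mm) != 3L || any(!is.finite(voxel_size_mm)) ||
    any(voxel_size_mm <= 0)) {
    abort("`voxel_size_mm` must be 3 positive numbers.")
  }
  if (is.null(fit_mask)) {
    fit_mask <- array(TRUE, dim = dim(D)[1:3])
  }
  stopifnot(identical(dim(fit_mask), dim(D)[1:3]))
  structure(
    list(D = D, voxel_size_mm = voxel_size_mm, fit_mask = fit_mask),
    class = "tensor_volume"
  )
}

#' @export
print.tensor_volume <- function(x, ...) {
  d <- dim(x$D)
  cat(sprintf(
    "<tensor_volume> %d x %d x %d voxels (%.3g x %.3g x %.3g mm), %d/%d fitted\n",
    d[1], d[2], d[3], x$voxel_size_mm[1], x$voxel_size_mm[2], x$voxel_size_mm[3],
    sum(x$fit_mask), prod(d[1:3])
  ))
  invisible(x)
}

# Design matrix of the log-linear tensor model: log S = log S0 - b g' D g,
# columns (logS0, Dxx, Dyy, Dzz, Dxy, Dxz, Dyz).
tensor_design_matrix <- function(gtab) {
  b <- gtab$bvals
  g <- gtab$bvecs
  cbind(
    1,
    -b * g[1, ]^2,
    -b * g[2, ]^2,
    -b * g[3, ]^2,
    -2 * b * g[1, ] * g[2, ],
    -2 * b * g[1, ] * g[3, ],
    -2 * b * g[2, ] * g[3, ]
  )
}

#' Fit diffusion tensors by log-linear least squares
#'
#' Fits a symmetric diffusion tensor per voxel by ordinary (unweighted) linear
#' least squares on `log(S)` against the b-matrix, the classical log-linear
#' estimator. Voxels with any nonpositive signal cannot be log-transformed;
#' they are masked out (tensor set to `NA`) and their count reported.
#'
#' @param dwi 4-D numeric array of diffusion-weighted signals, 4th dimension
#'   indexing volumes in gradient-table order.
#' @param gtab A [gradient_table] matching the 4th dimension of `dwi`.
#' @param voxel_size_mm Voxel edge lengths in mm (default 1 mm isotropic).
#' @return A [tensor_volume]; the attribute `n_masked` holds the number of
#'   voxels excluded for nonpositive signals.
#' @examples
#' gt <- default_gradient_scheme()
#' S <- simulate_dwi_signal(diag(3) * 7e-4, gt)
#' dwi <- array(rep(S, each = 8), dim = c(2, 2, 2, length(S)))
#' fit <- fit_tensor(dwi, gt)
#' fit$D[1, 1, 1, ] # ~ (7e-4, 7e-4, 7e-4, 0, 0, 0)
#' @export
fit_tensor <- function(dwi, gtab, voxel_size_mm = c(1, 1, 1)) {
  stopifnot(inherits(gtab, "gradient_table"))
  dwi <- unclass(dwi)
  dm <- dim(dwi)
  if (length(dm) != 4L) {
    abort("`dwi` must be a 4-D array (x, y, z, volume).")
  }
  if (dm[4] != length(gtab$bvals)) {
    abort(sprintf(
      "DWI has %d volumes but the gradient table has %d entries.",
      dm[4], length(gtab$bvals)
    ))
  }
  if (!any(gtab$bvals == 0)) {
    abort("Gradient table has no b = 0 reference volume.")
  }
  if (n_unique_directions(gtab$bvals, gtab$bvecs) < 6L) {
    abort("Rank-deficient design: fewer than 6 unique nonzero-b directions.")
  }
  X <- tensor_design_matrix(gtab)
  if (qr(X)$rank < 7L) {
    abort("Rank-deficient design: the b-matrix does not span all tensor components.")
  }

  nvox <- prod(dm[1:3])
  S <- matrix(dwi, nrow = nvox, ncol = dm[4]) # voxels x volumes
  ok <- rowSums(!is.finite(S) | S <= 0) == 0L
  n_masked <- sum(!ok)
  if (n_masked > 0L) {
    inform(sprintf(
      "fit_tensor: %d voxel(s) with nonpositive or non-finite signal masked out.",
      n_masked
    ))
  }

  B <- matrix(NA_real_, nrow = nvox, ncol = 7L)
  if (any(ok)) {
    Y <- t(log(S[ok, , drop = FALSE])) # volumes x voxels
    # one shared design -> solve the normal equations once for all voxels
    B[ok, ] <- t(solve(crossprod(X), crossprod(X, Y)))
  }
  D <- array(B[, 2:7], dim = c(dm[1:3], 6L))
  out <- tensor_volume(D, voxel_size_mm,
    fit_mask = array(ok, dim = dm[1:3])
  )
  attr(out, "n_masked") <- n_masked
  attr(out, "log_s0") <- array(B[, 1], dim = dm[1:3])
  out
}

#' Forward-simulate DWI signals from a single tensor
#'
#' Noise-free single-tensor forward model `S = S0 * exp(-b g' D g)`, used by
#' the phantom generator and as the round-trip oracle for [fit_tensor()].
#'
#' @param D Symmetric 3 x 3 tensor in mm^2/s.
#' @param gtab A [gradient_table].
#' @param s0 Non-diffusion-weighted signal (default 1000).
#' @return Numeric vector of signals, one per gradient-table entry.
#' @export
simulate_dwi_signal <- function(D, gtab, s0 = 1000) {
  stopifnot(inherits(gtab, "gradient_table"))
  D <- as.matrix(D)
  stopifnot(identical(dim(D), c(3L, 3L)), max(abs(D - t(D))) < 1e-12)
  g <- gtab$bvecs
  quad <- colSums(g * (D %*% g))
  as.numeric(s0 * exp(-gtab$bvals * quad))
}

# voxelwise symmetric 3x3 from a 6-vector (Dxx, Dyy, Dzz, Dxy, Dxz, Dyz)
tensor6_to_mat <- function(v) {
  matrix(c(
    v[1], v[4], v[5],
    v[4], v[2], v[6],
    v[5], v[6], v[3]
  ), 3, 3)
}

#' Eigen-decompose a tensor volume
#'
#' Per-voxel eigenvalues (sorted descending) and orthonormal eigenvectors of
#' the symmetric diffusion tensor. Voxels with non-finite tensor entries
#' (e.g. masked during fitting) propagate `NA` eigenvalues; their count is
#' reported. Voxels with negative eigenvalues are flagged, not clamped, so
#' downstream ratios are never silently biased.
#'
#' @param tensors A [tensor_volume].
#' @return List with `values` (array `nx x ny x nz x 3`, descending),
#'   `vectors` (array `nx x ny x nz x 3 x 3`; `[,,,,"k"]` is the k-th
#'   eigenvector), and `negative_eigenvalue` (logical 3-D array flagging
#'   voxels whose smallest eigenvalue is negative).
#' @export
tensor_eigen <- function(tensors) {
  stopifnot(inherits(tensors, "tensor_volume"))
  dm <- dim(tensors$D)
  nvox <- prod(dm[1:3])
  Dm <- matrix(tensors$D, nrow = nvox, ncol = 6L)
  vals <- matrix(NA_real_, nvox, 3L)
  vecs <- array(NA_real_, c(nvox, 3L, 3L))
  finite <- rowSums(!is.finite(Dm)) == 0L
  n_bad <- sum(!finite)
  if (n_bad > 0L) {
    inform(sprintf(
      "tensor_eigen: %d voxel(s) with non-finite tensors propagated as NA.",
      n_bad
    ))
  }
  for (i in which(finite)) {
    e <- eigen(tensor6_to_mat(Dm[i, ]), symmetric = TRUE)
    vals[i, ] <- e$values # eigen() returns descending for symmetric
    vecs[i, , ] <- e$vectors
  }
  list(
    values = array(vals, c(dm[1:3], 3L)),
    vectors = array(vecs, c(dm[1:3], 3L, 3L)),
    negative_eigenvalue = array(!is.na(vals[, 3]) & vals[, 3] < 0, dm[1:3])
  )
}

#' Eigenvalue-derived scalar maps (FA, MD, AD, RD)
#'
#' Fractional anisotropy, mean diffusivity, axial diffusivity and radial
#' diffusivity from sorted eigenvalues:
#' MD = mean(lambda), AD = lambda1, RD = (lambda2 + lambda3)/2, and
#' FA = sqrt(3/2) * sqrt(sum((lambda - MD)^2)) / sqrt(sum(lambda^2)),
#' with FA defined as 0 at an all-zero voxel.
#'
#' @param eigenvalues Either the list returned by [tensor_eigen()] or an array
#'   whose last dimension holds the 3 eigenvalues sorted descending.
#' @return List of arrays `fa`, `md`, `ad`, `rd` (FA unitless in `[0, 1]` for
#'   nonnegative eigenvalues; the others in mm^2/s).
#' @examples
#' scalar_maps(array(c(1.4e-3, 0.4e-3, 0.3e-3), c(1, 1, 1, 3)))
#' @export
scalar_maps <- function(eigenvalues) {
  if (is.list(eigenvalues) && !is.null(eigenvalues$values)) {
    eigenvalues <- eigenvalues$values
  }
  dm <- dim(eigenvalues)
  stopifnot(dm[length(dm)] == 3L)
  shape <- dm[-length(dm)]
  L <- matrix(eigenvalues, ncol = 3L)
  md <- rowMeans(L)
  ad <- L[, 1]
  rd <- (L[, 2] + L[, 3]) / 2
  num <- (L[, 1] - md)^2 + (L[, 2] - md)^2 + (L[, 3] - md)^2
  den <- L[, 1]^2 + L[, 2]^2 + L[, 3]^2
  fa <- ifelse(den > 0, sqrt(1.5) * sqrt(num) / sqrt(den), 0)
  fa[is.na(md)] <- NA_real_
  to_arr <- function(v) array(v, dim = shape)
  list(fa = to_arr(fa), md = to_arr(md), ad = to_arr(ad), rd = to_arr(rd))
}
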